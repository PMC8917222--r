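#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values with the Benjamini-Hochberg step-up
#' procedure, returning the adjusted values together with the bookkeeping
#' fields shared by all FDR procedures in the package.
#'
#' @param p Numeric vector of p-values, all in \[0, 1\].
#' @return An object of class `"adjustment_result"`: a list with elements
#'   `procedure` (`"bh"`), `m` (number of tests) and `adj_p` (adjusted
#'   p-values, same order as the input).
#' @seealso [bky_two_stage()] for the adaptive two-stage procedure.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adj_p
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  structure(
    list(procedure = "bh", m = length(p),
         adj_p = stats::p.adjust(p, method = "BH")),
    class = "adjustment_result"
  )
}

#' Benjamini-Krieger-Yekutieli two-stage step-up procedure
#'
#' Adaptive FDR control: a first BH pass at level q/(1+q) estimates the
#' number of true null hypotheses, and a second BH pass at the inflated
#' level q/(1+q) * m/(m - r1) declares the discoveries. If the first stage
#' rejects nothing there are no discoveries; if it rejects everything, all
#' tests are discoveries.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level, in (0, 1). Default 0.01, the level used for
#'   multiple independent t comparisons of summed LFQ intensities.
#' @return An `"adjustment_result"` list with `procedure = "bky"`, `m`, `q`,
#'   `r1` (stage-1 rejection count), `m0_hat = m - r1` (estimated true null
#'   count), `discovery` (logical vector, input order), `q_values`
#'   (adaptive BH-adjusted q-values, `adj_p * m0_hat / m` when
#'   `0 < r1 < m`) and `stage2_level` (NA when stage 2 is not reached).
#' @examples
#' bky_two_stage(c(0.001, 0.01, 0.3, 0.9), q = 0.05)
#' @export
bky_two_stage <- function(p, q = 0.01) {
  check_pvalues(p)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  m <- length(p)
  q1 <- q / (1 + q)
  s1 <- step_up(p, q1)
  r1 <- s1$r
  adj <- stats::p.adjust(p, method = "BH")
  if (r1 == 0L) {
    disc <- rep(FALSE, m)
    qv <- adj
    lvl2 <- NA_real_
  } else if (r1 == m) {
    disc <- rep(TRUE, m)
    qv <- adj * 0 # all rejected; m0_hat = 0
    lvl2 <- NA_real_
  } else {
    lvl2 <- q1 * m / (m - r1)
    disc <- step_up(p, lvl2)$reject
    qv <- pmin(1, adj * (m - r1) / m)
  }
  structure(
    list(procedure = "bky", m = m, q = q, r1 = r1, m0_hat = m - r1,
         discovery = disc, q_values = qv, stage2_level = lvl2),
    class = "adjustment_result"
  )
}

# BH step-up at a fixed level: r = max{k : p_(k) <= k * alpha / m}
step_up <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= alpha * seq_len(m) / m)
  r <- if (length(ok)) max(ok) else 0L
  rej <- logical(m)
  if (r > 0L) rej[o[seq_len(r)]] <- TRUE
  list(r = r, reject = rej)
}

check_pvalues <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (anyNA(p)) stop("p-values must not contain NA")
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("p-values must lie in [0, 1]")
  invisible(p)
}

#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf("FDR adjustment (%s), m = %d tests\n",
              toupper(x$procedure), x$m))
  if (identical(x$procedure, "bky")) {
    cat(sprintf("  q = %g; stage-1 rejections r1 = %d; m0_hat = %d\n",
                x$q, x$r1, x$m0_hat))
    cat(sprintf("  discoveries: %d\n", sum(x$discovery)))
  } else {
    cat(sprintf("  min adjusted p = %s\n",
                if (x$m) format(min(x$adj_p)) else "NA"))
  }
  invisible(x)
}

#' Classify features for volcano-style reporting
#'
#' Assigns each feature to one of four exhaustive, mutually exclusive
#' categories from its log2 fold change and adjusted p-value:
#' `sig_and_fc` (significant with a large fold change, the "red" set),
#' `sig_small_fc` ("blue"), `fc_only` ("green") and `ns`.
#'
#' Features with no adjusted p-value (pseudo fold-change estimates carry no
#' p-value) are classified on fold change alone and flagged in the
#' `"p_missing"` attribute.
#'
#' @param log2_fc Numeric vector of log2 fold changes.
#' @param adj_p Numeric vector of adjusted p-values (NA allowed).
#' @param fc_cut Linear fold-change cut-off; the threshold on
#'   `|log2_fc|` is `log2(fc_cut)`. Default 2.
#' @param p_cut Significance cut-off on the adjusted p-value, strict
#'   (`adj_p < p_cut`). Default 0.05.
#' @return A factor with levels `sig_and_fc`, `sig_small_fc`, `fc_only`,
#'   `ns`, with attribute `p_missing` marking features classified without a
#'   p-value.
#' @examples
#' classify_volcano(c(1.58, 0.58, -1.32), c(0.01, 0.01, 0.2))
#' @export
classify_volcano <- function(log2_fc, adj_p, fc_cut = 2, p_cut = 0.05) {
  stopifnot(length(log2_fc) == length(adj_p), fc_cut > 0)
  if (any(!is.finite(log2_fc)))
    stop("log2_fc must be finite")
  lcut <- log2(fc_cut)
  big <- abs(log2_fc) >= lcut
  sig <- !is.na(adj_p) & adj_p < p_cut
  out <- ifelse(sig & big, "sig_and_fc",
         ifelse(sig & !big, "sig_small_fc",
         ifelse(big, "fc_only", "ns")))
  out <- factor(out, levels = c("sig_and_fc", "sig_small_fc", "fc_only", "ns"))
  attr(out, "p_missing") <- is.na(adj_p)
  out
}

#' Signed linear fold change
#'
#' Converts a log2 fold change to the signed linear convention used in
#' volcano reporting: `2^log2_fc` for increases and `-2^|log2_fc|` for
#' decreases, so that a "fold change beyond +/-2" threshold corresponds to
#' `|log2_fc| >= 1`. A log2 fold change of 0 maps to +1.
#'
#' @param log2_fc Numeric vector of log2 fold changes.
#' @return Numeric vector; `abs()` of every element is >= 1.
#' @examples
#' signed_fc(c(-2, 0, 1))  # -4, 1, 2
#' @export
signed_fc <- function(log2_fc) {
  ifelse(log2_fc >= 0, 2^log2_fc, -2^(-log2_fc))
}
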