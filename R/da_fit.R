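#' Methods for fitted differential-abundance objects
#'
#' The pipeline drivers [run_os_da()], [run_eye_da()] and [lipid_da()]
#' return objects inheriting class `"da_fit"`, holding a per-feature
#' results table plus a skip log. Standard methods are provided:
#' `print`, `summary`, `coef` (named vector of log2 fold changes),
#' `as.data.frame` (the results table) and `plot` (a volcano plot).
#'
#' @param x,object A `da_fit` object.
#' @param ... Passed on where applicable.
#' @name da_fit
NULL

#' @rdname da_fit
#' @export
print.da_fit <- function(x, ...) {
  kind <- switch(x$kind,
                 os = "Peptide-level mixed-model differential abundance",
                 eye = "Protein-level pooled-t differential abundance",
                 lipid = "Targeted-lipidomics differential abundance",
                 "Differential abundance")
  r <- x$results
  cat(kind, "\n", sep = "")
  cat(sprintf("  contrast: %s (reference level %s)\n",
              x$contrast, x$ref_level))
  cat(sprintf("  features analysed: %d (%s); skipped: %d\n", nrow(r),
              paste(sprintf("%s %d", names(table(r$method)),
                            as.integer(table(r$method))), collapse = ", "),
              nrow(x$skipped)))
  if ("category" %in% names(r)) {
    tb <- table(r$category)
    cat(sprintf("  classification: %s\n",
                paste(sprintf("%s %d", names(tb), as.integer(tb)),
                      collapse = ", ")))
  }
  if ("significant" %in% names(r))
    cat(sprintf("  significant (raw p < %g & |FC| >= %g): %d\n",
                x$p_cut, x$fc_cut, sum(r$significant)))
  invisible(x)
}

#' @rdname da_fit
#' @export
summary.da_fit <- function(object, ...) {
  r <- object$results
  out <- list(
    kind = object$kind,
    n_features = nrow(r),
    n_skipped = nrow(object$skipped),
    by_method = table(r$method),
    category = if ("category" %in% names(r)) table(r$category) else NULL,
    n_enriched = sum(r$log2_fc >= log2(object$fc_cut), na.rm = TRUE),
    n_reduced = sum(r$log2_fc <= -log2(object$fc_cut), na.rm = TRUE))
  class(out) <- "summary.da_fit"
  out
}

#' @export
print.summary.da_fit <- function(x, ...) {
  cat(sprintf("%d features analysed (%d skipped)\n",
              x$n_features, x$n_skipped))
  cat(sprintf("  fold change beyond threshold: %d enriched, %d reduced\n",
              x$n_enriched, x$n_reduced))
  if (!is.null(x$category)) {
    cat("  volcano classes:\n")
    for (nm in names(x$category))
      cat(sprintf("    %-12s %d\n", nm, as.integer(x$category[nm])))
  }
  invisible(x)
}

#' @rdname da_fit
#' @export
coef.da_fit <- function(object, ...) {
  stats::setNames(object$results$log2_fc, object$results$feature_id)
}

#' @rdname da_fit
#' @export
as.data.frame.da_fit <- function(x, ...) x$results

#' @rdname da_fit
#' @param p_axis Which p-value to plot on the y axis: `"adj_p"` (default
#'   where available) or `"p"`.
#' @export
plot.da_fit <- function(x, p_axis = c("adj_p", "p"), ...) {
  p_axis <- match.arg(p_axis)
  r <- x$results
  if (!p_axis %in% names(r) || all(is.na(r[[p_axis]]))) p_axis <- "p"
  pv <- r[[p_axis]]
  col <- if ("category" %in% names(r)) {
    c(sig_and_fc = "red3", sig_small_fc = "blue3",
      fc_only = "green4", ns = "grey60")[as.character(r$category)]
  } else if ("significant" %in% names(r)) {
    ifelse(r$significant, "red3", "grey60")
  } else "grey60"
  y <- -log10(pmax(pv, .Machine$double.xmin))
  graphics::plot(r$log2_fc, y, col = col, pch = 16,
                 xlab = "log2 fold change (mutant over control)",
                 ylab = sprintf("-log10 %s", p_axis), ...)
  graphics::abline(v = c(-1, 1) * log2(x$fc_cut), lty = 2, col = "grey40")
  graphics::abline(h = -log10(x$p_cut), lty = 2, col = "grey40")
  invisible(x)
}
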