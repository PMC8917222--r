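#' Two-sample pooled-variance t-test
#'
#' Classical equal-variance two-sample t statistic with a two-sided
#' p-value. Degenerate inputs are resolved explicitly: when the pooled
#' variance is zero with equal means the statistic is 0 with p = 1; with
#' unequal means the p-value is 0 and the comparison is flagged
#' degenerate.
#'
#' @param a,b Numeric vectors, each of length >= 2. The reported
#'   difference is `mean(a) - mean(b)`.
#' @return Object of class `"group_comparison"`: list with `mean_a`,
#'   `mean_b`, `diff`, `pooled_var`, `se`, `t`, `df`, `p`, `degenerate`.
#' @examples
#' pooled_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
pooled_t_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  degenerate <- FALSE
  if (sp2 == 0) {
    if (diff == 0) { t <- 0; p <- 1 }
    else { t <- sign(diff) * Inf; p <- 0; degenerate <- TRUE }
    se <- 0
  } else {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b), diff = diff,
                 pooled_var = sp2, se = se, t = t, df = df, p = p,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Pooled-variance t: diff = %.4f, t = %.4f, df = %d, p = %.4g%s\n",
              x$diff, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate: zero pooled variance)" else ""))
  invisible(x)
}

#' Pseudo fold change for a protein-level comparison
#'
#' When all measurements of a protein are missing in one condition, the
#' missing group average is replaced by the mean of the 10% smallest
#' protein intensities observed in that condition across the dataset
#' (at least one value), and the log2 fold change is reported as mutant
#' minus control. No p-value is produced.
#'
#' @param observed_mean Mean normalized log2 intensity of the protein in
#'   the condition where it was observed.
#' @param pool Normalized per-protein condition-mean intensities of all
#'   proteins observed in the missing condition.
#' @param missing Which condition is fully missing: `"control"` or
#'   `"mutant"`.
#' @param quantile Pool fraction averaged (count `ceiling(quantile * N)`).
#' @return List with `log2_fc`, `fc_signed`, `impute_value`,
#'   `method = "pseudo"`.
#' @examples
#' pseudo_fc_protein(12, pool = 5:14, missing = "control")  # log2 FC 7
#' @export
pseudo_fc_protein <- function(observed_mean, pool,
                              missing = c("control", "mutant"),
                              quantile = 0.10) {
  missing <- match.arg(missing)
  stopifnot(is.numeric(pool), length(pool) >= 1L,
            is.numeric(observed_mean), length(observed_mean) == 1L)
  k <- max(1L, ceiling(quantile * length(pool)))
  impute <- mean(sort(pool)[seq_len(k)])
  lfc <- if (missing == "control") observed_mean - impute
         else impute - observed_mean
  list(log2_fc = lfc, fc_signed = signed_fc(lfc), impute_value = impute,
       method = "pseudo")
}

#' Protein-level (whole-eye) differential abundance pipeline
#'
#' Differential abundance from a protein-level intensity table: proteins
#' are filtered to those with at least `min_peptides` peptides and at most
#' `max_missing` missing sample values, intensities are log2 transformed
#' and normalized with the rescaled robust z-score, and each protein is
#' tested with the pooled-variance t-test (mutant minus control). Proteins
#' fully missing in one condition receive a pseudo fold change instead
#' ([pseudo_fc_protein()]). P-values are Benjamini-Hochberg adjusted.
#'
#' @param table Protein-level long table (`protein_id`, `sample_id`,
#'   `intensity`, `n_peptides`), e.g. from [read_protein_groups()].
#' @param annotation A [sample_annotation()].
#' @param min_peptides,max_missing Filter settings (defaults 2 and 4).
#' @param rescale Use the rescaled robust z-score. Default `TRUE`.
#' @param quantile Imputation pool fraction. Default 0.10.
#' @param fc_cut,p_cut Volcano classification cut-offs.
#' @return Object of class `c("eye_da", "da_fit")` with `results`,
#'   `skipped` (including filtered proteins with their reason) and design
#'   metadata.
#' @export
run_eye_da <- function(table, annotation, min_peptides = 2L,
                       max_missing = 4L, rescale = TRUE, quantile = 0.10,
                       fc_cut = 2, p_cut = 0.05) {
  check_annotation_coverage(table$sample_id, annotation)
  if ("is_reverse" %in% names(table))
    table <- table[!(table$is_reverse | table$is_contaminant), , drop = FALSE]
  input_proteins <- unique(table$protein_id)
  samples <- annotation$sample_id
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")

  skip <- list()
  f1 <- filter_min_peptides(table, min_peptides = min_peptides)
  dropped <- setdiff(input_proteins, unique(f1$protein_id))
  if (length(dropped))
    skip[[1L]] <- data.frame(feature_id = dropped,
                             reason = sprintf("fewer than %d peptides",
                                              min_peptides),
                             stringsAsFactors = FALSE)
  f2 <- filter_max_missing(f1, max_missing = max_missing, samples = samples)
  dropped2 <- setdiff(unique(f1$protein_id), unique(f2$protein_id))
  if (length(dropped2))
    skip[[length(skip) + 1L]] <-
      data.frame(feature_id = dropped2,
                 reason = sprintf("more than %d missing values", max_missing),
                 stringsAsFactors = FALSE)

  norm <- robust_z_normalize(log2_transform_nonzero(f2), rescale = rescale)
  cond <- as.character(
    annotation[[contrast]][match(norm$sample_id, annotation$sample_id)])
  is_mut <- cond != ref

  # dataset-wide per-protein condition means (imputation pools)
  grp <- interaction(norm$protein_id, cond, drop = TRUE)
  cm <- data.frame(
    protein_id = tapply(norm$protein_id, grp, `[`, 1L),
    condition = tapply(cond, grp, `[`, 1L),
    mean_t = as.numeric(tapply(norm$t_intensity, grp, mean)),
    stringsAsFactors = FALSE)
  pool_ctrl <- cm$mean_t[cm$condition == ref]
  pool_mut <- cm$mean_t[cm$condition != ref]

  rows <- list()
  for (pid in unique(f2$protein_id)) {
    sel <- norm$protein_id == pid
    a <- norm$t_intensity[sel & is_mut]   # mutant
    b <- norm$t_intensity[sel & !is_mut]  # control
    if (length(a) >= 2L && length(b) >= 2L) {
      tt <- pooled_t_test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = pid, log2_fc = tt$diff, fc_signed = signed_fc(tt$diff),
        mean_control = tt$mean_b, mean_mutant = tt$mean_a,
        se = tt$se, df = as.numeric(tt$df), p = tt$p, adj_p = NA_real_,
        method = "pooled_t", n_obs = length(a) + length(b),
        impute_value = NA_real_, stringsAsFactors = FALSE)
    } else if (length(a) == 0L && length(b) >= 1L) {
      pf <- pseudo_fc_protein(mean(b), pool_mut, missing = "mutant",
                              quantile = quantile)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = pid, log2_fc = pf$log2_fc, fc_signed = pf$fc_signed,
        mean_control = mean(b), mean_mutant = NA_real_,
        se = NA_real_, df = NA_real_, p = NA_real_, adj_p = NA_real_,
        method = "pseudo", n_obs = length(b),
        impute_value = pf$impute_value, stringsAsFactors = FALSE)
    } else if (length(b) == 0L && length(a) >= 1L) {
      pf <- pseudo_fc_protein(mean(a), pool_ctrl, missing = "control",
                              quantile = quantile)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = pid, log2_fc = pf$log2_fc, fc_signed = pf$fc_signed,
        mean_control = NA_real_, mean_mutant = mean(a),
        se = NA_real_, df = NA_real_, p = NA_real_, adj_p = NA_real_,
        method = "pseudo", n_obs = length(a),
        impute_value = pf$impute_value, stringsAsFactors = FALSE)
    } else {
      skip[[length(skip) + 1L]] <- data.frame(
        feature_id = pid, reason = "fewer than 2 observations in a group",
        stringsAsFactors = FALSE)
    }
  }

  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(feature_id = character(), log2_fc = numeric(),
                      fc_signed = numeric(), mean_control = numeric(),
                      mean_mutant = numeric(), se = numeric(), df = numeric(),
                      p = numeric(), adj_p = numeric(), method = character(),
                      n_obs = integer(), impute_value = numeric(),
                      stringsAsFactors = FALSE)
  tested <- res$method == "pooled_t"
  if (any(tested)) res$adj_p[tested] <- bh_adjust(res$p[tested])$adj_p
  res$category <- classify_volcano(res$log2_fc, res$adj_p,
                                   fc_cut = fc_cut, p_cut = p_cut)
  rownames(res) <- NULL
  structure(
    list(results = res,
         skipped = if (length(skip)) do.call(rbind, skip)
                   else data.frame(feature_id = character(),
                                   reason = character()),
         contrast = contrast, ref_level = ref,
         n_samples = nrow(annotation), fc_cut = fc_cut, p_cut = p_cut,
         kind = "eye", call = match.call()),
    class = c("eye_da", "da_fit"))
}

#' Per-protein comparison of summed normalized peptide intensities
#'
#' For a chosen protein set (for example the BBSome subunits), sums the
#' per-sample peptide intensities of each protein (undetected peptides
#' contribute 0), runs an independent pooled-variance t-test per protein
#' on the sums, and controls the FDR over the comparisons with the
#' two-stage step-up procedure at the given Q level.
#'
#' With `normalize = TRUE` (default), peptide intensities are first log2
#' transformed, normalized with the rescaled robust z-score, and mapped
#' back to the linear scale before summing, so the sums are detected
#' signal on a between-sample-normalized intensity scale.
#'
#' @param table Raw peptide table.
#' @param annotation A [sample_annotation()].
#' @param protein_set Character vector of protein ids to compare.
#' @param normalize Normalize peptide intensities before summing.
#' @param q Target FDR for the two-stage procedure. Default 0.01.
#' @return Object of class `"summed_lfq"`: list with `results` (per
#'   protein: group means of the sums, `t`, `df`, `p`, `q_value`,
#'   `discovery`, `absent_in`), the `adjustment` object and the per-sample
#'   `sums` matrix.
#' @export
summed_lfq_compare <- function(table, annotation, protein_set,
                               normalize = TRUE, q = 0.01) {
  stopifnot(length(protein_set) >= 1L)
  check_annotation_coverage(table$sample_id, annotation)
  if ("is_reverse" %in% names(table))
    table <- table[!(table$is_reverse | table$is_contaminant), , drop = FALSE]
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")
  samples <- annotation$sample_id
  is_mut <- as.character(annotation[[contrast]]) != ref

  if (normalize) {
    norm <- robust_z_normalize(log2_transform_nonzero(table), rescale = TRUE)
    norm$linear <- 2^norm$t_intensity
  } else {
    norm <- table[table$intensity > 0, , drop = FALSE]
    norm$linear <- norm$intensity
  }

  sums <- matrix(0, nrow = length(protein_set), ncol = length(samples),
                 dimnames = list(protein_set, samples))
  present <- protein_set %in% unique(table$protein_id)
  for (pid in protein_set[present]) {
    sel <- norm$protein_id == pid
    s <- tapply(norm$linear[sel], norm$sample_id[sel], sum)
    sums[pid, names(s)] <- s
  }

  rows <- list()
  for (k in seq_along(protein_set)) {
    pid <- protein_set[k]
    if (!present[k]) {
      rows[[k]] <- data.frame(
        feature_id = pid, mean_control = NA_real_, mean_mutant = NA_real_,
        log2_fc = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
        absent_in = "dataset", stringsAsFactors = FALSE)
      next
    }
    a <- sums[pid, is_mut]   # mutant
    b <- sums[pid, !is_mut]  # control
    absent <- if (all(a == 0) && any(b > 0)) "mutant"
              else if (all(b == 0) && any(a > 0)) "control"
              else NA_character_
    tt <- pooled_t_test(a, b)
    rows[[k]] <- data.frame(
      feature_id = pid, mean_control = tt$mean_b, mean_mutant = tt$mean_a,
      log2_fc = if (tt$mean_a > 0 && tt$mean_b > 0)
        log2(tt$mean_a / tt$mean_b) else NA_real_,
      t = tt$t, df = as.numeric(tt$df), p = tt$p,
      absent_in = absent, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p)
  res$q_value <- NA_real_
  res$discovery <- NA
  if (any(ok)) {
    adj <- bky_two_stage(res$p[ok], q = q)
    res$q_value[ok] <- adj$q_values
    res$discovery[ok] <- adj$discovery
  } else adj <- NULL
  rownames(res) <- NULL
  structure(list(results = res, adjustment = adj, sums = sums,
                 contrast = contrast, ref_level = ref, q = q,
                 call = match.call()),
            class = "summed_lfq")
}

#' @export
print.summed_lfq <- function(x, ...) {
  r <- x$results
  cat(sprintf("Summed-intensity comparisons: %d proteins, Q = %g\n",
              nrow(r), x$q))
  cat(sprintf("  discoveries: %d; absent in one condition: %d\n",
              sum(r$discovery, na.rm = TRUE),
              sum(!is.na(r$absent_in))))
  invisible(x)
}
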