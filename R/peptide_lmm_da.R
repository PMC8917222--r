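#' Fit the per-protein peptide-level mixed-effects model
#'
#' Fits, for one protein, a REML linear mixed model of normalized log2
#' peptide intensity on the experimental factors (full factorial of all
#' annotation factors, e.g. `t_intensity ~ Background * Knockout`) with a
#' random intercept per peptide, and reports the contrast effect
#' (mutant minus control, marginal over the levels of any other factor),
#' its standard error, Satterthwaite denominator degrees of freedom and a
#' two-sided t-based p-value.
#'
#' Non-contrast factors are coded with sum-to-zero contrasts so that the
#' contrast coefficient is the marginal effect; factors constant within
#' the protein's observed data are dropped from the fixed design. When the
#' model is singular (peptide variance estimated at zero), the protein has
#' a single peptide, or the mixed fit fails, the model degrades to
#' ordinary least squares on the same fixed effects with residual degrees
#' of freedom, flagged via `method = "ols"`.
#'
#' @param data Normalized peptide records of one protein: data frame with
#'   `peptide_id`, `sample_id`, `t_intensity`.
#' @param annotation A [sample_annotation()].
#' @param factors Annotation columns used as fixed factors; default all
#'   non-`sample_id` columns.
#' @return Object of class `"lmm_fit"`: list with `estimate` (contrast
#'   log2 FC), `se`, `df`, `p`, `method` (`"lmm"` or `"ols"`),
#'   `singular_fallback`, `n_obs`, `n_peptides`, `sigma_pep`, `sigma_e`.
#' @export
fit_protein_lmm <- function(data, annotation, factors = NULL) {
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")
  if (is.null(contrast)) stop("annotation lacks a contrast attribute")
  stopifnot(all(c("peptide_id", "sample_id", "t_intensity") %in% names(data)))
  if (is.null(factors)) factors <- setdiff(names(annotation), "sample_id")
  if (!contrast %in% factors) factors <- c(factors, contrast)

  d <- merge(data, annotation, by = "sample_id")
  lev <- unique(as.character(d[[contrast]]))
  if (length(lev) < 2L) {
    cnd <- structure(
      class = c("oslfq_one_condition", "error", "condition"),
      list(message = "only one contrast level observed; pseudo-FC required",
           call = sys.call()))
    stop(cnd)
  }
  mut <- setdiff(sort(lev), ref)
  d[[contrast]] <- factor(d[[contrast]], levels = c(ref, mut))
  use <- contrast
  for (f in setdiff(factors, contrast)) {
    if (length(unique(d[[f]])) >= 2L) {
      d[[f]] <- factor(d[[f]])
      stats::contrasts(d[[f]]) <- stats::contr.sum(nlevels(d[[f]]))
      use <- c(use, f)
    }
  }
  fixed <- paste(use, collapse = " * ")
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), d)
  if (nrow(d) < ncol(X) + 2L) {
    cnd <- structure(
      class = c("oslfq_too_few_obs", "error", "condition"),
      list(message = sprintf(
        "too few observations (%d) for %d fixed-effect parameters",
        nrow(d), ncol(X)), call = sys.call()))
    stop(cnd)
  }
  coef_name <- paste0(contrast, mut)
  n_pep <- length(unique(d$peptide_id))

  fit <- NULL
  singular <- FALSE
  if (n_pep >= 2L && n_pep < nrow(d)) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lmerTest::lmer(
        stats::as.formula(paste("t_intensity ~", fixed, "+ (1 | peptide_id)")),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      if (lme4::isSingular(fit, tol = 1e-6) ||
          vc$vcov[vc$grp == "peptide_id"] <= 0) {
        singular <- TRUE
        fit <- NULL
      }
    } else singular <- TRUE
  }

  if (!is.null(fit)) {
    cf <- stats::coef(summary(fit))  # lmerTest: Satterthwaite df
    est <- cf[coef_name, "Estimate"]
    se <- cf[coef_name, "Std. Error"]
    df <- cf[coef_name, "df"]
    p <- cf[coef_name, "Pr(>|t|)"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_pep <- sqrt(vc$vcov[vc$grp == "peptide_id"])
    sigma_e <- sqrt(vc$vcov[vc$grp == "Residual"])
    method <- "lmm"
  } else {
    ols <- stats::lm(stats::as.formula(paste("t_intensity ~", fixed)),
                     data = d)
    cf <- stats::coef(summary(ols))
    est <- cf[coef_name, "Estimate"]
    se <- cf[coef_name, "Std. Error"]
    df <- stats::df.residual(ols)
    p <- cf[coef_name, "Pr(>|t|)"]
    sigma_pep <- 0
    sigma_e <- summary(ols)$sigma
    method <- "ols"
  }
  structure(
    list(estimate = unname(est), se = unname(se), df = unname(df),
         p = unname(p), method = method, singular_fallback = singular,
         n_obs = nrow(d), n_peptides = n_pep,
         sigma_pep = sigma_pep, sigma_e = sigma_e,
         contrast = contrast, mutant_level = mut),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Per-protein %s fit: %d peptides, %d observations\n",
              if (x$method == "lmm") "mixed-model" else "least-squares",
              x$n_peptides, x$n_obs))
  cat(sprintf("  %s (%s vs ref): log2 FC = %.4f (se %.4f), df = %.2f, p = %.4g\n",
              x$contrast, x$mutant_level, x$estimate, x$se, x$df, x$p))
  invisible(x)
}

#' Dataset-wide per-peptide per-condition mean intensities
#'
#' Step one of the pseudo fold-change procedure: the mean normalized
#' intensity of each peptide over the observed samples of each condition.
#'
#' @param table Normalized peptide table (`protein_id`, `peptide_id`,
#'   `sample_id`, `t_intensity`).
#' @param annotation A [sample_annotation()].
#' @return Data frame `protein_id`, `peptide_id`, `condition`, `mean_t`.
#' @export
peptide_condition_means <- function(table, annotation) {
  contrast <- attr(annotation, "contrast")
  cond <- annotation[[contrast]][match(table$sample_id,
                                       annotation$sample_id)]
  grp <- interaction(table$peptide_id, cond, drop = TRUE)
  out <- data.frame(
    protein_id = tapply(table$protein_id, grp, `[`, 1L),
    peptide_id = tapply(table$peptide_id, grp, `[`, 1L),
    condition = tapply(as.character(cond), grp, `[`, 1L),
    mean_t = as.numeric(tapply(table$t_intensity, grp, mean)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pseudo fold change for a protein unobserved in one condition
#'
#' For a protein with no observations in exactly one condition, imputes
#' the missing condition's peptide intensity with the mean of the 10%
#' smallest per-peptide condition-mean intensities observed dataset-wide
#' in that condition (at least one value), forms per-peptide log2 fold
#' changes oriented mutant minus control, and reports their median as the
#' protein fold change. No p-value is produced.
#'
#' @param protein_data Normalized peptide records of the protein.
#' @param condition_peptide_means Dataset-wide pool from
#'   [peptide_condition_means()].
#' @param annotation A [sample_annotation()].
#' @param quantile Fraction of the pool averaged; the count is
#'   `ceiling(quantile * N)`. Default 0.10.
#' @return One-row data frame in the differential-abundance result layout
#'   (`feature_id`, `log2_fc`, `fc_signed`, `method = "pseudo"`, `p` and
#'   `adj_p` absent, peptide/observation counts, `impute_value`).
#' @export
pseudo_fc_peptide <- function(protein_data, condition_peptide_means,
                              annotation, quantile = 0.10) {
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")
  lev <- sort(unique(as.character(annotation[[contrast]])))
  mut <- setdiff(lev, ref)
  cond <- annotation[[contrast]][match(protein_data$sample_id,
                                       annotation$sample_id)]
  obs_lev <- unique(as.character(cond))
  if (length(obs_lev) == 0L)
    stop("protein unobserved in both conditions")
  if (length(obs_lev) == 2L)
    stop("protein observed in both conditions; pseudo fold change refused")
  observed <- obs_lev
  missing <- setdiff(lev, observed)

  pool <- condition_peptide_means$mean_t[
    condition_peptide_means$condition == missing]
  if (!length(pool))
    stop("empty imputation pool for condition '", missing, "'")
  k <- max(1L, ceiling(quantile * length(pool)))
  impute <- mean(sort(pool)[seq_len(k)])

  pep_means <- tapply(protein_data$t_intensity, protein_data$peptide_id, mean)
  fc <- if (identical(missing, ref)) pep_means - impute else impute - pep_means
  lfc <- stats::median(fc)
  data.frame(
    feature_id = protein_data$protein_id[1L],
    log2_fc = unname(lfc), fc_signed = signed_fc(unname(lfc)),
    se = NA_real_, df = NA_real_, p = NA_real_, adj_p = NA_real_,
    method = "pseudo",
    n_peptides = length(pep_means), n_obs = nrow(protein_data),
    impute_value = impute,
    stringsAsFactors = FALSE)
}

#' Peptide-level mixed-model differential abundance pipeline
#'
#' End-to-end differential protein abundance from a raw peptide intensity
#' table: zero intensities are removed, the remainder log2 transformed and
#' normalized with the rescaled robust z-score, then each protein is
#' analysed with the peptide-level mixed model ([fit_protein_lmm()]) when
#' it is observed in both conditions, or with the pseudo fold-change
#' procedure ([pseudo_fc_peptide()]) when it is fully unobserved in one.
#' Benjamini-Hochberg adjustment is computed over the family of
#' model-based p-values (pseudo fold changes carry none). Every input
#' protein is accounted for in the results or the skip log.
#'
#' @param table Raw peptide table (from [read_peptides()] or
#'   [simulate_peptide_dataset()]).
#' @param annotation A [sample_annotation()].
#' @param rescale Use the rescaled ("modified") robust z-score. Default
#'   `TRUE`.
#' @param quantile Imputation pool fraction for pseudo fold changes.
#' @param fc_cut,p_cut Volcano classification cut-offs.
#' @return Object of class `c("os_da", "da_fit")`: list with `results`
#'   (one row per analysed protein: `feature_id`, `log2_fc`, `fc_signed`,
#'   `se`, `df`, `p`, `adj_p`, `method` = lmm/ols/pseudo, counts,
#'   `category`), `skipped` (protein, reason), and design metadata.
#' @export
run_os_da <- function(table, annotation, rescale = TRUE, quantile = 0.10,
                      fc_cut = 2, p_cut = 0.05) {
  check_annotation_coverage(table$sample_id, annotation)
  if ("is_reverse" %in% names(table))
    table <- table[!(table$is_reverse | table$is_contaminant), , drop = FALSE]
  input_proteins <- unique(table$protein_id)

  norm <- robust_z_normalize(log2_transform_nonzero(table), rescale = rescale)
  cond_means <- peptide_condition_means(norm, annotation)
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")
  cond <- annotation[[contrast]][match(norm$sample_id,
                                       annotation$sample_id)]

  by_prot <- split(seq_len(nrow(norm)), norm$protein_id)
  rows <- list()
  skip <- list()
  note_skip <- function(id, reason)
    data.frame(feature_id = id, reason = reason, stringsAsFactors = FALSE)

  for (pid in input_proteins) {
    idx <- by_prot[[pid]]
    if (is.null(idx)) {
      skip[[length(skip) + 1L]] <-
        note_skip(pid, "no non-zero observations")
      next
    }
    d <- norm[idx, , drop = FALSE]
    n_lev <- length(unique(as.character(cond[idx])))
    if (n_lev == 2L) {
      f <- tryCatch(fit_protein_lmm(d, annotation), error = function(e) e)
      if (inherits(f, "lmm_fit")) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = pid, log2_fc = f$estimate,
          fc_signed = signed_fc(f$estimate),
          se = f$se, df = f$df, p = f$p, adj_p = NA_real_,
          method = f$method, n_peptides = f$n_peptides, n_obs = f$n_obs,
          impute_value = NA_real_, stringsAsFactors = FALSE)
      } else {
        skip[[length(skip) + 1L]] <- note_skip(pid, conditionMessage(f))
      }
    } else {
      r <- tryCatch(
        pseudo_fc_peptide(d, cond_means, annotation, quantile = quantile),
        error = function(e) e)
      if (is.data.frame(r)) rows[[length(rows) + 1L]] <- r
      else skip[[length(skip) + 1L]] <- note_skip(pid, conditionMessage(r))
    }
  }

  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(feature_id = character(), log2_fc = numeric(),
                      fc_signed = numeric(), se = numeric(), df = numeric(),
                      p = numeric(), adj_p = numeric(), method = character(),
                      n_peptides = integer(), n_obs = integer(),
                      impute_value = numeric(), stringsAsFactors = FALSE)
  tested <- res$method %in% c("lmm", "ols")
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
         kind = "os", call = match.call()),
    class = c("os_da", "da_fit"))
}
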