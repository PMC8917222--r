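#' Ground-truth parameters for a synthetic peptide-level experiment
#'
#' Defines the generative model for a label-free peptide-intensity
#' experiment: per-protein true log2 fold changes (a spike at zero for the
#' null fraction, the rest drawn from symmetric discrete effect levels),
#' per-peptide random intercepts, residual noise, per-sample location and
#' scale distortions, and intensity-dependent left-censored (MNAR)
#' missingness with an optional MCAR component. A designated set of
#' proteins can be fully unobserved in one condition to exercise the
#' pseudo fold-change path.
#'
#' Default dimensions mirror the outer-segment study design: 300 proteins,
#' 3-10 peptides each, 4 vs 4 samples (set at simulation time), log2
#' intensities centred near 25 with peptide sd 0.5 and residual sd 0.3.
#' The censoring midpoint 23.2 with scale 0.5 yields roughly 20% missing
#' values under these defaults.
#'
#' @param n_proteins Number of proteins.
#' @param pi0 Fraction of true-null proteins (log2 FC = 0).
#' @param effect_levels Absolute log2 FC values for non-null proteins;
#'   each non-null protein draws one level and a random sign.
#' @param n_peptides_range Integer range (min, max) of peptides per protein.
#' @param sigma_pep Peptide random-intercept sd (log2 units).
#' @param sigma_e Residual sd (log2 units).
#' @param mu_mean,mu_sd Mean and sd of per-protein baseline log2 intensity.
#' @param sample_loc_sd Sd of per-sample additive location shifts.
#' @param sample_scale_sd Sd of log per-sample multiplicative scale
#'   distortions (0 = no scale distortion).
#' @param censor_mid,censor_scale Midpoint and scale of the logistic
#'   left-censoring curve `P(missing | x) = 1 / (1 + exp((x - mid)/scale))`;
#'   `censor_scale = 0` disables MNAR censoring.
#' @param mcar_rate Additional missing-completely-at-random rate.
#' @param n_absent_mutant,n_absent_control Number of proteins forced to be
#'   fully unobserved in the mutant (resp. control) condition; the two
#'   sets are disjoint.
#' @param seed Integer seed governing all draws.
#' @return An object of class `"synthetic_truth"`: a list with a
#'   `proteins` data frame (`protein_id`, `delta` = true log2 FC,
#'   `n_peptides`, `mu`, `absent_in`) and the generator parameters.
#' @export
peptide_truth <- function(n_proteins = 300L, pi0 = 0.8,
                          effect_levels = c(1, 2),
                          n_peptides_range = c(3L, 10L),
                          sigma_pep = 0.5, sigma_e = 0.3,
                          mu_mean = 25, mu_sd = 2,
                          sample_loc_sd = 0.5, sample_scale_sd = 0,
                          censor_mid = 23.2, censor_scale = 0.5,
                          mcar_rate = 0,
                          n_absent_mutant = 0L, n_absent_control = 0L,
                          seed = 20220311L) {
  stopifnot(n_proteins >= 1, pi0 >= 0, pi0 <= 1,
            sigma_pep >= 0, sigma_e >= 0, mcar_rate >= 0, mcar_rate < 1,
            censor_scale >= 0, length(n_peptides_range) == 2L)
  if (n_absent_mutant + n_absent_control > n_proteins)
    stop("more fully-missing proteins than proteins")
  set.seed(seed)
  n_null <- round(pi0 * n_proteins)
  delta <- numeric(n_proteins)
  n_alt <- n_proteins - n_null
  if (n_alt > 0) {
    idx <- sample.int(n_proteins, n_alt)
    delta[idx] <- sample(effect_levels, n_alt, replace = TRUE) *
      sample(c(-1, 1), n_alt, replace = TRUE)
  }
  absent_in <- rep(NA_character_, n_proteins)
  if (n_absent_mutant > 0)
    absent_in[seq_len(n_absent_mutant)] <- "mutant"
  if (n_absent_control > 0)
    absent_in[n_absent_mutant + seq_len(n_absent_control)] <- "control"
  proteins <- data.frame(
    protein_id = sprintf("PROT%04d", seq_len(n_proteins)),
    delta = delta,
    n_peptides = sample(seq.int(n_peptides_range[1], n_peptides_range[2]),
                        n_proteins, replace = TRUE),
    mu = stats::rnorm(n_proteins, mu_mean, mu_sd),
    absent_in = absent_in,
    stringsAsFactors = FALSE)
  structure(
    list(proteins = proteins, sigma_pep = sigma_pep, sigma_e = sigma_e,
         sample_loc_sd = sample_loc_sd, sample_scale_sd = sample_scale_sd,
         censor_mid = censor_mid, censor_scale = censor_scale,
         mcar_rate = mcar_rate, pi0 = pi0, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Simulate a peptide-level label-free dataset with known ground truth
#'
#' Generates log2 peptide intensities
#' `x = mu_p + b_j + delta_p * 1[mutant] + e`, with peptide intercepts
#' `b_j ~ N(0, sigma_pep^2)` and residuals `e ~ N(0, sigma_e^2)`, applies
#' the per-sample affine distortion `a_i + s_i * x`, exponentiates to the
#' raw intensity scale, then applies logistic left-censoring, MCAR
#' dropout and the designated fully-missing protein sets (missing values
#' are recorded as intensity 0).
#'
#' @param truth A [peptide_truth()] object.
#' @param n_control,n_mutant Samples per condition (default 4 vs 4, the
#'   outer-segment design).
#' @return A list with `peptides` (long-format table: `protein_id`,
#'   `peptide_id`, `sample_id`, `intensity`, flag columns), `annotation`
#'   (a [sample_annotation()] with contrast factor `Knockout`,
#'   levels control/mutant) and `truth` (the input, with the realized
#'   per-sample distortions attached as `sample_effects`).
#' @export
simulate_peptide_dataset <- function(truth, n_control = 4L, n_mutant = 4L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_control >= 1, n_mutant >= 1)
  set.seed(truth$seed + 1L)
  pr <- truth$proteins
  samples <- c(sprintf("ctrl_%d", seq_len(n_control)),
               sprintf("mut_%d", seq_len(n_mutant)))
  is_mut <- rep(c(FALSE, TRUE), c(n_control, n_mutant))
  n_s <- length(samples)
  loc <- stats::rnorm(n_s, 0, truth$sample_loc_sd)
  scl <- exp(stats::rnorm(n_s, 0, truth$sample_scale_sd))

  j_pep <- sequence(pr$n_peptides)             # peptide index within protein
  p_idx <- rep(seq_len(nrow(pr)), pr$n_peptides)
  n_pep_rows <- length(p_idx)
  b <- stats::rnorm(n_pep_rows, 0, truth$sigma_pep)

  # expand to peptide x sample grid
  row_p <- rep(p_idx, each = n_s)
  row_j <- rep(j_pep, each = n_s)
  row_b <- rep(b, each = n_s)
  row_s <- rep(seq_len(n_s), times = n_pep_rows)
  x <- pr$mu[row_p] + row_b + pr$delta[row_p] * is_mut[row_s] +
    stats::rnorm(n_pep_rows * n_s, 0, truth$sigma_e)
  x_obs <- loc[row_s] + scl[row_s] * x

  miss <- rep(FALSE, length(x_obs))
  if (truth$censor_scale > 0) {
    p_miss <- 1 / (1 + exp((x_obs - truth$censor_mid) / truth$censor_scale))
    miss <- stats::runif(length(x_obs)) < p_miss
  }
  if (truth$mcar_rate > 0)
    miss <- miss | (stats::runif(length(x_obs)) < truth$mcar_rate)
  ab <- pr$absent_in[row_p]
  miss <- miss | (!is.na(ab) & ab == "mutant" & is_mut[row_s]) |
    (!is.na(ab) & ab == "control" & !is_mut[row_s])

  peptides <- data.frame(
    protein_id = pr$protein_id[row_p],
    peptide_id = sprintf("%s_pep%02d", pr$protein_id[row_p], row_j),
    sample_id = samples[row_s],
    intensity = ifelse(miss, 0, 2^x_obs),
    is_reverse = FALSE,
    is_contaminant = FALSE,
    stringsAsFactors = FALSE)

  ann <- sample_annotation(
    data.frame(sample_id = samples,
               Knockout = ifelse(is_mut, "mutant", "control"),
               stringsAsFactors = FALSE),
    contrast = "Knockout", ref_level = "control")
  truth$sample_effects <- data.frame(sample_id = samples, loc = loc,
                                     scale = scl, stringsAsFactors = FALSE)
  list(peptides = peptides, annotation = ann, truth = truth)
}

#' Ground truth for a synthetic targeted lipid panel
#'
#' @param n_lipids Number of lipid species.
#' @param n_classes Number of lipid classes; one shared internal standard
#'   per class.
#' @param fc Per-lipid true linear fold change (mutant over control);
#'   recycled to `n_lipids`. Must be > 0.
#' @param bio_cv Per-lipid biological coefficient of variation of sample
#'   areas (fractional, e.g. 0.2); recycled.
#' @param qc_cv Per-lipid CV of the QC replicate areas (fractional);
#'   recycled.
#' @param is_cv CV of internal-standard areas.
#' @param sample_scale_sd Sd of log per-sample injection scale factors.
#' @param base_mean_log,base_sd_log Mean and sd of log10 base peak areas.
#' @param seed Integer seed.
#' @return Object of class `"synthetic_lipid_truth"` with a `lipids` data
#'   frame (`lipid_id`, `class`, `is_id`, `fc`, `bio_cv`, `qc_cv`,
#'   `base_area`) and generator parameters.
#' @export
lipid_truth <- function(n_lipids = 50L, n_classes = 5L, fc = 1,
                        bio_cv = 0.2, qc_cv = 0.1, is_cv = 0.02,
                        sample_scale_sd = 0.2,
                        base_mean_log = 5, base_sd_log = 0.5,
                        seed = 20220311L) {
  stopifnot(n_lipids >= 1, n_classes >= 1, all(fc > 0),
            all(bio_cv >= 0), all(qc_cv >= 0), is_cv >= 0)
  set.seed(seed)
  cls <- sprintf("CL%d", ((seq_len(n_lipids) - 1L) %% n_classes) + 1L)
  lipids <- data.frame(
    lipid_id = sprintf("LIP%03d", seq_len(n_lipids)),
    class = cls,
    is_id = paste0("IS_", cls),
    fc = rep_len(fc, n_lipids),
    bio_cv = rep_len(bio_cv, n_lipids),
    qc_cv = rep_len(qc_cv, n_lipids),
    base_area = 10^stats::rnorm(n_lipids, base_mean_log, base_sd_log),
    stringsAsFactors = FALSE)
  structure(
    list(lipids = lipids, is_cv = is_cv, sample_scale_sd = sample_scale_sd,
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "synthetic_lipid_truth")
}

#' Simulate a targeted lipid panel with internal standards and QC series
#'
#' Sample peak areas follow
#' `area = scale_i * base * FC^{1[mutant]} * lognormal(cv)`; internal
#' standards share the per-sample injection scale. The QC dilution series
#' is generated at the five levels 1x, 0.8x, 0.5x, 0.2x and 0.1x in
#' triplicate with each lipid's stated QC coefficient of variation.
#'
#' @param truth A [lipid_truth()] object.
#' @param n_control,n_mutant Samples per condition (default 15 vs 13, the
#'   outer-segment lipidomics design).
#' @return A [lipid_panel()] object; the realized sample scale factors are
#'   attached as attribute `"sample_scales"`.
#' @export
simulate_lipid_panel <- function(truth, n_control = 15L, n_mutant = 13L) {
  stopifnot(inherits(truth, "synthetic_lipid_truth"))
  set.seed(truth$seed + 2L)
  li <- truth$lipids
  n_l <- nrow(li)
  samples <- c(sprintf("ctrl_%02d", seq_len(n_control)),
               sprintf("mut_%02d", seq_len(n_mutant)))
  is_mut <- rep(c(FALSE, TRUE), c(n_control, n_mutant))
  n_s <- length(samples)
  scl <- exp(stats::rnorm(n_s, 0, truth$sample_scale_sd))
  is_ids <- unique(li$is_id)
  is_base <- stats::setNames(10^stats::rnorm(length(is_ids), 5, 0.2), is_ids)
  sdlog <- function(cv) sqrt(log(1 + cv^2))

  row_l <- rep(seq_len(n_l), each = n_s)
  row_s <- rep(seq_len(n_s), times = n_l)
  areas <- data.frame(
    lipid_id = li$lipid_id[row_l],
    sample_id = samples[row_s],
    area = scl[row_s] * li$base_area[row_l] *
      ifelse(is_mut[row_s], li$fc[row_l], 1) *
      stats::rlnorm(n_l * n_s, 0, sdlog(li$bio_cv[row_l])),
    stringsAsFactors = FALSE)
  is_areas <- data.frame(
    is_id = rep(is_ids, each = n_s),
    sample_id = rep(samples, times = length(is_ids)),
    area = rep(scl, times = length(is_ids)) *
      rep(is_base, each = n_s) *
      stats::rlnorm(length(is_ids) * n_s, 0, sdlog(truth$is_cv)),
    stringsAsFactors = FALSE)

  levels <- c("1x", "0.8x", "0.5x", "0.2x", "0.1x")
  lev_frac <- c(1, 0.8, 0.5, 0.2, 0.1)
  grid <- expand.grid(rep = 1:3, lev = seq_along(levels),
                      lip = seq_len(n_l), KEEP.OUT.ATTRS = FALSE)
  qc <- data.frame(
    lipid_id = li$lipid_id[grid$lip],
    level = levels[grid$lev],
    replicate = grid$rep,
    area = lev_frac[grid$lev] * li$base_area[grid$lip] *
      stats::rlnorm(nrow(grid), 0, sdlog(li$qc_cv[grid$lip])),
    stringsAsFactors = FALSE)
  gridi <- expand.grid(rep = 1:3, lev = seq_along(levels),
                       is = seq_along(is_ids), KEEP.OUT.ATTRS = FALSE)
  qc_is <- data.frame(
    is_id = is_ids[gridi$is],
    level = levels[gridi$lev],
    replicate = gridi$rep,
    area = lev_frac[gridi$lev] * is_base[gridi$is] *
      stats::rlnorm(nrow(gridi), 0, sdlog(truth$is_cv)),
    stringsAsFactors = FALSE)

  panel <- lipid_panel(lipids = li[, c("lipid_id", "class", "is_id")],
                       areas = areas, is_areas = is_areas,
                       qc = qc, qc_is = qc_is)
  attr(panel, "sample_scales") <- data.frame(
    sample_id = samples, scale = scl,
    condition = ifelse(is_mut, "mutant", "control"),
    stringsAsFactors = FALSE)
  attr(panel, "truth") <- truth
  panel
}

#' Write the hand-computable worked fixture files
#'
#' Writes the small toy datasets used by the worked examples (peptide
#' table parsing, pseudo fold-change pool, pooled-t values, two-stage FDR
#' p-vector, QC CV replicates) to a directory, each with a plain-text
#' sidecar recording its expected outputs and the oracle used. Content is
#' fully deterministic, so regeneration is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_worked_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, lines) {
    path <- file.path(dir, name)
    con <- file(path, open = "wb")  # LF endings everywhere, byte-stable
    writeLines(lines, con, sep = "\n")
    close(con)
    path
  }
  paths <- c(
    w("peptides_toy.txt", c(
      "Sequence\tProteins\tReverse\tPotential contaminant\tIntensity A\tIntensity B",
      "AAAAK\tP1\t\t\t1024\t2048",
      "CCCCK\tP1;P2\t\t\t512\t0",
      "DDDDK\tP3\t\t\t256\t128")),
    w("peptides_toy.expected.txt", c(
      "oracle: direct hand parse of the 3-row table",
      "records: 6 (3 peptides x 2 samples), 0 flagged",
      "protein group of CCCCK kept verbatim as 'P1;P2'",
      "empty/zero intensity cells parse as 0 (not detected)")),
    w("peptides_toy_rev.txt", c(
      "Sequence\tProteins\tReverse\tPotential contaminant\tIntensity A\tIntensity B",
      "AAAAK\tP1\t\t\t1024\t2048",
      "CCCCK\tP1;P2\t\t\t512\t0",
      "DDDDK\tP3\t\t\t256\t128",
      "EEEEK\tREV__P4\t+\t\t64\t32")),
    w("peptides_toy_rev.expected.txt", c(
      "oracle: hand parse; row EEEEK is a reverse decoy (Reverse = '+')",
      "default read drops the decoy: 6 records remain, flagged copy has 8")),
    w("annotation_toy.csv", c(
      "sample_id,Knockout",
      paste0("ctrl_", 1:4, ",control"),
      paste0("mut_", 1:4, ",mutant"))),
    w("annotation_toy.expected.txt", c(
      "oracle: by construction",
      "8 samples, contrast Knockout with levels control (n=4) / mutant (n=4)")),
    w("bky_pvector.txt", c("0.001", "0.01", "0.3", "0.9")),
    w("bky_pvector.expected.txt", c(
      "oracle: hand-traced two-stage step-up at q = 0.05",
      "stage-1 level q/(1+q) = 0.047619 -> r1 = 2 rejections",
      "stage-2 level 0.047619 * 4 / 2 = 0.095238 -> discoveries {0.001, 0.01}")),
    w("pseudo_pool_toy.csv", c(
      "peptide_id,condition,mean_t",
      paste0("obs_pep", 1:2, ",A,", c(10, 12)),
      paste0("pool_pep", 1:10, ",B,", 6:15))),
    w("pseudo_pool_toy.expected.txt", c(
      "oracle: brute-force enumeration of the imputation rule",
      "pool for missing condition B = {6..15}, N = 10, ceil(0.1*10) = 1",
      "imputation value = mean of 1 smallest = 6.0",
      "peptide FCs = {10-6, 12-6} = {4, 6}; protein log2 FC = median = 5.0")),
    w("qc_cv_toy.csv", c(
      "lipid_id,replicate,ratio",
      paste0("LIP_OK,", 1:3, ",", c(90, 100, 110)),
      paste0("LIP_BAD,", 1:3, ",", c(10, 100, 190)))),
    w("qc_cv_toy.expected.txt", c(
      "oracle: CV% = 100 * sd/mean with the n-1 standard deviation",
      "LIP_OK: mean 100, sd 10 -> CV 10% -> retained (< 30)",
      "LIP_BAD: mean 100, sd 90 -> CV 90% -> removed")),
    w("pooled_t_toy.csv", c(
      "group,value",
      paste0("a,", 1:3),
      paste0("b,", 2:4))),
    w("pooled_t_toy.expected.txt", c(
      "oracle: closed-form pooled-variance t, checked against the t CDF",
      "sp^2 = 1, se = sqrt(2/3) = 0.8165, t = -1.2247, df = 4, p = 0.2878")))
  invisible(paths)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  pr <- x$proteins
  cat(sprintf("Synthetic peptide-level truth: %d proteins (%d non-null)\n",
              nrow(pr), sum(pr$delta != 0)))
  cat(sprintf("  sigma_pep = %g, sigma_e = %g, seed = %d\n",
              x$sigma_pep, x$sigma_e, x$seed))
  cat(sprintf("  censoring: mid %g scale %g; MCAR %g; absent sets %d/%d\n",
              x$censor_mid, x$censor_scale, x$mcar_rate,
              sum(!is.na(pr$absent_in) & pr$absent_in == "mutant"),
              sum(!is.na(pr$absent_in) & pr$absent_in == "control")))
  invisible(x)
}
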