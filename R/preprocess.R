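#' Drop undetected records and log2-transform intensities
#'
#' Raw label-free intensities of zero mean "not detected" and are removed
#' rather than imputed; the remaining intensities are log2 transformed.
#'
#' @param table Data frame with a numeric `intensity` column (raw scale,
#'   >= 0); typically a peptide table from [read_peptides()] or a protein
#'   table from [read_protein_groups()].
#' @return The same table with zero-intensity records removed and a new
#'   `t_intensity` column holding `log2(intensity)`.
#' @export
log2_transform_nonzero <- function(table) {
  stopifnot(is.data.frame(table), "intensity" %in% names(table))
  if (any(table$intensity < 0)) stop("intensities must be >= 0")
  out <- table[table$intensity > 0, , drop = FALSE]
  out$t_intensity <- log2(out$intensity)
  rownames(out) <- NULL
  out
}

#' Robust z-score normalization across samples
#'
#' Removes systematic per-sample location and scale differences by the
#' robust z-score: for each sample, `z = (x - median) / (1.4826 * MAD)`,
#' computed over that sample's observed values. With `rescale = TRUE` (the
#' "modified" variant) the z-scores are mapped back onto a pooled
#' log2-intensity scale,
#' `z * mean(1.4826 * MAD_s) + mean(median_s)` (means over samples), so
#' that downstream smallest-intensity imputation operates on a common
#' intensity-like scale.
#'
#' @param table Data frame with `sample_id` and `t_intensity` columns
#'   (log2 scale, zeros already removed).
#' @param rescale Map normalized values back onto the pooled intensity
#'   scale. Default `TRUE`.
#' @return The table with `t_intensity` replaced by its normalized value.
#'   Attribute `"norm_constants"` records the per-sample median and scaled
#'   MAD used plus the rescale constants.
#' @details A sample whose scaled MAD is zero (a constant sample) is a
#'   degenerate input and raises an error naming the sample. Each sample
#'   must contribute at least two observed values.
#' @export
robust_z_normalize <- function(table, rescale = TRUE) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "t_intensity") %in% names(table)))
  sp <- split(table$t_intensity, table$sample_id)
  n_obs <- vapply(sp, length, integer(1))
  if (any(n_obs < 2L))
    stop("samples with fewer than 2 observed values: ",
         paste(names(sp)[n_obs < 2L], collapse = ", "))
  med <- vapply(sp, stats::median, numeric(1))
  smad <- vapply(sp, stats::mad, numeric(1)) # constant = 1.4826
  if (any(smad == 0))
    stop("zero MAD (constant sample): ",
         paste(names(sp)[smad == 0], collapse = ", "))
  i <- match(table$sample_id, names(sp))
  z <- (table$t_intensity - med[i]) / smad[i]
  a <- mean(smad)
  b <- mean(med)
  out <- table
  out$t_intensity <- if (rescale) z * a + b else z
  attr(out, "norm_constants") <- list(
    sample_id = names(sp), median = unname(med), scaled_mad = unname(smad),
    rescale = rescale, rescale_scale = if (rescale) a else 1,
    rescale_center = if (rescale) b else 0)
  out
}

#' Filter proteins by peptide support
#'
#' Keeps only proteins supported by at least `min_peptides` distinct
#' peptides. On peptide-level tables, distinct `peptide_id`s per
#' `protein_id` are counted over the whole table; on protein-level tables
#' carrying an `n_peptides` column, that count is used directly.
#'
#' @param table Data frame with `protein_id` and either `peptide_id` or
#'   `n_peptides`.
#' @param min_peptides Minimum number of distinct peptides. Default 2.
#' @return The filtered table (all records of failing proteins removed).
#' @export
filter_min_peptides <- function(table, min_peptides = 2L) {
  stopifnot(is.data.frame(table), "protein_id" %in% names(table),
            min_peptides >= 0)
  if ("n_peptides" %in% names(table)) {
    keep <- table$n_peptides >= min_peptides
  } else if ("peptide_id" %in% names(table)) {
    counts <- tapply(table$peptide_id, table$protein_id,
                     function(x) length(unique(x)))
    keep <- counts[match(table$protein_id, names(counts))] >= min_peptides
  } else {
    stop("table must have a peptide_id or n_peptides column")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter proteins by missing-value count
#'
#' Removes proteins with more than `max_missing` missing sample values,
#' where missing means "no positive intensity recorded for that sample"
#' (absent row or intensity 0).
#'
#' @param table Protein-level data frame with `protein_id`, `sample_id`
#'   and `intensity`.
#' @param max_missing Maximum tolerated missing values per protein across
#'   all samples. Default 4.
#' @param samples Character vector of all sample ids in the experiment;
#'   defaults to the samples present in the table.
#' @return The filtered table.
#' @export
filter_max_missing <- function(table, max_missing = 4L,
                               samples = unique(table$sample_id)) {
  stopifnot(is.data.frame(table),
            all(c("protein_id", "sample_id", "intensity") %in% names(table)),
            max_missing >= 0)
  obs <- table[table$intensity > 0, c("protein_id", "sample_id")]
  n_obs <- tapply(obs$sample_id, obs$protein_id,
                  function(x) length(unique(x)))
  n_missing <- length(samples) - n_obs
  prot <- unique(table$protein_id)
  miss <- n_missing[match(prot, names(n_missing))]
  miss[is.na(miss)] <- length(samples) # protein never observed
  keep_prot <- prot[miss <= max_missing]
  out <- table[table$protein_id %in% keep_prot, , drop = FALSE]
  rownames(out) <- NULL
  out
}
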