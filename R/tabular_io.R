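#' Read a MaxQuant-style peptides.txt table into long format
#'
#' Parses the tab-separated peptide report dialect written by MaxQuant:
#' one row per peptide with `Sequence` and `Proteins` columns, per-sample
#' intensity columns identified by a prefix (default `"Intensity "`), and
#' decoy/contaminant marker columns (`Reverse`, `Potential contaminant`,
#' marked with `"+"`; accessions prefixed `REV__`/`CON__`).
#'
#' The `Proteins` cell may list several accessions joined by `";"`; the
#' full group string is kept as the protein identifier (razor-group
#' convention, no parsimony resolution).
#'
#' @param path Path to the tab-separated file (header row required).
#' @param intensity_prefix Prefix identifying per-sample intensity
#'   columns; the sample id is the remainder of the column name.
#' @param peptide_col,protein_col Column names holding the peptide
#'   sequence and the protein group string.
#' @param remove_flagged Drop reverse-decoy and contaminant records from
#'   the returned table (default `TRUE`). Flags are always computed.
#' @return A long-format data frame with columns `protein_id`,
#'   `peptide_id`, `sample_id`, `intensity`, `is_reverse`,
#'   `is_contaminant`. Empty intensity cells parse as 0 (not detected).
#' @export
read_peptides <- function(path, intensity_prefix = "Intensity ",
                          peptide_col = "Sequence", protein_col = "Proteins",
                          remove_flagged = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in c(peptide_col, protein_col))
    if (!col %in% names(raw)) stop("missing required column: ", col)
  int_cols <- names(raw)[startsWith(names(raw), intensity_prefix) &
                           nchar(names(raw)) > nchar(intensity_prefix)]
  if (!length(int_cols))
    stop("no intensity columns found with prefix '", intensity_prefix, "'")
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)

  protein <- as.character(raw[[protein_col]])
  peptide <- as.character(raw[[peptide_col]])
  rev_flag <- flag_column(raw, "Reverse") | startsWith(protein, "REV__")
  con_flag <- flag_column(raw, "Potential contaminant") |
    flag_column(raw, "Contaminant") | startsWith(protein, "CON__")

  n <- nrow(raw)
  out <- data.frame(
    protein_id = rep(protein, times = length(samples)),
    peptide_id = rep(peptide, times = length(samples)),
    sample_id = rep(samples, each = n),
    intensity = unlist(lapply(int_cols, function(cl) {
      v <- suppressWarnings(as.numeric(raw[[cl]]))
      v[is.na(v)] <- 0
      v
    }), use.names = FALSE),
    is_reverse = rep(rev_flag, times = length(samples)),
    is_contaminant = rep(con_flag, times = length(samples)),
    stringsAsFactors = FALSE)

  key <- paste(out$protein_id, out$peptide_id, out$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (protein, peptide, sample) keys: ",
         paste(gsub("\r", " / ", utils::head(dup, 5L)), collapse = "; "))
  }
  pep_map <- unique(out[, c("protein_id", "peptide_id")])
  if (anyDuplicated(pep_map$peptide_id))
    stop("peptide mapped to more than one protein group: ",
         paste(unique(pep_map$peptide_id[duplicated(pep_map$peptide_id)]),
               collapse = ", "))
  if (remove_flagged)
    out <- out[!(out$is_reverse | out$is_contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

flag_column <- function(raw, name) {
  if (name %in% names(raw)) {
    v <- as.character(raw[[name]])
    !is.na(v) & v == "+"
  } else rep(FALSE, nrow(raw))
}

#' Read a MaxQuant-style proteinGroups.txt table into long format
#'
#' @param path Path to the tab-separated file.
#' @param intensity_prefix Prefix of per-sample intensity columns.
#' @param id_col Column holding the protein group accession string.
#' @param peptides_col Column holding the peptide count per protein.
#' @param remove_flagged Drop reverse/contaminant protein groups.
#' @return Long-format data frame with columns `protein_id`, `sample_id`,
#'   `intensity`, `n_peptides`, `is_reverse`, `is_contaminant`.
#' @export
read_protein_groups <- function(path, intensity_prefix = "Intensity ",
                                id_col = "Protein IDs",
                                peptides_col = "Peptides",
                                remove_flagged = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in c(id_col, peptides_col))
    if (!col %in% names(raw)) stop("missing required column: ", col)
  int_cols <- names(raw)[startsWith(names(raw), intensity_prefix) &
                           nchar(names(raw)) > nchar(intensity_prefix)]
  if (!length(int_cols))
    stop("no intensity columns found with prefix '", intensity_prefix, "'")
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  protein <- as.character(raw[[id_col]])
  if (anyDuplicated(protein))
    stop("duplicate protein ids: ",
         paste(unique(protein[duplicated(protein)]), collapse = ", "))
  rev_flag <- flag_column(raw, "Reverse") | startsWith(protein, "REV__")
  con_flag <- flag_column(raw, "Potential contaminant") |
    flag_column(raw, "Contaminant") | startsWith(protein, "CON__")
  n <- nrow(raw)
  out <- data.frame(
    protein_id = rep(protein, times = length(samples)),
    sample_id = rep(samples, each = n),
    intensity = unlist(lapply(int_cols, function(cl) {
      v <- suppressWarnings(as.numeric(raw[[cl]]))
      v[is.na(v)] <- 0
      v
    }), use.names = FALSE),
    n_peptides = rep(as.integer(raw[[peptides_col]]), times = length(samples)),
    is_reverse = rep(rev_flag, times = length(samples)),
    is_contaminant = rep(con_flag, times = length(samples)),
    stringsAsFactors = FALSE)
  if (remove_flagged)
    out <- out[!(out$is_reverse | out$is_contaminant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample-annotation table
#'
#' Reads a CSV or TSV file mapping sample ids to experimental factors and
#' validates the designated contrast factor.
#'
#' @param path File path; tab-separated if the first line contains a tab,
#'   comma-separated otherwise.
#' @param contrast Name of the two-level contrast factor column (for
#'   example `"Knockout"`).
#' @param ref_level Reference (control) level of the contrast factor.
#'   Default: the first level in sort order.
#' @return A data frame with a `sample_id` column and one column per
#'   factor; attributes `"contrast"` and `"ref_level"` record the design.
#' @export
read_sample_annotation <- function(path, contrast, ref_level = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  ann <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ann)) stop("annotation needs a sample_id column")
  sample_annotation(ann, contrast = contrast, ref_level = ref_level)
}

#' Construct and validate a sample annotation
#'
#' @param ann Data frame with `sample_id` plus factor columns.
#' @param contrast Two-level contrast factor column name.
#' @param ref_level Reference (control) level; default first in sort order.
#' @return Validated annotation data frame with `"contrast"` and
#'   `"ref_level"` attributes.
#' @export
sample_annotation <- function(ann, contrast, ref_level = NULL) {
  stopifnot(is.data.frame(ann), "sample_id" %in% names(ann))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in annotation")
  if (!contrast %in% names(ann))
    stop("contrast factor '", contrast, "' not in annotation")
  lev <- sort(unique(as.character(ann[[contrast]])))
  if (length(lev) != 2L)
    stop("contrast factor '", contrast, "' must have exactly 2 levels, has ",
         length(lev))
  if (is.null(ref_level)) ref_level <- lev[1L]
  if (!ref_level %in% lev) stop("ref_level '", ref_level, "' not a level")
  if (any(table(ann[[contrast]]) < 1L))
    stop("each contrast level needs at least one sample")
  attr(ann, "contrast") <- contrast
  attr(ann, "ref_level") <- ref_level
  ann
}

# Checks that every data sample is annotated (hard error) and warns about
# annotated samples absent from the data.
check_annotation_coverage <- function(sample_ids, annotation) {
  sample_ids <- unique(sample_ids)
  missing <- setdiff(sample_ids, annotation$sample_id)
  if (length(missing))
    stop("samples present in data but absent from annotation: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(annotation$sample_id, sample_ids)
  if (length(extra))
    warning("annotated samples not present in data: ",
            paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Write differential-abundance results to a tab-separated file
#'
#' Writes the results table of a [da_fit] object (or a plain results data
#' frame) with a deterministic column order, rows ordered by feature id,
#' and floats serialized at full precision so that a write/read round trip
#' reproduces the values bit-identically.
#'
#' @param results A `da_fit` object or its results data frame.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path) {
  df <- if (inherits(results, "da_fit")) results$results else results
  stopifnot(is.data.frame(df))
  lead <- intersect(
    c("feature_id", "log2_fc", "fc_signed", "se", "df", "p", "adj_p",
      "method", "n_peptides", "n_obs", "category"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  if (nrow(df)) df <- df[order(df$feature_id), , drop = FALSE]
  ser <- df
  for (cl in names(ser)) {
    if (is.numeric(ser[[cl]]) && !is.integer(ser[[cl]]))
      ser[[cl]] <- ifelse(is.na(ser[[cl]]), NA,
                          sprintf("%.17g", ser[[cl]]))
    if (is.factor(ser[[cl]])) ser[[cl]] <- as.character(ser[[cl]])
  }
  ok <- tryCatch({
    utils::write.table(ser, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to '", path, "'")
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path File path.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  num_cols <- intersect(c("log2_fc", "fc_signed", "se", "df", "p", "adj_p"),
                        names(df))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}
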