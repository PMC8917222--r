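#' Construct a targeted-lipidomics panel
#'
#' Bundles the components of a targeted lipid experiment: the lipid
#' catalogue with its internal-standard (IS) assignment, per-sample peak
#' areas of lipids and internal standards, and the QC dilution series
#' (levels 1x, 0.8x, 0.5x, 0.2x, 0.1x measured in triplicate).
#'
#' @param lipids Data frame `lipid_id`, `class`, `is_id` (exactly one
#'   internal standard per lipid).
#' @param areas Data frame `lipid_id`, `sample_id`, `area` (>= 0).
#' @param is_areas Data frame `is_id`, `sample_id`, `area`.
#' @param qc Data frame `lipid_id`, `level`, `replicate`, `area`; may be
#'   `NULL` when no QC series was acquired.
#' @param qc_is Data frame `is_id`, `level`, `replicate`, `area`.
#' @return Object of class `"lipid_panel"`.
#' @export
lipid_panel <- function(lipids, areas, is_areas, qc = NULL, qc_is = NULL) {
  stopifnot(is.data.frame(lipids),
            all(c("lipid_id", "class", "is_id") %in% names(lipids)),
            all(c("lipid_id", "sample_id", "area") %in% names(areas)),
            all(c("is_id", "sample_id", "area") %in% names(is_areas)))
  if (anyDuplicated(lipids$lipid_id))
    stop("duplicate lipid ids in catalogue")
  if (any(areas$area < 0) || any(is_areas$area < 0))
    stop("peak areas must be >= 0")
  unknown <- setdiff(areas$lipid_id, lipids$lipid_id)
  if (length(unknown))
    stop("areas for lipids not in catalogue: ",
         paste(unknown, collapse = ", "))
  if (!is.null(qc))
    stopifnot(all(c("lipid_id", "level", "replicate", "area") %in% names(qc)))
  if (!is.null(qc_is))
    stopifnot(all(c("is_id", "level", "replicate", "area") %in% names(qc_is)))
  structure(list(lipids = lipids, areas = areas, is_areas = is_areas,
                 qc = qc, qc_is = qc_is),
            class = "lipid_panel")
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat(sprintf("Lipid panel: %d species, %d classes, %d internal standards\n",
              nrow(x$lipids), length(unique(x$lipids$class)),
              length(unique(x$lipids$is_id))))
  cat(sprintf("  samples: %d; QC series: %s\n",
              length(unique(x$areas$sample_id)),
              if (is.null(x$qc)) "none"
              else sprintf("%d levels x %d replicates",
                           length(unique(x$qc$level)),
                           length(unique(x$qc$replicate)))))
  invisible(x)
}

#' Read a lipid panel from a long-format CSV
#'
#' The file has one row per measured area with columns `lipid_id`,
#' `class`, `is_id`, `sample_id`, `qc_level`, `replicate`, `area`.
#' Internal-standard rows carry their own id in both `lipid_id` and
#' `is_id`; QC dilution rows have a non-empty `qc_level` (e.g. `"1x"`)
#' and `replicate`, study-sample rows a non-empty `sample_id`. A
#' Skyline-style transition report reduces to this layout by mapping
#' Molecule/Molecule List/peak area onto `lipid_id`/`class`/`area`.
#'
#' @param path CSV file path.
#' @return A [lipid_panel()].
#' @seealso [write_lipid_panel()]
#' @export
read_lipid_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("lipid_id", "class", "is_id", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- NA_character_
  if (!"qc_level" %in% names(df)) df$qc_level <- NA_character_
  if (!"replicate" %in% names(df)) df$replicate <- NA_integer_
  is_std <- df$lipid_id == df$is_id
  is_qc <- !is.na(df$qc_level)
  cat_rows <- df[!is_std, c("lipid_id", "class", "is_id")]
  lipids <- unique(cat_rows)
  areas <- df[!is_std & !is_qc, c("lipid_id", "sample_id", "area")]
  is_areas <- df[is_std & !is_qc, c("is_id", "sample_id", "area")]
  qc <- df[!is_std & is_qc, c("lipid_id", "qc_level", "replicate", "area")]
  names(qc)[2] <- "level"
  qc_is <- df[is_std & is_qc, c("is_id", "qc_level", "replicate", "area")]
  names(qc_is)[2] <- "level"
  rownames(lipids) <- rownames(areas) <- rownames(is_areas) <- NULL
  rownames(qc) <- rownames(qc_is) <- NULL
  lipid_panel(lipids, areas, is_areas,
              qc = if (nrow(qc)) qc else NULL,
              qc_is = if (nrow(qc_is)) qc_is else NULL)
}

#' Write a lipid panel to the long-format CSV layout
#'
#' @param panel A [lipid_panel()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_lipid_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lipid_panel"))
  row_of <- function(lipid_id, class, is_id, sample_id, qc_level,
                     replicate, area)
    data.frame(lipid_id = lipid_id, class = class, is_id = is_id,
               sample_id = sample_id, qc_level = qc_level,
               replicate = replicate, area = area, stringsAsFactors = FALSE)
  li <- panel$lipids
  idx <- match(panel$areas$lipid_id, li$lipid_id)
  parts <- list(
    row_of(panel$areas$lipid_id, li$class[idx], li$is_id[idx],
           panel$areas$sample_id, NA, NA, panel$areas$area),
    row_of(panel$is_areas$is_id, NA, panel$is_areas$is_id,
           panel$is_areas$sample_id, NA, NA, panel$is_areas$area))
  if (!is.null(panel$qc)) {
    idx <- match(panel$qc$lipid_id, li$lipid_id)
    parts <- c(parts, list(
      row_of(panel$qc$lipid_id, li$class[idx], li$is_id[idx], NA,
             panel$qc$level, panel$qc$replicate, panel$qc$area)))
  }
  if (!is.null(panel$qc_is))
    parts <- c(parts, list(
      row_of(panel$qc_is$is_id, NA, panel$qc_is$is_id, NA,
             panel$qc_is$level, panel$qc_is$replicate, panel$qc_is$area)))
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Internal-standard ratio quantification
#'
#' Divides each lipid's peak area by the area of its assigned internal
#' standard in the same sample. A zero lipid area gives ratio 0 (not
#' detected); a missing or non-positive internal-standard area makes the
#' cell invalid.
#'
#' @param panel A [lipid_panel()].
#' @return Long data frame `lipid_id`, `sample_id`, `ratio`, `valid`.
#'   Invalid cells carry `ratio = NA` and are reported with a warning.
#' @export
is_ratio_quantify <- function(panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  ar <- panel$areas
  is_id <- panel$lipids$is_id[match(ar$lipid_id, panel$lipids$lipid_id)]
  key <- paste(is_id, ar$sample_id, sep = "\r")
  is_key <- paste(panel$is_areas$is_id, panel$is_areas$sample_id, sep = "\r")
  denom <- panel$is_areas$area[match(key, is_key)]
  valid <- !is.na(denom) & denom > 0
  out <- data.frame(lipid_id = ar$lipid_id, sample_id = ar$sample_id,
                    ratio = ifelse(valid, ar$area / denom, NA_real_),
                    valid = valid, stringsAsFactors = FALSE)
  if (any(!valid))
    warning(sum(!valid), " lipid/sample cells have a missing or zero ",
            "internal-standard area and were marked invalid")
  out
}

#' QC dilution-series coefficient-of-variation filter
#'
#' Computes, per lipid and QC level, the CV% (`100 * sd / mean`, sample
#' standard deviation) of the triplicate internal-standard ratios, and
#' retains a lipid when its CV% at the decision level is below the
#' threshold (default 30%, the reporting rule for the panel).
#'
#' @param panel A [lipid_panel()] with a QC series.
#' @param cv_threshold Retention threshold in percent; strict `<`.
#' @param level Decision level. Default `"1x"` (undiluted pooled QC).
#' @param all_levels Require the CV criterion at every QC level instead
#'   of the decision level only.
#' @return Object of class `"lipid_qc_report"`: list with `cv` (long data
#'   frame `lipid_id`, `level`, `cv`, `n_replicates`), `report` (per lipid:
#'   decision-level CV, `retained`, `reason`), `cv_threshold`, `level`.
#' @export
qc_cv_filter <- function(panel, cv_threshold = 30, level = "1x",
                         all_levels = FALSE) {
  stopifnot(inherits(panel, "lipid_panel"), cv_threshold > 0)
  if (is.null(panel$qc)) stop("panel has no QC series")
  qc <- panel$qc
  is_id <- panel$lipids$is_id[match(qc$lipid_id, panel$lipids$lipid_id)]
  if (!is.null(panel$qc_is)) {
    key <- paste(is_id, qc$level, qc$replicate, sep = "\r")
    is_key <- paste(panel$qc_is$is_id, panel$qc_is$level,
                    panel$qc_is$replicate, sep = "\r")
    denom <- panel$qc_is$area[match(key, is_key)]
    ratio <- ifelse(!is.na(denom) & denom > 0, qc$area / denom, NA_real_)
  } else {
    ratio <- qc$area  # ratios supplied directly
  }
  grp <- interaction(qc$lipid_id, qc$level, drop = TRUE)
  agg <- data.frame(
    lipid_id = tapply(qc$lipid_id, grp, `[`, 1L),
    level = tapply(qc$level, grp, `[`, 1L),
    cv = as.numeric(tapply(ratio, grp, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2L) NA_real_ else 100 * stats::sd(r) / mean(r)
    })),
    n_replicates = as.integer(tapply(ratio, grp, function(r) sum(!is.na(r)))),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL

  lip <- panel$lipids$lipid_id
  if (all_levels) {
    dec <- tapply(agg$cv, agg$lipid_id, function(v) max(v))
    n_min <- tapply(agg$n_replicates, agg$lipid_id, min)
  } else {
    at <- agg[agg$level == level, ]
    dec <- stats::setNames(at$cv, at$lipid_id)[lip]
    n_min <- stats::setNames(at$n_replicates, at$lipid_id)[lip]
  }
  dec <- as.numeric(dec[lip])
  n_min <- as.integer(n_min[lip])
  n_min[is.na(n_min)] <- 0L
  insufficient <- is.na(dec) | n_min < 2L
  report <- data.frame(
    lipid_id = lip,
    cv = dec,
    retained = !insufficient & dec < cv_threshold,
    reason = ifelse(insufficient, "insufficient QC",
                    ifelse(dec < cv_threshold, "", "CV above threshold")),
    stringsAsFactors = FALSE)
  structure(list(cv = agg, report = report, cv_threshold = cv_threshold,
                 level = if (all_levels) "all" else level),
            class = "lipid_qc_report")
}

#' @export
print.lipid_qc_report <- function(x, ...) {
  cat(sprintf("QC CV filter at %g%% (decision level %s): %d/%d retained\n",
              x$cv_threshold, x$level, sum(x$report$retained),
              nrow(x$report)))
  invisible(x)
}

#' Median normalization of internal-standard ratios
#'
#' Divides each sample's ratios by that sample's median positive ratio,
#' removing any residual per-sample scale factor; after normalization the
#' median of positive values in every sample is exactly 1.
#'
#' @param ratios Long data frame `lipid_id`, `sample_id`, `ratio` (from
#'   [is_ratio_quantify()]); zeros are kept as zeros, `NA`s pass through.
#' @return The table with `ratio` normalized.
#' @export
median_normalize <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("lipid_id", "sample_id", "ratio") %in% names(ratios)))
  sp <- split(ratios$ratio, ratios$sample_id)
  med <- vapply(sp, function(r) {
    r <- r[!is.na(r) & r > 0]
    if (!length(r)) NA_real_ else stats::median(r)
  }, numeric(1))
  if (anyNA(med))
    stop("samples with no positive ratio: ",
         paste(names(med)[is.na(med)], collapse = ", "))
  out <- ratios
  out$ratio <- ratios$ratio / med[match(ratios$sample_id, names(med))]
  out
}

#' Per-lipid differential abundance
#'
#' Two-sided pooled-variance t-test per lipid on log2-transformed
#' median-normalized ratios (zeros treated as missing), with the fold
#' change as the mutant-minus-control difference of log2 means.
#' Benjamini-Hochberg adjusted p-values are reported alongside; the
#' `significant` flag follows the volcano convention on the raw p-value
#' (`p < p_cut` and `|log2_fc| >= log2(fc_cut)`).
#'
#' @param ratios Normalized long ratio table (`lipid_id`, `sample_id`,
#'   `ratio`).
#' @param annotation A [sample_annotation()] whose contrast factor
#'   separates control and mutant samples.
#' @param p_cut,fc_cut Significance and linear fold-change cut-offs
#'   (defaults 0.05 and 2).
#' @return Object of class `c("lipid_da", "da_fit")`: list with `results`
#'   (per lipid: `feature_id`, `log2_fc`, `fc_signed`, means, `se`, `df`,
#'   `p`, `adj_p`, `significant`, observation counts) and `skipped`.
#' @export
lipid_da <- function(ratios, annotation, p_cut = 0.05, fc_cut = 2) {
  stopifnot(is.data.frame(ratios))
  contrast <- attr(annotation, "contrast")
  ref <- attr(annotation, "ref_level")
  if (is.null(contrast)) stop("annotation lacks a contrast attribute")
  check_annotation_coverage(ratios$sample_id, annotation)
  cond <- annotation[[contrast]][match(ratios$sample_id,
                                       annotation$sample_id)]
  is_mut <- cond != ref
  obs <- !is.na(ratios$ratio) & ratios$ratio > 0
  lv <- log2(ratios$ratio)

  lipids <- unique(ratios$lipid_id)
  rows <- vector("list", length(lipids))
  skip <- list()
  for (k in seq_along(lipids)) {
    sel <- ratios$lipid_id == lipids[k] & obs
    a <- lv[sel & is_mut]   # mutant
    b <- lv[sel & !is_mut]  # control
    if (length(a) < 2L || length(b) < 2L) {
      skip[[length(skip) + 1L]] <- data.frame(
        feature_id = lipids[k],
        reason = "detected in fewer than 2 samples of a group",
        stringsAsFactors = FALSE)
      next
    }
    tt <- pooled_t_test(a, b)
    rows[[k]] <- data.frame(
      feature_id = lipids[k], log2_fc = tt$diff,
      fc_signed = signed_fc(tt$diff),
      mean_control = tt$mean_b, mean_mutant = tt$mean_a,
      se = tt$se, df = tt$df, p = tt$p,
      n_obs_control = length(b), n_obs_mutant = length(a),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(feature_id = character(), log2_fc = numeric(),
                      fc_signed = numeric(), mean_control = numeric(),
                      mean_mutant = numeric(), se = numeric(),
                      df = numeric(), p = numeric(),
                      n_obs_control = integer(), n_obs_mutant = integer(),
                      stringsAsFactors = FALSE)
  res$adj_p <- if (nrow(res)) bh_adjust(res$p)$adj_p else numeric()
  res$significant <- res$p < p_cut & abs(res$log2_fc) >= log2(fc_cut)
  res$method <- rep("pooled_t", nrow(res))
  rownames(res) <- NULL
  structure(list(results = res,
                 skipped = if (length(skip)) do.call(rbind, skip)
                           else data.frame(feature_id = character(),
                                           reason = character()),
                 contrast = contrast, ref_level = ref,
                 p_cut = p_cut, fc_cut = fc_cut, kind = "lipid",
                 call = match.call()),
            class = c("lipid_da", "da_fit"))
}
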