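lip_ann <- function(n_ctrl = 15, n_mut = 13) sample_annotation(
  data.frame(sample_id = c(sprintf("ctrl_%02d", seq_len(n_ctrl)),
                           sprintf("mut_%02d", seq_len(n_mut))),
             Knockout = rep(c("control", "mutant"), c(n_ctrl, n_mut)),
             stringsAsFactors = FALSE),
  contrast = "Knockout", ref_level = "control")

toy_panel <- function() {
  lipids <- data.frame(lipid_id = c("PC 38:5", "PC 34:1", "TG 52:4"),
                       class = c("PC", "PC", "TG"),
                       is_id = c("IS_PC", "IS_PC", "IS_TG"),
                       stringsAsFactors = FALSE)
  samples <- c("s1", "s2")
  areas <- expand.grid(lipid_id = lipids$lipid_id, sample_id = samples,
                       stringsAsFactors = FALSE)
  areas$area <- c(1000, 500, 300, 2000, 1000, 600)
  is_areas <- expand.grid(is_id = c("IS_PC", "IS_TG"), sample_id = samples,
                          stringsAsFactors = FALSE)
  is_areas$area <- c(1000, 100, 2000, 200)
  lipid_panel(lipids, areas, is_areas)
}

test_that("internal-standard ratios divide by the assigned standard per sample", {
  rt <- is_ratio_quantify(toy_panel())
  expect_equal(rt$ratio[rt$lipid_id == "PC 38:5" & rt$sample_id == "s1"], 1.0)
  expect_equal(rt$ratio[rt$lipid_id == "TG 52:4" & rt$sample_id == "s1"], 3.0)
  # lipids sharing an IS share the per-sample denominator
  pc <- rt[rt$lipid_id %in% c("PC 38:5", "PC 34:1") & rt$sample_id == "s2", ]
  expect_equal(pc$ratio, c(2000, 1000) / 2000)
})

test_that("per-sample scale factors cancel exactly through the ratio step", {
  pan <- toy_panel()
  pan2 <- pan
  sel <- pan2$areas$sample_id == "s1"
  pan2$areas$area[sel] <- pan2$areas$area[sel] * 7.3
  sel_is <- pan2$is_areas$sample_id == "s1"
  pan2$is_areas$area[sel_is] <- pan2$is_areas$area[sel_is] * 7.3
  expect_equal(is_ratio_quantify(pan)$ratio, is_ratio_quantify(pan2)$ratio,
               tolerance = 1e-12)
})

test_that("zero or missing internal-standard areas invalidate cells", {
  pan <- toy_panel()
  pan$is_areas$area[1] <- 0
  expect_warning(rt <- is_ratio_quantify(pan), "invalid")
  bad <- rt$lipid_id %in% c("PC 38:5", "PC 34:1") & rt$sample_id == "s1"
  expect_true(all(is.na(rt$ratio[bad])))
  expect_true(all(!rt$valid[bad]))
  expect_true(all(rt$valid[!bad]))
})

qc_panel <- function(ok = c(90, 100, 110), bad = c(10, 100, 190)) {
  lipids <- data.frame(lipid_id = c("LIP_OK", "LIP_BAD"), class = "PC",
                       is_id = "IS_PC", stringsAsFactors = FALSE)
  areas <- data.frame(lipid_id = lipids$lipid_id, sample_id = "s1",
                      area = c(10, 10))
  is_areas <- data.frame(is_id = "IS_PC", sample_id = "s1", area = 1)
  qc <- data.frame(lipid_id = rep(c("LIP_OK", "LIP_BAD"), each = 3),
                   level = "1x", replicate = rep(1:3, 2),
                   area = c(ok, bad))
  lipid_panel(lipids, areas, is_areas, qc = qc) # qc areas are ratios directly
}

test_that("QC CV filter retains below-30% lipids and removes the rest", {
  rep_ <- qc_cv_filter(qc_panel())
  r <- rep_$report
  expect_equal(r$cv[r$lipid_id == "LIP_OK"], 10.0)
  expect_equal(r$cv[r$lipid_id == "LIP_BAD"], 90.0)
  expect_true(r$retained[r$lipid_id == "LIP_OK"])
  expect_false(r$retained[r$lipid_id == "LIP_BAD"])
  # identical replicates: CV 0, retained
  rep0 <- qc_cv_filter(qc_panel(ok = c(5, 5, 5)))
  expect_equal(rep0$report$cv[rep0$report$lipid_id == "LIP_OK"], 0)
  expect_true(rep0$report$retained[rep0$report$lipid_id == "LIP_OK"])
})

test_that("QC retention is monotone in the CV threshold and needs replicates", {
  pan <- qc_panel()
  kept <- vapply(c(5, 15, 50, 95), function(th)
    sum(qc_cv_filter(pan, cv_threshold = th)$report$retained), numeric(1))
  expect_true(all(diff(kept) >= 0))
  pan1 <- pan
  pan1$qc <- pan1$qc[pan1$qc$replicate == 1 | pan1$qc$lipid_id == "LIP_OK", ]
  r <- qc_cv_filter(pan1)$report
  expect_false(r$retained[r$lipid_id == "LIP_BAD"])
  expect_equal(r$reason[r$lipid_id == "LIP_BAD"], "insufficient QC")
})

test_that("median normalization sets every sample's positive median to 1", {
  rt <- data.frame(lipid_id = paste0("L", 1:4), sample_id = "s1",
                   ratio = c(0.5, 1.0, 2.0, 4.0))
  nm <- median_normalize(rt)
  expect_equal(nm$ratio, c(1/3, 2/3, 4/3, 8/3), tolerance = 1e-12)
  expect_equal(median_normalize(nm)$ratio, nm$ratio, tolerance = 1e-12)
  # injected per-sample factors are removed exactly
  rt2 <- rbind(rt, transform(rt, sample_id = "s2", ratio = ratio * 11))
  nm2 <- median_normalize(rt2)
  expect_equal(nm2$ratio[nm2$sample_id == "s1"],
               nm2$ratio[nm2$sample_id == "s2"], tolerance = 1e-12)
  expect_error(median_normalize(
    data.frame(lipid_id = "L", sample_id = "dead", ratio = 0)), "dead")
})

test_that("lipid differential abundance on identical groups is null", {
  ann <- lip_ann(3, 3)
  rt <- expand.grid(lipid_id = c("L1", "L2"), sample_id = ann$sample_id,
                    stringsAsFactors = FALSE)
  rt$ratio <- rep(c(1.0, 2.0), times = 6)
  fit <- lipid_da(rt, ann)
  expect_equal(fit$results$log2_fc, c(0, 0))
  expect_equal(fit$results$p, c(1, 1))
  expect_false(any(fit$results$significant))
})

test_that("full pipeline is invariant to per-sample injection scale", {
  tr <- lipid_truth(n_lipids = 12, fc = c(rep(1, 10), 4, 0.25), seed = 9)
  pan <- simulate_lipid_panel(tr, n_control = 5, n_mutant = 5)
  ann <- lip_ann(5, 5)
  run <- function(panel) {
    nm <- median_normalize(is_ratio_quantify(panel))
    lipid_da(nm, ann)$results
  }
  base <- run(pan)
  pan2 <- pan
  f <- 13.7
  sel <- pan2$areas$sample_id == "ctrl_01"
  pan2$areas$area[sel] <- pan2$areas$area[sel] * f
  sel <- pan2$is_areas$sample_id == "ctrl_01"
  pan2$is_areas$area[sel] <- pan2$is_areas$area[sel] * f
  expect_equal(run(pan2), base, tolerance = 1e-12)
  # the injected effects are detected with the right sign
  expect_true(base$significant[base$feature_id == "LIP011"])
  expect_gt(base$log2_fc[base$feature_id == "LIP011"], 1)
  expect_lt(base$log2_fc[base$feature_id == "LIP012"], -1)
})

test_that("lipid panels round-trip through the long-format CSV", {
  tr <- lipid_truth(n_lipids = 6, seed = 60)
  pan <- simulate_lipid_panel(tr, n_control = 3, n_mutant = 2)
  path <- tempfile(fileext = ".csv")
  write_lipid_panel(pan, path)
  back <- read_lipid_panel(path)
  expect_equal(back$lipids, pan$lipids)
  expect_equal(back$areas$area, pan$areas$area)
  expect_equal(back$is_areas$area, pan$is_areas$area)
  expect_equal(back$qc$area, pan$qc$area)
  expect_equal(back$qc_is$level, pan$qc_is$level)
  # ratios computed from the re-read panel are identical
  expect_equal(is_ratio_quantify(back)$ratio, is_ratio_quantify(pan)$ratio)
})

test_that("lipid p-values are uniform under the null", {
  tr <- lipid_truth(n_lipids = 1000, fc = 1, sample_scale_sd = 0, seed = 10)
  pan <- simulate_lipid_panel(tr)
  nm <- median_normalize(is_ratio_quantify(pan))
  fit <- lipid_da(nm, lip_ann())
  expect_gt(ks.test(fit$results$p, "punif")$p.value, 0.01)
})
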