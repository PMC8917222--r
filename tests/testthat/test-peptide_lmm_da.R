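ann_44 <- sample_annotation(
  data.frame(sample_id = c(paste0("c", 1:4), paste0("m", 1:4)),
             Knockout = rep(c("control", "mutant"), each = 4),
             stringsAsFactors = FALSE),
  contrast = "Knockout", ref_level = "control")

# complete balanced normalized peptide table for one protein
balanced_protein <- function(n_pep, ann, effect = 0, sigma_pep = 0.5,
                             sigma_e = 0.3, seed = 1) {
  set.seed(seed)
  is_mut <- ann$Knockout != "control"
  b <- rnorm(n_pep, 0, sigma_pep)
  d <- expand.grid(peptide_id = paste0("pep", seq_len(n_pep)),
                   sample_id = ann$sample_id, stringsAsFactors = FALSE)
  d$protein_id <- "P1"
  d$t_intensity <- 20 + b[match(d$peptide_id, paste0("pep", seq_len(n_pep)))] +
    effect * is_mut[match(d$sample_id, ann$sample_id)] +
    rnorm(nrow(d), 0, sigma_e)
  d
}

test_that("balanced complete design: LMM contrast equals difference of condition means", {
  for (seed in 1:5) {
    vs <- runif(2, 0.1, 2) # arbitrary variance components
    d <- balanced_protein(5, ann_44, effect = 1.3, sigma_pep = vs[1],
                          sigma_e = vs[2], seed = seed)
    f <- fit_protein_lmm(d, ann_44)
    is_mut <- ann_44$Knockout[match(d$sample_id, ann_44$sample_id)] == "mutant"
    expect_equal(f$estimate,
                 mean(d$t_intensity[is_mut]) - mean(d$t_intensity[!is_mut]),
                 tolerance = 1e-6)
  }
})

test_that("single-peptide protein degrades to the pooled-variance t-test", {
  ann_33 <- sample_annotation(
    data.frame(sample_id = c("c1", "c2", "c3", "m1", "m2", "m3"),
               Knockout = rep(c("control", "mutant"), each = 3)),
    contrast = "Knockout", ref_level = "control")
  set.seed(7)
  d <- data.frame(protein_id = "P1", peptide_id = "pep1",
                  sample_id = ann_33$sample_id,
                  t_intensity = rnorm(6, 20, 1))
  f <- fit_protein_lmm(d, ann_33)
  expect_equal(f$method, "ols")
  mut <- d$t_intensity[4:6]; ctl <- d$t_intensity[1:3]
  tt <- pooled_t_test(mut, ctl)
  expect_equal(f$estimate, tt$diff, tolerance = 1e-10)
  expect_equal(f$p, tt$p, tolerance = 1e-10)
  expect_equal(f$df, tt$df)
})

test_that("zero peptide variance degrades to fixed-effects least squares", {
  # sigma_pep = 0 makes the random intercept collapse; compare against lm
  set.seed(8)
  n_bad <- 0
  for (i in 1:20) {
    d <- balanced_protein(sample(2:4, 1), ann_44, effect = runif(1, -1, 1),
                          sigma_pep = 0, sigma_e = runif(1, 0.2, 1),
                          seed = 100 + i)
    f <- fit_protein_lmm(d, ann_44)
    if (f$method != "ols") next # REML may still estimate tiny variance
    n_bad <- n_bad + 1
    ols <- lm(t_intensity ~ Knockout,
              data = merge(d, ann_44, by = "sample_id"))
    expect_equal(f$estimate, unname(coef(ols)["Knockoutmutant"]),
                 tolerance = 1e-10)
    expect_equal(f$p, summary(ols)$coefficients["Knockoutmutant", 4],
                 tolerance = 1e-10)
  }
  expect_gt(n_bad, 5) # the degenerate path must actually be exercised
})

test_that("two-factor design reports the marginal knockout effect", {
  ann2 <- sample_annotation(
    data.frame(sample_id = sprintf("s%d", 1:8),
               Background = rep(c("bgA", "bgB"), times = 4),
               Knockout = rep(c("control", "mutant"), each = 4)),
    contrast = "Knockout", ref_level = "control")
  set.seed(9)
  d <- balanced_protein(4, ann2, effect = 0, seed = 30)
  # inject knockout effect 1 plus background effect and interaction
  meta <- ann2[match(d$sample_id, ann2$sample_id), ]
  d$t_intensity <- d$t_intensity + 1.0 * (meta$Knockout == "mutant") +
    0.5 * (meta$Background == "bgB") +
    0.6 * (meta$Knockout == "mutant") * (meta$Background == "bgB")
  f <- fit_protein_lmm(d, ann2)
  # marginal mutant - control difference averaged over backgrounds: 1 + 0.6/2
  is_mut <- meta$Knockout == "mutant"
  expect_equal(f$estimate,
               mean(d$t_intensity[is_mut]) - mean(d$t_intensity[!is_mut]),
               tolerance = 1e-6)
  expect_equal(f$estimate, 1.3, tolerance = 0.2)
})

test_that("simulated proteins recover the true fold change on average", {
  est <- vapply(1:500, function(i) {
    d <- balanced_protein(5, ann_44, effect = 1.0, sigma_pep = 0.5,
                          sigma_e = 0.3, seed = 1000 + i)
    fit_protein_lmm(d, ann_44)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 0.05)
})

test_that("pseudo fold change reproduces the worked pool example", {
  # protein observed only in the mutant condition (control missing):
  # peptide means {10, 12}; control pool {6..15} -> impute 6 -> median FC 5
  pool <- data.frame(protein_id = "various",
                     peptide_id = paste0("pp", 1:10),
                     condition = "control", mean_t = 6:15)
  d <- data.frame(protein_id = "PX",
                  peptide_id = rep(c("a", "b"), each = 2),
                  sample_id = rep(c("m1", "m2"), 2),
                  t_intensity = rep(c(10, 12), each = 2))
  r <- pseudo_fc_peptide(d, pool, ann_44)
  expect_equal(r$log2_fc, 5.0)
  expect_equal(r$method, "pseudo")
  expect_true(is.na(r$p) && is.na(r$adj_p))
  expect_equal(r$impute_value, 6.0)
  expect_equal(r$log2_fc,
               brute_pseudo_fc(c(10, 12), 6:15, missing_is_control = TRUE))
  # single peptide: median of one
  r1 <- pseudo_fc_peptide(d[d$peptide_id == "a", ], pool, ann_44)
  expect_equal(r1$log2_fc, 4.0)
})

test_that("pseudo fold change refuses fully observed or unobserved proteins", {
  pool <- data.frame(protein_id = "v", peptide_id = "q",
                     condition = "control", mean_t = 5)
  both <- data.frame(protein_id = "PX", peptide_id = "a",
                     sample_id = c("c1", "m1"), t_intensity = c(1, 2))
  expect_error(pseudo_fc_peptide(both, pool, ann_44), "both conditions")
  none <- both[0, ]
  expect_error(pseudo_fc_peptide(none, pool, ann_44), "unobserved")
})

test_that("pseudo fold change is monotone in observed means and pool-insensitive above the cut", {
  pool <- data.frame(protein_id = "v", peptide_id = paste0("q", 1:10),
                     condition = "control", mean_t = 6:15)
  mk <- function(m1, m2) data.frame(
    protein_id = "PX", peptide_id = rep(c("a", "b"), each = 1),
    sample_id = c("m1", "m1"), t_intensity = c(m1, m2))
  r_lo <- pseudo_fc_peptide(mk(9, 11), pool, ann_44)
  r_hi <- pseudo_fc_peptide(mk(10, 12), pool, ann_44)
  expect_lt(r_lo$log2_fc, r_hi$log2_fc)
  # adding pool values above the 10% quantile changes nothing
  pool2 <- rbind(pool, data.frame(protein_id = "w",
                                  peptide_id = paste0("r", 1:5),
                                  condition = "control", mean_t = 8:12))
  k <- ceiling(0.1 * nrow(pool2)) # still picks values from {6, 7}
  expect_equal(pseudo_fc_peptide(mk(10, 12), pool2, ann_44)$log2_fc,
               median(c(10, 12) - mean(sort(pool2$mean_t)[1:k])))
})

test_that("the peptide-level pipeline accounts for every input protein", {
  # censoring disabled so the designated absent set is the only source of
  # fully-missing proteins
  tr <- peptide_truth(n_proteins = 30, pi0 = 0.8, n_absent_mutant = 5,
                      censor_scale = 0, seed = 42)
  sim <- simulate_peptide_dataset(tr)
  fit <- run_os_da(sim$peptides, sim$annotation)
  res <- fit$results
  expect_equal(sum(res$method == "pseudo"), 5L)
  expect_equal(nrow(res) + nrow(fit$skipped),
               length(unique(sim$peptides$protein_id)))
  # pseudo rows carry no p-value and BH is computed over model p only
  expect_true(all(is.na(res$adj_p[res$method == "pseudo"])))
  tested <- res$method %in% c("lmm", "ols")
  expect_equal(res$adj_p[tested], p.adjust(res$p[tested], "BH"))
  expect_true(all(res$adj_p[tested] >= res$p[tested]))
  # signed fold changes follow the documented convention
  expect_equal(res$fc_signed, signed_fc(res$log2_fc))
  # pseudo fold changes match a direct recomputation from the pipeline's
  # own normalized table (median over peptides of observed mean - impute)
  norm <- robust_z_normalize(log2_transform_nonzero(sim$peptides))
  pools <- peptide_condition_means(norm, sim$annotation)
  mut_pool <- pools$mean_t[pools$condition == "mutant"]
  for (pid in res$feature_id[res$method == "pseudo"]) {
    d <- norm[norm$protein_id == pid, ]
    obs_means <- tapply(d$t_intensity, d$peptide_id, mean)
    expect_equal(res$log2_fc[res$feature_id == pid],
                 brute_pseudo_fc(as.numeric(obs_means), mut_pool,
                                 missing_is_control = FALSE),
                 tolerance = 1e-12)
  }
})
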