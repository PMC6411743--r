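test_that("preprocessing pins vehicles at 1 and is invariant to per-label scaling", {
  sim <- quick_2d_sim(n = 15, noise_cv = 0.05)
  cfg <- quick_cfg()
  fc <- preprocess_2dtpp(sim$quant, sim$meta, cfg)
  expect_equal(as.vector(fc$phi[, , 1, ]), rep(1, 15 * 10 * 3))

  # multiplying every intensity of one TMT label by 10 changes nothing:
  # the label's fold changes shift by a constant on the log scale and the
  # median normalization removes it
  q2 <- sim$quant
  lab_samples <- sim$meta$sample_id[sim$meta$tmt_label == "128H"]
  sel <- q2$sample_id %in% lab_samples
  q2$value[sel] <- q2$value[sel] * 10
  fc2 <- preprocess_2dtpp(q2, sim$meta, cfg)
  expect_equal(fc2$phi, fc$phi, tolerance = 1e-9)

  # median-centering: each non-vehicle sample has median log2 fold change 0
  lphi <- log2(fc$phi)
  for (jc in 2:5) expect_equal(median(lphi[, 3, jc, 2]), 0, tolerance = 1e-9)
})

test_that("window scores enumerate adjacent-temperature pairs and vanish on null data", {
  sim <- quick_2d_sim(n = 6, noise_cv = 0,
                      class_fractions = c(null = 1, stabilized = 0, destabilized = 0))
  cfg <- quick_cfg()
  fc <- preprocess_2dtpp(sim$quant, sim$meta, cfg)
  win <- window_scores(fc, cfg, gated_only = FALSE)
  expect_equal(nrow(win), 6 * 9)     # 10 temperatures -> 9 windows
  expect_true(all(win$t_hi > win$t_lo))
  expect_true(all(win$F == 0))
  expect_true(all(abs(win$phi_max - 1) < 1e-9))
})

test_that("combined scores gate windows at h and sum logs", {
  win <- data.frame(
    protein_id = "P1", window = 1:3, t_lo = c(42, 44.1, 46.2),
    t_hi = c(44.1, 46.2, 48.1),
    phi_max = c(2.0, 1.2, 1.8),       # 1.2 sits inside (1/1.5, 1.5): excluded
    gated = c(TRUE, FALSE, TRUE),
    F = c(exp(1), 50, exp(2)), n_reps = 3, stringsAsFactors = FALSE)
  sc <- combined_score(win, analysis_config())
  expect_equal(sc$F_comb, 3)          # ln(e^1) + ln(e^2)
  expect_equal(sc$direction, "stabilized")
  expect_equal(sc$n_gated, 2L)

  # no gated windows -> zero score, no direction
  win$gated <- FALSE
  sc <- combined_score(win, analysis_config())
  expect_equal(sc$F_comb, 0)
  expect_equal(sc$direction, "none")

  # a window with F < 1 contributes nothing under the default flooring,
  # but a negative term when raw logs are allowed
  win2 <- data.frame(protein_id = "P1", window = 1:2, t_lo = c(42, 44.1),
                     t_hi = c(44.1, 46.2), phi_max = c(2, 2), gated = TRUE,
                     F = c(exp(2), 0.5), n_reps = 3, stringsAsFactors = FALSE)
  expect_equal(combined_score(win2, analysis_config())$F_comb, 2)
  expect_equal(combined_score(win2, analysis_config(allow_negative_log_terms = TRUE))$F_comb,
               2 + log(0.5))

  # destabilization gate and the tie rule
  win3 <- data.frame(protein_id = "P1", window = 1:2, t_lo = c(42, 44.1),
                     t_hi = c(44.1, 46.2), phi_max = c(0.5, 1.8), gated = TRUE,
                     F = c(2, 2), n_reps = 3, stringsAsFactors = FALSE)
  expect_equal(combined_score(win3, analysis_config())$direction, "destabilized")
})

test_that("stratified permutation preserves vehicles and per-stratum multisets", {
  sim <- quick_2d_sim(n = 25, noise_cv = 0.1)
  cfg <- quick_cfg()
  fc <- preprocess_2dtpp(sim$quant, sim$meta, cfg)
  perm <- permute_dataset(fc, seed = 123)
  # vehicle (reference) values bit-identical
  expect_identical(perm$phi[, , 1, ], fc$phi[, , 1, ])
  # the permutation moved something
  expect_false(identical(perm$phi, fc$phi))
  # per-(temperature x qupm) stratum multisets preserved exactly
  for (jt in seq_along(fc$temperatures)) {
    for (qb in unique(fc$qupm)) {
      sel <- fc$qupm == qb
      expect_identical(sort(as.vector(perm$phi[sel, jt, -1, ])),
                       sort(as.vector(fc$phi[sel, jt, -1, ])))
    }
  }
  # same seed -> identical permutation; different seed -> different
  expect_identical(permute_dataset(fc, 123)$phi, perm$phi)
  expect_false(identical(permute_dataset(fc, 124)$phi, perm$phi))
})

test_that("the fast scoring engine matches the reference window-score path", {
  sim <- quick_2d_sim(n = 30, seed = 8, noise_cv = 0.08)
  cfg <- quick_cfg()
  fc <- preprocess_2dtpp(sim$quant, sim$meta, cfg)
  a <- thermsol:::tpp2d_engine(fc, cfg)
  b <- combined_score(window_scores(fc, cfg, gated_only = TRUE), cfg)
  b <- b[match(a$protein_id, b$protein_id), ]
  expect_equal(a$F_comb, b$F_comb)
  expect_equal(a$direction, b$direction)
})

test_that("the permutation FDR reproduces hand-computed rankings and a brute-force loop", {
  cfg <- analysis_config()
  # r = 10 original hits, exactly one permuted score above threshold in each
  # of B permutations: FDR = 2*1/(10+1)
  original <- rep(5, 10)
  permuted <- replicate(4, c(6, rep(0, 9)), simplify = FALSE)
  tab <- fdr_estimate(original, permuted, cfg)
  expect_equal(tab$fdr[tab$theta == 5], 2 / 11, tolerance = 1e-12)

  # B = 2 with v = {0, 2} at r = 8: (0 + 2*2/(8+2))/2 = 0.2
  original <- rep(1, 8)
  permuted <- list(rep(0, 8), c(2, 2, rep(0, 6)))
  tab <- fdr_estimate(original, permuted, cfg)
  expect_equal(tab$fdr[tab$theta == 1], 0.2, tolerance = 1e-12)

  # all permutations empty -> FDR 0
  tab <- fdr_estimate(rep(3, 5), list(rep(0, 5)), cfg)
  expect_equal(tab$fdr, 0)

  # brute-force recomputation on random scores agrees exactly
  set.seed(11)
  original <- round(rexp(50), 2)
  permuted <- replicate(7, round(rexp(50), 2), simplify = FALSE)
  tab <- fdr_estimate(original, permuted, cfg)
  for (th in tab$theta) {
    r <- 0
    for (s in original) if (s >= th) r <- r + 1
    acc <- 0
    for (pv in permuted) {
      v <- 0
      for (s in pv) if (s >= th) v <- v + 1
      if (r + v > 0) acc <- acc + 2 * v / (r + v)
    }
    expect_equal(tab$fdr_raw[tab$theta == th], acc / length(permuted), tolerance = 1e-12)
  }
  # monotonized FDR is non-increasing in the threshold and within [0, 1]
  expect_true(all(diff(tab$fdr) <= 1e-12))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
})

test_that("hit calling requires low FDR and a nonzero combined score", {
  cfg <- analysis_config(fdr_cutoff = 0.05)
  scores <- data.frame(protein_id = c("A", "B", "C"), F_comb = c(9, 0, 2),
                       direction = c("stabilized", "none", "stabilized"),
                       stringsAsFactors = FALSE)
  tab <- fdr_estimate(scores$F_comb, list(c(0, 0, 0), c(3, 0, 0)), cfg)
  out <- call_hits(scores, tab, cfg)
  expect_true(out$hit[out$protein_id == "A"])
  expect_false(out$hit[out$protein_id == "B"])  # zero score is never a hit
  # empty input stays empty
  e <- call_hits(scores[0, ], tab, cfg)
  expect_equal(nrow(e), 0)
})

test_that("pEC50 assignment needs the gate in at least two replicates", {
  sim <- quick_2d_sim(n = 10, noise_cv = 0,
                      class_fractions = c(null = 1, stabilized = 0, destabilized = 0))
  cfg <- quick_cfg()
  fc <- preprocess_2dtpp(sim$quant, sim$meta, cfg)
  # inject a strong dose effect into replicate 1 only of protein 1
  x <- log10(fc$concentrations[-1] / 1000)
  fc$phi[1, , -1, 1] <- rep(1 + 2 / (1 + exp(-(x + 4))), each = 10)
  scores <- data.frame(protein_id = fc$proteins, F_comb = c(10, rep(0, 9)),
                       direction = c("stabilized", rep("none", 9)),
                       hit = c(TRUE, rep(FALSE, 9)), stringsAsFactors = FALSE)
  out <- assign_pec50(scores, fc, cfg)
  expect_true(is.na(out$pEC50[1]))  # only one replicate ever reaches the gate

  # with the same effect in two replicates the median pEC50 appears
  fc$phi[1, , -1, 2] <- rep(1 + 2 / (1 + exp(-(x + 4))), each = 10)
  out2 <- assign_pec50(scores, fc, cfg)
  expect_false(is.na(out2$pEC50[1]))
  expect_lt(abs(out2$pEC50[1] - 4), 0.25)
})

test_that("combined scores are invariant under protein order", {
  sim <- quick_2d_sim(n = 20, seed = 13, noise_cv = 0.08)
  cfg <- quick_cfg()
  r1 <- thermsol:::tpp2d_engine(preprocess_2dtpp(sim$quant, sim$meta, cfg), cfg)
  set.seed(1)
  q2 <- sim$quant[sample(nrow(sim$quant)), ]
  r2 <- thermsol:::tpp2d_engine(preprocess_2dtpp(q2, sim$meta, cfg), cfg)
  r2 <- r2[match(r1$protein_id, r2$protein_id), ]
  expect_equal(r1$F_comb, r2$F_comb)
})

test_that("the full 2D pipeline recovers strong spiked effects with directions", {
  sim <- quick_2d_sim(n = 60, seed = 21, noise_cv = 0.05)
  res <- tpp2d(sim$quant, sim$meta, analysis_config(n_permutations = 20, seed = 21))
  m <- merge(res$scores, sim$truth)
  expect_true(all(!m$hit[m$effect_class == "null"]))
  expect_gt(mean(m$hit[m$effect_class == "stabilized"]), 0.8)
  expect_true(all(m$direction[m$hit & m$effect_class == "stabilized"] == "stabilized"))
  expect_true(all(is.na(m$pEC50[!m$hit])))
  expect_output(print(res), "2D-TPP analysis")
})
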