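test_that("glog2 behaves like log2 at high intensity and inverts exactly", {
  x <- c(1e4, 1e5, 1e6)
  expect_equal(glog2(x, c = 100), log2(x), tolerance = 0.01)
  z <- glog2(c(0, 5, 50, 5e5), c = 30)
  expect_equal(glog2_inv(z, c = 30), c(0, 5, 50, 5e5), tolerance = 1e-9)
})

test_that("normalization calibrates away per-sample scale factors", {
  sim <- simulate_spp(sim_config("SPP", n_proteins = 60, seed = 2, noise_cv = 0.05))
  cfg <- quick_cfg()
  # two samples identical up to a factor of 2 calibrate onto each other
  q2 <- sim$quant
  s1 <- sim$meta$sample_id[2]; s2 <- sim$meta$sample_id[3]
  q2$value[q2$sample_id == s2] <- 2 * q2$value[q2$sample_id == s1]
  tab <- normalize_spp(q2, sim$meta, cfg)
  n1 <- tab$normalized$value[tab$normalized$sample_id == s1]
  n2 <- tab$normalized$value[tab$normalized$sample_id == s2]
  expect_equal(n2, n1, tolerance = 1e-6)

  # rescaling one sample wholesale leaves fold changes essentially unchanged
  # (the row-median reference moves slightly, hence the loose tolerance)
  t1 <- normalize_spp(sim$quant, sim$meta, cfg)
  q3 <- sim$quant
  sid <- sim$meta$sample_id[5]
  q3$value[q3$sample_id == sid] <- q3$value[q3$sample_id == sid] * 2
  t2 <- normalize_spp(q3, sim$meta, cfg)
  expect_equal(t2$fc, t1$fc, tolerance = 0.03)
  # vehicle vs itself is exactly 1
  expect_equal(as.vector(t1$fc[, 1, ]), rep(1, 60 * 3))
})

test_that("insoluble classification is boundary-inclusive and scale-invariant", {
  sim <- simulate_spp(sim_config("SPP", n_proteins = 40, seed = 4, noise_cv = 0))
  cfg <- quick_cfg()
  tab <- normalize_spp(sim$quant, sim$meta, cfg)
  # direct boundary arithmetic on crafted ratios
  tab2 <- tab
  tab2$sds_ratio <- matrix(rep(c(1.5, 1.49, 2.5, 0.9), 3), 4, 3)
  tab2$proteins <- paste0("Q", 1:4)
  cls <- classify_insoluble(tab2, cfg)
  expect_equal(cls$insoluble, c(TRUE, FALSE, TRUE, FALSE)) # 1.5 is insoluble
  # scale invariance: multiply one replicate wholesale
  q2 <- sim$quant
  r1 <- sim$meta$sample_id[sim$meta$replicate == 1]
  q2$value[q2$sample_id %in% r1] <- q2$value[q2$sample_id %in% r1] * 7
  cls1 <- classify_insoluble(normalize_spp(sim$quant, sim$meta, cfg), cfg)
  cls2 <- classify_insoluble(normalize_spp(q2, sim$meta, cfg), cfg)
  expect_equal(cls2$insoluble, cls1$insoluble)
  # agreement with ground truth at zero noise: ratio = 1/(1 - insoluble_fraction)
  cls <- classify_insoluble(tab, cfg)
  expect_equal(cls$insoluble, sim$truth$insoluble_fraction >= 1 / 3)
})

test_that("the solubilization F-statistic separates flat from sigmoidal profiles", {
  cfg <- analysis_config()
  doses <- c(0, 0.1, 0.5, 1, 2, 4, 5, 8, 10)
  flat <- spp_score(rep(doses, 3), rep(1, 27), cfg)
  expect_lt(flat$F, 1e-6)
  x <- log10(doses[-1] / 1000)
  y <- 1 + 1.5 / (1 + exp(-2 * (x + 3)))
  prof <- spp_score(rep(doses, 3), rep(c(1, y), 3), cfg)
  expect_gt(prof$F, 1e3)
  expect_lt(abs(prof$fit$e - (-3)), 0.05)
})

test_that("SPP hit calling recovers solubilized proteins and rejects nulls", {
  sim <- simulate_spp(sim_config("SPP", n_proteins = 150, seed = 6, noise_cv = 0.05,
                                 insoluble_proteome_fraction = 0.3,
                                 insoluble_fraction_range = c(0.6, 0.6),
                                 class_fractions = c(null = 0.8, solubilized = 0.15,
                                                     desolubilized = 0.05)))
  res <- spp(sim$quant, sim$meta, analysis_config(n_permutations = 20, seed = 6))
  m <- merge(res$profiles, sim$truth)
  expect_true(all(!m$hit[m$effect_class == "null"]))
  expect_gt(mean(m$hit[m$effect_class == "solubilized"]), 0.8)
  sol <- m$hit & m$effect_class == "solubilized"
  expect_true(all(m$direction[sol] == "solubilized"))
  expect_true(all(is.finite(m$pEC50_s[m$hit])))
  # a large F with a sub-gate fold change is never a hit
  expect_true(all(m$max_median_fc[sol] >= 1.5))
})

test_that("mass balance bounds the estimated maximal fold change", {
  sim <- simulate_spp(sim_config("SPP", n_proteins = 120, seed = 9, noise_cv = 0.1,
                                 insoluble_proteome_fraction = 0.3,
                                 insoluble_fraction_range = c(0.6, 0.6),
                                 class_fractions = c(null = 0.85, solubilized = 0.15,
                                                     desolubilized = 0)))
  tab <- normalize_spp(sim$quant, sim$meta, quick_cfg())
  med <- apply(tab$fc[, -1, , drop = FALSE], c(1, 2), median)
  # per protein: never above 1/(1 - insoluble_fraction) by more than 3 noise CVs
  bound <- 1 / (1 - sim$truth$insoluble_fraction[match(tab$proteins, sim$truth$protein_id)])
  expect_true(all(med <= bound * (1 + 3 * 0.1)))
})

test_that("hit calling is monotone in the simulated release fraction", {
  cfgs <- lapply(c(0.5, 1), function(rel)
    sim_config("SPP", n_proteins = 100, seed = 17, noise_cv = 0.05,
               insoluble_proteome_fraction = 0.3,
               insoluble_fraction_range = c(0.6, 0.6), release_fraction = rel,
               class_fractions = c(null = 0.8, solubilized = 0.2, desolubilized = 0)))
  acfg <- analysis_config(n_permutations = 20, seed = 17)
  hits <- lapply(cfgs, function(sc) {
    sim <- simulate_spp(sc)
    res <- spp(sim$quant, sim$meta, acfg)
    res$profiles$protein_id[res$profiles$hit]
  })
  expect_true(all(hits[[1]] %in% hits[[2]]))
})
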