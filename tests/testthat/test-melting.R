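standard_temps <- c(37.0, 40.4, 44.0, 46.9, 49.8, 52.9, 55.5, 58.6, 62.0, 66.3)

test_that("noise-free melting curves refit their melting point to 0.1 degC", {
  set.seed(3)
  for (i in 1:20) {
    tm <- runif(1, 44, 58); p <- runif(1, 0, 0.25); a <- runif(1, 350, 900)
    y <- melt_model(standard_temps, a, melt_b_for_tm(a, tm, p), p)
    fit <- fit_melting_curve(standard_temps, y)
    expect_true(fit$valid)
    expect_lt(abs(fit$Tm - tm), 0.1)
  }
  # the closed-form Tm solves f(Tm) = 0.5
  expect_equal(melt_model(melt_tm(550, 12, 0.1), 550, 12, 0.1), 0.5, tolerance = 1e-12)
})

test_that("flat or truncated profiles yield no melting point", {
  fit <- fit_melting_curve(standard_temps, rep(1, 10))
  expect_true(is.na(fit$Tm))
  expect_false(fit$valid)
  short <- fit_melting_curve(standard_temps[1:4], rep(1, 4))
  expect_false(short$converged)
})

test_that("Tm estimation is equivariant under temperature shifts", {
  y <- melt_model(standard_temps, 550, melt_b_for_tm(550, 50, 0.05), 0.05)
  t1 <- fit_melting_curve(standard_temps, y)$Tm
  y2 <- melt_model(standard_temps + 4, 550, melt_b_for_tm(550, 54, 0.05), 0.05)
  t2 <- fit_melting_curve(standard_temps + 4, y2)$Tm
  expect_equal(t2 - t1, 4, tolerance = 0.05)
})

test_that("delta Tm subtracts vehicle from treated and propagates missingness", {
  y <- melt_model(standard_temps, 550, melt_b_for_tm(550, 50, 0.05), 0.05)
  veh <- fit_melting_curve(standard_temps, y)
  expect_equal(delta_tm(veh, veh), 0, tolerance = 1e-9)
  y3 <- melt_model(standard_temps, 550, melt_b_for_tm(550, 53, 0.05), 0.05)
  trt <- fit_melting_curve(standard_temps, y3)
  expect_equal(delta_tm(trt, veh), 3, tolerance = 0.05)
  bad <- fit_melting_curve(standard_temps, rep(1, 10))
  expect_true(is.na(delta_tm(trt, bad)))
})

test_that("the co-melting distance is a semimetric on the stated scale", {
  a <- melt_model(standard_temps, 550, melt_b_for_tm(550, 50, 0.05), 0.05)
  expect_equal(comelt_distance(a, a), 0)
  expect_equal(comelt_distance(a, a + 0.1), 0.01, tolerance = 1e-12)
  b <- melt_model(standard_temps, 550, melt_b_for_tm(550, 55, 0.05), 0.05)
  expect_equal(comelt_distance(a, b), comelt_distance(b, a))
  expect_gt(comelt_distance(a, b), 0)
  expect_true(is.na(comelt_distance(a[1:4], b[1:4])))
  # root-sum-square alternative is larger for 10-point profiles
  expect_gt(comelt_distance(a, a + 0.1, metric = "rss"), comelt_distance(a, a + 0.1))
})

test_that("intra-complex pairs co-melt below the cutoff; separated proteins do not", {
  cfg <- analysis_config()
  sim <- simulate_tpp_tr(sim_config("TPP_TR", n_proteins = 40, seed = 12, noise_cv = 0,
                                    n_complexes = 3, subunits_per_complex = 4,
                                    complex_jitter_sd = 0))
  res <- tpp_tr(sim$quant, sim$meta, cfg)
  prof <- res$profiles[["vehicle_1"]]
  for (cid in unique(na.omit(sim$truth$complex_id))) {
    sub <- which(!is.na(sim$truth$complex_id) & sim$truth$complex_id == cid)
    d <- combn(sub, 2, function(k) comelt_distance(prof[k[1], ], prof[k[2], ]))
    expect_true(all(d < cfg$comelt_cutoff))
  }
  # random pairs with clearly distinct melting points are not in proximity
  tm <- sim$truth$true_Tm_vehicle
  far <- which(outer(tm, tm, function(x, y) abs(x - y)) >= 4, arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  d <- apply(far, 1, function(k) comelt_distance(prof[k[1], ], prof[k[2], ]))
  expect_true(all(d >= cfg$comelt_cutoff))
})

test_that("the co-melting randomization test is reproducible and detects tight complexes", {
  set.seed(31)
  tt <- standard_temps
  bg <- t(sapply(runif(60, 44, 58), function(tm)
    melt_model(tt, 550, melt_b_for_tm(550, tm, 0.05), 0.05) * rlnorm(10, 0, 0.03)))
  tight <- bg[rep(7, 4), ] * matrix(rlnorm(40, 0, 0.005), 4)
  ct <- complex_comelt_test(tight, bg, n_rand = 999, seed = 1)
  expect_lte(ct$p_value, 0.001)
  expect_true(all(ct$pair_distances$in_proximity))
  ct2 <- complex_comelt_test(tight, bg, n_rand = 999, seed = 1)
  expect_equal(ct$p_value, ct2$p_value)
  expect_error(complex_comelt_test(tight, bg[1:3, ], n_rand = 9, seed = 1), "background")
  expect_error(complex_comelt_test(tight[1:2, ], bg, n_rand = 9, seed = 1), "at least 3")
})

test_that("maximal fold change on heating finds the solubilization peak", {
  out <- max_fold_change_on_heating(c(37, 42, 58, 66), c(1, 1.3, 2, 0.4))
  expect_equal(out$max_fc, 2)
  expect_equal(out$log2_max_fc, 1)
  expect_equal(out$t_max, 58)
  dec <- max_fold_change_on_heating(c(37, 45, 55, 65), c(1, 0.8, 0.5, 0.2))
  expect_lt(dec$log2_max_fc, 0)
  expect_error(max_fold_change_on_heating(c(40, 50), c(1, 2)), "reference")
})

test_that("solubility correction divides out the dose fold change before normalization", {
  y <- melt_model(standard_temps, 550, melt_b_for_tm(550, 50, 0.05), 0.05)
  same <- solubility_corrected_curve(standard_temps, y, 1)
  expect_equal(same$fraction, y / y[1], tolerance = 1e-12)
  # treated = 2x vehicle everywhere and spp_fc = 2 -> corrected equals vehicle
  corr <- solubility_corrected_curve(standard_temps, 2 * y, 2)
  expect_equal(corr$fraction, y / y[1], tolerance = 1e-12)
  expect_true(attr(corr, "corrected"))
  expect_error(solubility_corrected_curve(standard_temps, y, 0), "undefined")
  flagged <- solubility_corrected_curve(standard_temps, y, NA)
  expect_false(attr(flagged, "corrected"))
})

test_that("group shift tests wrap the Wilcoxon machinery with tie handling", {
  set.seed(5)
  a <- rnorm(50); b <- a + 3
  expect_lt(group_shift_test(a, b, paired = TRUE)$p_value, 0.001)
  expect_lt(group_shift_test(a, b, paired = FALSE)$p_value, 0.001)
  expect_true(is.na(group_shift_test(a, a, paired = TRUE)$p_value))
  expect_gt(group_shift_test(a, a, paired = FALSE)$p_value, 0.9)
  expect_error(group_shift_test(numeric(0), a), "empty")
  expect_error(group_shift_test(a, b[1:10], paired = TRUE), "equal lengths")
})

test_that("the TPP-TR pipeline recovers melting points and condition shifts", {
  sim <- simulate_tpp_tr(sim_config("TPP_TR", n_proteins = 30, seed = 14, noise_cv = 0.03))
  res <- tpp_tr(sim$quant, sim$meta, quick_cfg())
  cv <- res$curves[res$curves$condition == "vehicle" & res$curves$valid, ]
  m <- merge(cv, sim$truth)
  expect_gt(nrow(m), 40)
  expect_lt(median(abs(m$Tm - m$true_Tm_vehicle)), 0.6)
  dm <- merge(res$delta_tm, sim$truth)
  st <- dm$effect_class == "stabilized"
  if (any(st)) expect_gt(median(dm$delta_tm[st], na.rm = TRUE), 1)
  nl <- dm$effect_class == "null"
  expect_lt(abs(median(dm$delta_tm[nl], na.rm = TRUE)), 0.3)
})
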