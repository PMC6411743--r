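test_that("generators are pure functions of (config, seed)", {
  for (kind in c("TPP_2D", "SPP", "TPP_TR")) {
    cfg <- sim_config(kind, n_proteins = 10, seed = 5)
    a <- switch(kind, TPP_2D = simulate_2dtpp(cfg), SPP = simulate_spp(cfg),
                TPP_TR = simulate_tpp_tr(cfg))
    b <- switch(kind, TPP_2D = simulate_2dtpp(cfg), SPP = simulate_spp(cfg),
                TPP_TR = simulate_tpp_tr(cfg))
    expect_identical(a$quant, b$quant)
    expect_identical(a$truth, b$truth)
  }
})

test_that("noise-free null proteins have fold change exactly 1 in 2D layouts", {
  sim <- quick_2d_sim(n = 20, noise_cv = 0,
                      class_fractions = c(null = 1, stabilized = 0, destabilized = 0))
  fc <- preprocess_2dtpp(sim$quant, sim$meta, quick_cfg())
  expect_equal(as.vector(fc$phi), rep(1, length(fc$phi)), tolerance = 1e-12)
})

test_that("the generating dose effect hits the sigmoid midpoint at the true EC50", {
  # a stabilized protein with pEC50 = 5 measured at dose 0.01 mM (= 1e-5 M)
  # must show the midpoint (c+d)/2 of its generating curve
  cfg <- sim_config("TPP_2D", n_proteins = 6, seed = 2, noise_cv = 0,
                    concentrations_mM = c(0, 0.01, 0.1, 1, 10),
                    pec50_range = c(5, 5),
                    class_fractions = c(null = 0, stabilized = 1, destabilized = 0))
  sim <- simulate_2dtpp(cfg)
  # raw generator-level fold changes: treated intensity over the matched vehicle
  raw_phi <- function(p, temp, conc, r) {
    id <- sprintf("P%04d", p)
    v <- function(cc) sim$quant$value[sim$quant$protein_id == id &
      sim$quant$sample_id == sprintf("2D_r%d_T%g_c%g", r, temp, cc)]
    v(conc) / v(0)
  }
  for (p in seq_len(6)) {
    for (temp in cfg$temperatures[c(2, 5, 9)]) {
      phi_mid <- raw_phi(p, temp, 0.01, 1)   # 0.01 mM = 1e-5 M = true EC50
      phi_sat <- raw_phi(p, temp, 10, 1)
      s_sat <- 1 / (1 + exp(-(log10(10 / 1000) + 5)))
      # both doses share (amp-1)*ramp: phi_mid - 1 = half the full amplitude
      expect_equal(phi_mid - 1, (phi_sat - 1) / s_sat * 0.5, tolerance = 1e-9)
      # midpoint identity: phi at the EC50 = (c + d)/2 with c = 1
      d_full <- 1 + (phi_sat - 1) / s_sat
      expect_equal(phi_mid, (1 + d_full) / 2, tolerance = 1e-9)
    }
  }
})

test_that("SPP mass balance: SDS/NP40 ratio and saturation bound follow the insoluble fraction", {
  cfg <- sim_config("SPP", n_proteins = 30, seed = 3, noise_cv = 0,
                    insoluble_proteome_fraction = 1,
                    insoluble_fraction_range = c(0.6, 0.6),
                    class_fractions = c(null = 0.5, solubilized = 0.5, desolubilized = 0),
                    pec50_range = c(6, 6))
  sim <- simulate_spp(cfg)
  # raw generator-level values, one matrix per sample
  val <- function(tag) {
    q <- sim$quant[sim$quant$sample_id == tag, ]
    q$value[order(q$protein_id)]
  }
  sds <- val("SPP_r1_SDS_c0"); veh <- val("SPP_r1_NP40_c0"); top <- val("SPP_r1_NP40_c10")
  expect_equal(sds / veh, rep(1 / 0.4, 30), tolerance = 1e-9)
  # full release at a near-saturating dose approaches 1/(1 - insoluble_fraction)
  sol <- sim$truth$effect_class[order(sim$truth$protein_id)] == "solubilized"
  expect_true(all(top[sol] / veh[sol] > 0.95 * 2.5 & top[sol] / veh[sol] <= 2.5 + 1e-9))
  # null proteins stay at fold change 1 at every dose
  expect_equal(top[!sol] / veh[!sol], rep(1, sum(!sol)), tolerance = 1e-9)
  # NP40 never exceeds SDS in expectation (mass conservation)
  expect_true(all(top <= sds + 1e-9))
})

test_that("TPP-TR profiles melt through 0.5 at the true Tm and complexes share profiles", {
  cfg <- sim_config("TPP_TR", n_proteins = 12, seed = 4, noise_cv = 0,
                    plateau_range = c(0.05, 0.05), melt_slope_a = 1100,
                    n_complexes = 2, subunits_per_complex = 5, complex_jitter_sd = 0,
                    class_fractions = c(null = 1, stabilized = 0, destabilized = 0))
  sim <- simulate_tpp_tr(cfg)
  expect_error(simulate_tpp_tr(sim_config("TPP_TR", temperatures = c(40, 39, 45))),
               "strictly increasing")
  res <- tpp_tr(sim$quant, sim$meta, quick_cfg())
  prof <- res$profiles[["vehicle_1"]]
  tt <- res$temperatures
  for (p in 1:12) {
    tm <- sim$truth$true_Tm_vehicle[p]
    # undo the 37-degree normalization using the known generator parameters,
    # then the raw fraction must cross 0.5 exactly at the true Tm
    b <- melt_b_for_tm(1100, tm, 0.05)
    raw <- prof[p, ] * melt_model(37, 1100, b, 0.05)
    expect_equal(unname(raw), melt_model(tt, 1100, b, 0.05), tolerance = 1e-9)
    expect_equal(melt_model(tm, 1100, b, 0.05), 0.5, tolerance = 1e-12)
  }
  # complex members with zero jitter and zero noise have identical profiles
  for (cid in c("C01", "C02")) {
    sub <- which(!is.na(sim$truth$complex_id) & sim$truth$complex_id == cid)
    d <- combn(sub, 2, function(k) comelt_distance(prof[k[1], ], prof[k[2], ]))
    expect_equal(max(d), 0, tolerance = 1e-20)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config("TPP_2D", class_fractions = c(null = 0.5, stabilized = 0.2,
                                                        destabilized = 0.2)),
               "sum to 1")
  expect_error(sim_config("SPP", insoluble_fraction_range = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(sim_config("TPP_2D", noise_cv = -0.1), "noise_cv")
})
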