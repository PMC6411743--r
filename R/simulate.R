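#' Simulation configuration
#'
#' Describes a synthetic TPP-TR, 2D-TPP or SPP experiment: design (proteins,
#' temperatures, concentrations, replicates), effect structure (fractions of
#' proteins per effect class, affinity and amplitude ranges) and a lognormal
#' multiplicative noise level. Defaults reproduce the published designs: the
#' 2D-TPP ATP dose series (0, 0.005, 0.05, 0.5, 2 mM) over ten temperatures
#' (42-60.1 degrees C, one TMT10 plex per pair of neighboring temperatures),
#' the SPP series (vehicle + 0.1-10 mM in NP40, one SDS vehicle) and the
#' TPP-TR gradient (37.0-66.3 degrees C, vehicle vs treated).
#'
#' @param kind `"TPP_2D"`, `"SPP"` or `"TPP_TR"`.
#' @param n_proteins Number of simulated proteins.
#' @param temperatures Temperature gradient in degrees C (strictly
#'   increasing); `NULL` uses the published gradient for `kind`.
#' @param concentrations_mM Ligand doses in mM including the 0 mM vehicle;
#'   `NULL` uses the published series for `kind`.
#' @param n_replicates Number of independent replicates.
#' @param noise_cv Coefficient of variation of the lognormal multiplicative
#'   noise applied to every intensity (0 = noise-free).
#' @param class_fractions Named fractions per effect class, summing to 1.
#'   For `TPP_2D`/`TPP_TR`: `null`, `stabilized`, `destabilized`; for `SPP`:
#'   `null`, `solubilized`, `desolubilized`.
#' @param pec50_range Range of true pEC50 values (-log10 molar) for
#'   dose-responsive proteins.
#' @param effect_amplitude Saturating fold change of a full-strength dose
#'   effect (stabilization amplitude, or reciprocal for destabilization).
#' @param slope_b Slope of the generating dose-response sigmoid on the
#'   log10-molar axis (negative = effect grows with dose).
#' @param tm_range Range of vehicle melting points (degrees C).
#' @param tm_shift_range Range of treatment-induced Tm shifts (degrees C,
#'   applied with positive sign to stabilized and negative to destabilized
#'   proteins in TPP-TR simulations).
#' @param plateau_range Range of the non-denaturing plateau of melting
#'   curves (fraction remaining at high temperature).
#' @param melt_slope_a Steepness parameter of the melting model (Kelvin-like
#'   units of the `a/T` term).
#' @param n_complexes,subunits_per_complex Number of co-melting complexes and
#'   subunits per complex (TPP-TR; members share a melting-profile template).
#' @param complex_jitter_sd Standard deviation (degrees C) of the per-subunit
#'   Tm jitter around the complex template (0 = identical profiles).
#' @param insoluble_proteome_fraction Fraction of proteins with a large
#'   insoluble subpopulation (SPP).
#' @param insoluble_fraction_range,soluble_fraction_range Ranges of the
#'   per-protein insoluble fraction for insoluble- and soluble-class
#'   proteins.
#' @param release_fraction Fraction of the insoluble pool released at a
#'   saturating dose for solubilized proteins (1 = full release).
#' @param desolubilization_fraction Fraction of the soluble pool lost at a
#'   saturating dose for desolubilized proteins.
#' @param qupm_probs Probabilities for the qupm categories 2, 3, 4, "5+";
#'   assigned independently of effect class so permutation strata are
#'   exchangeable under the null.
#' @param seed Integer seed; generators are pure functions of (config, seed).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(kind = c("TPP_2D", "SPP", "TPP_TR"),
                       n_proteins = 200,
                       temperatures = NULL,
                       concentrations_mM = NULL,
                       n_replicates = NULL,
                       noise_cv = 0.1,
                       class_fractions = NULL,
                       pec50_range = NULL,
                       effect_amplitude = 3,
                       slope_b = -1,
                       tm_range = c(45, 55),
                       tm_shift_range = c(2, 5),
                       plateau_range = c(0.02, 0.15),
                       melt_slope_a = 1100,
                       n_complexes = 0,
                       subunits_per_complex = 4,
                       complex_jitter_sd = 0.2,
                       insoluble_proteome_fraction = 0.10,
                       insoluble_fraction_range = c(0.4, 0.9),
                       soluble_fraction_range = c(0, 0.2),
                       release_fraction = 1,
                       desolubilization_fraction = 0.5,
                       qupm_probs = c(0.3, 0.2, 0.15, 0.35),
                       seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(temperatures)) {
    temperatures <- switch(kind,
      TPP_2D = c(42, 44.1, 46.2, 48.1, 50.4, 51.9, 54.0, 56.1, 58.2, 60.1),
      TPP_TR = c(37.0, 40.4, 44.0, 46.9, 49.8, 52.9, 55.5, 58.6, 62.0, 66.3),
      SPP = 37.0)
  }
  if (is.null(concentrations_mM)) {
    concentrations_mM <- switch(kind,
      TPP_2D = c(0, 0.005, 0.05, 0.5, 2),
      SPP = c(0, 0.1, 0.5, 1, 2, 4, 5, 8, 10),
      TPP_TR = c(0, 2))
  }
  if (is.null(n_replicates)) n_replicates <- if (kind == "TPP_TR") 2L else 3L
  if (is.null(class_fractions)) {
    class_fractions <- switch(kind,
      TPP_2D = c(null = 0.88, stabilized = 0.10, destabilized = 0.02),
      TPP_TR = c(null = 0.85, stabilized = 0.10, destabilized = 0.05),
      SPP = NULL) # SPP classes derive from the insoluble-proteome structure
  }
  if (is.null(pec50_range)) {
    # affinities spanning the tested window: doses in molar are 10^x with
    # x in [log10(min dose), log10(max dose)]
    nz <- concentrations_mM[concentrations_mM > 0] / 1000
    pec50_range <- c(-log10(max(nz)), -log10(min(nz)) + 1)
  }
  if (any(diff(temperatures) <= 0)) stopf("temperatures must be strictly increasing")
  if (!is.null(class_fractions) && abs(sum(class_fractions) - 1) > 1e-8)
    stopf("class_fractions must sum to 1")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (any(insoluble_fraction_range < 0 | insoluble_fraction_range > 1) ||
      any(soluble_fraction_range < 0 | soluble_fraction_range > 1))
    stopf("insoluble fractions must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# deterministic class counts (rounded), randomized assignment
#' @noRd
assign_classes <- function(n, fractions) {
  counts <- diff(round(cumsum(c(0, fractions)) * n))
  cls <- rep(names(fractions), counts)
  if (length(cls) < n) cls <- c(cls, rep(names(fractions)[1], n - length(cls)))
  sample(cls[seq_len(n)])
}

# generating dose-response curve: fold change at dose (mM) for a protein with
# affinity pec50, amplitude amp (>1 stabilized, <1 destabilized is handled by
# the caller) and local effect scale `ramp` in [0,1]; dose 0 is the vehicle
# and is exactly 1 by construction
#' @noRd
dose_effect <- function(dose_mM, pec50, amp, ramp, slope_b) {
  if (dose_mM <= 0) return(rep(1, length(pec50)))
  s <- 1 / (1 + exp(slope_b * (log10(dose_mM / 1000) + pec50)))
  s[!is.finite(s)] <- 0 # proteins without a true affinity show no dose effect
  1 + (amp - 1) * ramp * s
}

#' @noRd
sim_truth_frame <- function(ids) {
  data.frame(protein_id = ids, effect_class = "null", true_pEC50 = NA_real_,
             true_Tm_vehicle = NA_real_, true_Tm_shift = 0,
             insoluble_fraction = NA_real_, complex_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate a 2D-TPP experiment
#'
#' Generates reporter intensities for a grid of ligand doses times
#' temperatures. Each protein follows a plateau-sigmoid vehicle melting
#' curve; dose-responsive proteins add a sigmoidal fold change (in log10
#' molar dose) whose amplitude ramps in proportionally to the melted
#' fraction of the vehicle curve, so dose effects appear only at
#' temperatures where the protein has started to denature - the behavior
#' the sliding temperature-window statistic is designed to detect.
#'
#' @param cfg A [sim_config()] with `kind = "TPP_2D"`.
#' @return A list of class `"thermsol_sim"` with `quant` (long intensity
#'   table), `meta` (sample metadata) and `truth` (per-protein ground truth).
#' @export
simulate_2dtpp <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$kind == "TPP_2D")
  if (length(cfg$temperatures) %% 2 != 0)
    stopf("2D layouts need an even number of temperatures (plexes span pairs)")
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  truth <- sim_truth_frame(ids)
  truth$effect_class <- assign_classes(n, cfg$class_fractions)
  eff <- truth$effect_class != "null"
  truth$true_pEC50[eff] <- runif(sum(eff), cfg$pec50_range[1], cfg$pec50_range[2])
  truth$true_Tm_vehicle <- runif(n, cfg$tm_range[1], cfg$tm_range[2])
  plateau <- runif(n, cfg$plateau_range[1], cfg$plateau_range[2])
  qupm <- sample(c("2", "3", "4", "5+"), n, replace = TRUE, prob = cfg$qupm_probs)
  i0 <- rlnorm(n, meanlog = log(1e6), sdlog = 1)

  temps <- cfg$temperatures
  concs <- cfg$concentrations_mM
  reps <- seq_len(cfg$n_replicates)

  # vehicle fraction remaining per protein x temperature, and the effect ramp
  bpar <- melt_b_for_tm(cfg$melt_slope_a, truth$true_Tm_vehicle, plateau)
  frac <- outer(seq_len(n), seq_along(temps), function(i, j)
    melt_model(temps[j], cfg$melt_slope_a, bpar[i], plateau[i]))
  ramp <- 1 - frac

  meta_rows <- list(); quant_rows <- list(); k <- 0
  for (r in reps) {
    for (pl in seq_len(length(temps) / 2)) {
      pair <- temps[c(2 * pl - 1, 2 * pl)]
      plex <- sprintf("r%d_p%d", r, pl)
      labs <- tmt10_labels()
      li <- 0
      for (tt in pair) {
        jt <- match(tt, temps)
        for (cc in concs) {
          li <- li + 1
          sid <- sprintf("2D_r%d_T%g_c%g", r, tt, cc)
          meta_rows[[length(meta_rows) + 1]] <- data.frame(
            sample_id = sid, replicate = r, temperature = tt,
            concentration_mM = cc, detergent = "NP40", tmt_plex = plex,
            tmt_label = labs[li],
            condition = if (cc > 0) "treated" else "vehicle",
            stringsAsFactors = FALSE)
          amp <- ifelse(truth$effect_class == "stabilized", cfg$effect_amplitude,
                 ifelse(truth$effect_class == "destabilized", 1 / cfg$effect_amplitude, 1))
          phi <- dose_effect(cc, truth$true_pEC50, amp, ramp[, jt], cfg$slope_b)
          phi[truth$effect_class == "null"] <- 1
          val <- i0 * frac[, jt] * phi * rnoise(n, cfg$noise_cv)
          k <- k + 1
          quant_rows[[k]] <- data.frame(
            protein_id = ids, sample_id = sid, value = val,
            value_kind = "intensity", qupm = qupm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(quant = do.call(rbind, quant_rows),
              meta = do.call(rbind, meta_rows), truth = truth,
              kind = "TPP_2D", cfg = cfg)
  class(out) <- "thermsol_sim"
  out
}

#' Simulate an SPP experiment
#'
#' Generates one TMT10 plex per replicate: an SDS-solubilized vehicle
#' carrying each protein's total abundance, an NP40 vehicle carrying its
#' soluble share `(1 - insoluble_fraction)`, and eight NP40 dose samples in
#' which solubilized proteins release a sigmoidal share of their insoluble
#' pool (and desolubilized proteins lose part of their soluble pool). Mass
#' balance holds in expectation: the NP40 signal never exceeds the SDS
#' signal.
#'
#' @param cfg A [sim_config()] with `kind = "SPP"`.
#' @inherit simulate_2dtpp return
#' @export
simulate_spp <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$kind == "SPP")
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  truth <- sim_truth_frame(ids)

  insol <- runif(n) < cfg$insoluble_proteome_fraction
  truth$insoluble_fraction <- ifelse(insol,
    runif(n, cfg$insoluble_fraction_range[1], cfg$insoluble_fraction_range[2]),
    runif(n, cfg$soluble_fraction_range[1], cfg$soluble_fraction_range[2]))
  # solubilized proteins are drawn from the insoluble proteome; a small set of
  # (any) proteins loses solubility with dose
  idx_ins <- which(insol)
  n_sol <- round(length(idx_ins) * 0.25)
  if (!is.null(cfg$class_fractions) && "solubilized" %in% names(cfg$class_fractions))
    n_sol <- round(n * cfg$class_fractions[["solubilized"]])
  sol_idx <- if (n_sol > 0) sample(idx_ins, min(n_sol, length(idx_ins))) else integer(0)
  truth$effect_class[sol_idx] <- "solubilized"
  n_des <- round(n * 0.01)
  if (!is.null(cfg$class_fractions) && "desolubilized" %in% names(cfg$class_fractions))
    n_des <- round(n * cfg$class_fractions[["desolubilized"]])
  des_pool <- setdiff(which(truth$insoluble_fraction < 0.5), sol_idx)
  des_idx <- if (n_des > 0) sample(des_pool, min(n_des, length(des_pool))) else integer(0)
  truth$effect_class[des_idx] <- "desolubilized"
  eff <- truth$effect_class != "null"
  truth$true_pEC50[eff] <- runif(sum(eff), cfg$pec50_range[1], cfg$pec50_range[2])

  qupm <- sample(c("2", "3", "4", "5+"), n, replace = TRUE, prob = cfg$qupm_probs)
  i0 <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
  concs <- sort(cfg$concentrations_mM)
  if (!0 %in% concs) stopf("SPP concentrations must include the 0 mM vehicle")

  meta_rows <- list(); quant_rows <- list(); k <- 0
  for (r in seq_len(cfg$n_replicates)) {
    plex <- sprintf("r%d", r)
    labs <- tmt10_labels()
    li <- 0
    for (cc in concs) {
      li <- li + 1
      sid <- sprintf("SPP_r%d_NP40_c%g", r, cc)
      meta_rows[[length(meta_rows) + 1]] <- data.frame(
        sample_id = sid, replicate = r, temperature = 37,
        concentration_mM = cc, detergent = "NP40", tmt_plex = plex,
        tmt_label = labs[li],
        condition = if (cc > 0) "treated" else "vehicle", stringsAsFactors = FALSE)
      ins <- truth$insoluble_fraction
      s <- ifelse(cc > 0 & eff,
                  1 / (1 + exp(cfg$slope_b * (log10(cc / 1000) - (-truth$true_pEC50)))), 0)
      soluble <- (1 - ins) +
        ifelse(truth$effect_class == "solubilized", ins * cfg$release_fraction * s, 0) -
        ifelse(truth$effect_class == "desolubilized",
               (1 - ins) * cfg$desolubilization_fraction * s, 0)
      val <- i0 * soluble * rnoise(n, cfg$noise_cv)
      k <- k + 1
      quant_rows[[k]] <- data.frame(protein_id = ids, sample_id = sid, value = val,
                                    value_kind = "intensity", qupm = qupm,
                                    stringsAsFactors = FALSE)
    }
    sid <- sprintf("SPP_r%d_SDS_c0", r)
    meta_rows[[length(meta_rows) + 1]] <- data.frame(
      sample_id = sid, replicate = r, temperature = 37, concentration_mM = 0,
      detergent = "SDS", tmt_plex = plex, tmt_label = labs[10],
      condition = "vehicle", stringsAsFactors = FALSE)
    k <- k + 1
    quant_rows[[k]] <- data.frame(protein_id = ids, sample_id = sid,
                                  value = i0 * rnoise(n, cfg$noise_cv),
                                  value_kind = "intensity", qupm = qupm,
                                  stringsAsFactors = FALSE)
  }
  out <- list(quant = do.call(rbind, quant_rows), meta = do.call(rbind, meta_rows),
              truth = truth, kind = "SPP", cfg = cfg)
  class(out) <- "thermsol_sim"
  out
}

#' Simulate a TPP-TR experiment
#'
#' Generates vehicle and treated melting profiles over the temperature
#' gradient. Fractions follow the plateau-sigmoid melting model; treated
#' profiles of stabilized (destabilized) proteins shift their Tm up (down)
#' by the ground-truth shift. Complex subunits share one profile template
#' plus a small Tm jitter.
#'
#' @param cfg A [sim_config()] with `kind = "TPP_TR"`.
#' @inherit simulate_2dtpp return
#' @export
simulate_tpp_tr <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$kind == "TPP_TR")
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  truth <- sim_truth_frame(ids)
  truth$effect_class <- assign_classes(n, cfg$class_fractions)
  truth$true_Tm_vehicle <- runif(n, cfg$tm_range[1], cfg$tm_range[2])
  shift <- runif(n, cfg$tm_shift_range[1], cfg$tm_shift_range[2])
  truth$true_Tm_shift <- ifelse(truth$effect_class == "stabilized", shift,
                         ifelse(truth$effect_class == "destabilized", -shift, 0))
  plateau <- runif(n, cfg$plateau_range[1], cfg$plateau_range[2])

  # complexes: subunits drawn from null proteins, sharing the template Tm and
  # plateau of their first member plus jitter
  if (cfg$n_complexes > 0) {
    pool <- which(truth$effect_class == "null")
    need <- cfg$n_complexes * cfg$subunits_per_complex
    if (length(pool) < need) stopf("not enough null proteins for %d complexes", cfg$n_complexes)
    members <- sample(pool, need)
    for (ci in seq_len(cfg$n_complexes)) {
      sub <- members[((ci - 1) * cfg$subunits_per_complex + 1):(ci * cfg$subunits_per_complex)]
      truth$complex_id[sub] <- sprintf("C%02d", ci)
      tm0 <- truth$true_Tm_vehicle[sub[1]]
      p0 <- plateau[sub[1]]
      truth$true_Tm_vehicle[sub] <- tm0 + rnorm(length(sub), 0, cfg$complex_jitter_sd)
      plateau[sub] <- p0
    }
  }

  qupm <- sample(c("2", "3", "4", "5+"), n, replace = TRUE, prob = cfg$qupm_probs)
  i0 <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
  temps <- cfg$temperatures
  treat_conc <- max(cfg$concentrations_mM)

  meta_rows <- list(); quant_rows <- list(); k <- 0
  for (r in seq_len(cfg$n_replicates)) {
    for (cond in c("vehicle", "treated")) {
      tm <- truth$true_Tm_vehicle + if (cond == "treated") truth$true_Tm_shift else 0
      bpar <- melt_b_for_tm(cfg$melt_slope_a, tm, plateau)
      plex <- sprintf("r%d_%s", r, cond)
      labs <- tmt10_labels()
      for (j in seq_along(temps)) {
        sid <- sprintf("TR_r%d_%s_T%g", r, cond, temps[j])
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          sample_id = sid, replicate = r, temperature = temps[j],
          concentration_mM = if (cond == "treated") treat_conc else 0,
          detergent = "none", tmt_plex = plex,
          tmt_label = labs[(j - 1) %% 10 + 1], condition = cond,
          stringsAsFactors = FALSE)
        frac <- melt_model(temps[j], cfg$melt_slope_a, bpar, plateau)
        k <- k + 1
        quant_rows[[k]] <- data.frame(
          protein_id = ids, sample_id = sid,
          value = i0 * frac * rnoise(n, cfg$noise_cv),
          value_kind = "intensity", qupm = qupm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(quant = do.call(rbind, quant_rows), meta = do.call(rbind, meta_rows),
              truth = truth, kind = "TPP_TR", cfg = cfg)
  class(out) <- "thermsol_sim"
  out
}

#' @export
print.thermsol_sim <- function(x, ...) {
  cat(sprintf("synthetic %s dataset: %d proteins, %d samples, noise CV %g\n",
              x$kind, length(unique(x$quant$protein_id)), nrow(x$meta),
              x$cfg$noise_cv))
  tab <- table(x$truth$effect_class)
  cat("  effect classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
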