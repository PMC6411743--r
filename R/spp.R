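#' @name spp-pipeline
#' @title Solubility proteome profiling: normalization, insoluble-proteome
#'   classification and dose-dependent solubilization detection
#'
#' @description
#' SPP compares, per protein, the abundance extracted with a mild detergent
#' (NP40) across ligand doses to the vehicle, and the strong-detergent (SDS)
#' vehicle to the NP40 vehicle. The SDS/NP40 vehicle ratio measures the
#' insoluble subpopulation; a dose-response sigmoid fitted jointly across
#' replicates against an intercept null model yields an F-statistic per
#' protein, assessed with the same permutation FDR machinery as the 2D-TPP
#' analysis (strata reduce to qupm bins, since SPP is performed at a single
#' temperature) and gated on a minimal median fold change.
NULL

# run expr under a fixed RNG state, restoring the caller's state afterwards;
# keeps the LTS calibration (which samples subsets internally) deterministic
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generalized log2 transform and its inverse
#'
#' `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`: approximately `log2(x)`
#' for `x >> c` and approximately linear near zero, so the variance of
#' multiplicative + additive noise is flattened across the intensity range.
#'
#' @param x Numeric vector (calibrated intensities).
#' @param c Glog shoulder parameter (> 0); intensities well above `c` are on
#'   the log scale.
#' @return Transformed (resp. back-transformed) values.
#' @export
glog2 <- function(x, c = 1) log2((x + sqrt(x^2 + c^2)) / 2)

#' @rdname glog2
#' @param z Values on the glog2 scale.
#' @export
glog2_inv <- function(z, c = 1) {
  u <- 2^z
  u - c^2 / (4 * u)
}

#' Normalize an SPP quant table
#'
#' A simplified variance-stabilizing normalization across replicates and
#' conditions: each sample is calibrated onto the row-median reference by a
#' robust affine fit (least trimmed squares), transformed with [glog2()]
#' (shoulder set to the 5% quantile of the calibrated reference),
#' back-transformed from log2 space, and fold changes are computed against
#' the NP40 vehicle of the same replicate. Samples with all-zero intensity
#' are excluded and logged.
#'
#' @param quant Long SPP quant table (intensities).
#' @param meta Sample metadata describing an SPP layout.
#' @param cfg An [analysis_config()].
#' @return An object of class `"spp_table"`: `fc` (protein x dose x
#'   replicate array of NP40 fold changes vs vehicle, dose index 1 =
#'   vehicle), `sds_ratio` (protein x replicate matrix of SDS/NP40 vehicle
#'   ratios), `normalized` (long table of calibrated intensities),
#'   `doses_mM`, `proteins`, `qupm`.
#' @export
normalize_spp <- function(quant, meta, cfg = analysis_config()) {
  layout <- validate_layout(meta, "SPP")
  proteins <- unique(quant$protein_id)
  P <- length(proteins)
  S <- nrow(meta)
  m <- matrix(NA_real_, P, S, dimnames = list(proteins, meta$sample_id))
  m[cbind(match(quant$protein_id, proteins), match(quant$sample_id, meta$sample_id))] <-
    quant$value
  qupm <- bin_qupm(quant$qupm[match(proteins, quant$protein_id)])

  dead <- which(colSums(m, na.rm = TRUE) == 0)
  if (length(dead)) {
    ts_log(cfg$verbose, "excluding %d all-zero sample(s): %s", length(dead),
           paste(colnames(m)[dead], collapse = ", "))
    m <- m[, -dead, drop = FALSE]
    meta <- meta[-dead, , drop = FALSE]
  }

  ref <- apply(m, 1, median, na.rm = TRUE)
  cal <- m
  for (k in seq_len(ncol(m))) {
    ok <- is.finite(m[, k]) & is.finite(ref)
    if (sum(ok) < 10) next
    fit <- with_local_seed(1L, MASS::lqs(m[ok, k] ~ ref[ok], method = "lts"))
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    if (!is.finite(b) || b <= 0) { # degenerate calibration: fall back to scale-only
      b <- median(m[ok, k] / ref[ok], na.rm = TRUE); a <- 0
    }
    cal[, k] <- (m[, k] - a) / b
  }
  shoulder <- max(quantile(ref, 0.05, na.rm = TRUE), .Machine$double.eps)
  norm <- glog2_inv(glog2(cal, shoulder), shoulder)

  reps <- sort(unique(meta$replicate))
  doses <- sort(unique(meta$concentration_mM[meta$detergent == "NP40"]))
  fc <- array(NA_real_, c(P, length(doses), length(reps)))
  sds_ratio <- matrix(NA_real_, P, length(reps))
  for (ri in seq_along(reps)) {
    sel_v <- meta$detergent == "NP40" & meta$concentration_mM == 0 & meta$replicate == reps[ri]
    veh <- norm[, which(sel_v)]
    for (di in seq_along(doses)) {
      sel <- meta$detergent == "NP40" & meta$concentration_mM == doses[di] &
        meta$replicate == reps[ri]
      fc[, di, ri] <- norm[, which(sel)] / veh
    }
    sel_s <- meta$detergent == "SDS" & meta$replicate == reps[ri]
    sds_ratio[, ri] <- norm[, which(sel_s)] / veh
  }
  fc[, 1, ] <- ifelse(is.na(fc[, 1, ]), NA_real_, 1)

  norm_long <- data.frame(
    protein_id = rep(proteins, times = ncol(norm)),
    sample_id = rep(colnames(norm), each = P),
    value = as.vector(norm), value_kind = "intensity",
    qupm = rep(qupm, times = ncol(norm)), stringsAsFactors = FALSE)
  structure(list(fc = fc, sds_ratio = sds_ratio, normalized = norm_long,
                 doses_mM = doses, proteins = proteins, qupm = qupm,
                 replicates = reps),
            class = "spp_table")
}

#' @export
print.spp_table <- function(x, ...) {
  cat(sprintf("SPP table: %d proteins, %d doses, %d replicate(s)\n",
              length(x$proteins), length(x$doses_mM) - 1, length(x$replicates)))
  invisible(x)
}

#' Classify the insoluble proteome
#'
#' A protein belongs to the insoluble proteome when its SDS-extracted
#' vehicle abundance is at least 50% higher than its NP40-extracted vehicle
#' abundance, i.e. the replicate-median SDS/NP40 ratio is `>=` the
#' configured `insoluble_ratio` (boundary inclusive). A zero NP40 vehicle
#' yields an infinite ratio and an insoluble call, flagged.
#'
#' @param spp An `"spp_table"` from [normalize_spp()].
#' @param cfg An [analysis_config()].
#' @return A data frame: `protein_id`, `sds_np40_ratio`, `insoluble`,
#'   `ratio_flagged`.
#' @export
classify_insoluble <- function(spp, cfg = analysis_config()) {
  ratio <- apply(spp$sds_ratio, 1, median, na.rm = TRUE)
  flagged <- !is.finite(ratio) & !is.na(ratio)
  data.frame(protein_id = spp$proteins, sds_np40_ratio = ratio,
             insoluble = !is.na(ratio) & ratio >= cfg$insoluble_ratio,
             ratio_flagged = flagged, stringsAsFactors = FALSE)
}

#' F-statistic for a dose-dependent solubility change
#'
#' Fits one dose-response sigmoid jointly across the pooled replicates of a
#' protein and one joint intercept model, and returns
#' `F = (RSS_H0 - RSS_H1)/RSS_H1` (zero on non-convergence) together with
#' the sigmoid fit.
#'
#' @param concentrations_mM Dose of each point (mM; 0 = vehicle), pooled
#'   across replicates.
#' @param fold_changes NP40 fold change vs vehicle of each point.
#' @param cfg An [analysis_config()].
#' @return A list with `F` and `fit` (a `"dr_fit"`).
#' @export
spp_score <- function(concentrations_mM, fold_changes, cfg = analysis_config()) {
  y <- if (cfg$fit_on_log) log2(fold_changes) else fold_changes
  if (cfg$fit_on_log) y <- y - min(y) + 1 # keep responses positive on the log scale
  s <- to_dose_series(concentrations_mM, y, cfg$min_points_per_fit,
                      cfg$include_vehicle_point)
  if (is.null(s)) return(list(F = 0, fit = NULL))
  fit <- fit_sigmoid(s)
  Fv <- if (fit$converged) f_component(fit$rss_null, fit$rss) else 0
  list(F = Fv, fit = fit)
}

# per-protein scores + direction + pEC50 from an fc array [P x doses x reps];
# only proteins passing the fold-change trigger are fitted
#' @noRd
spp_scores_engine <- function(fcarr, doses, qupm, cfg, keep_e = FALSE) {
  P <- dim(fcarr)[1]; R <- dim(fcarr)[3]
  nd <- length(doses) - 1
  med <- matrix(NA_real_, P, nd)
  for (di in seq_len(nd))
    med[, di] <- apply(fcarr[, di + 1, , drop = FALSE], 1, median, na.rm = TRUE)
  la <- abs(log(med)); la[is.na(la)] <- -Inf
  k <- max.col(la, ties.method = "first")
  mmfc <- med[cbind(seq_len(P), k)]
  mmfc[!is.finite(la[cbind(seq_len(P), k)])] <- NA_real_
  triggered <- !is.na(mmfc) & (mmfc >= cfg$h | mmfc <= 1 / cfg$h)

  nz <- doses[doses > 0]
  pseudo <- min(nz) / 100
  x1 <- log10(c(pseudo, nz) / 1000)
  if (!cfg$include_vehicle_point) x1 <- x1[-1]
  xfull <- rep(x1, R)

  Fv <- numeric(P); ev <- rep(NA_real_, P)
  idx <- which(triggered)
  if (length(idx)) {
    xs <- list(); ys <- list()
    for (p in idx) {
      y <- as.vector(sapply(seq_len(R), function(r) {
        v <- fcarr[p, , r]
        if (cfg$include_vehicle_point) v else v[-1]
      }))
      if (cfg$fit_on_log) { y <- log2(y); y <- y - min(y, na.rm = TRUE) + 1 }
      ok <- is.finite(y)
      xs[[length(xs) + 1]] <- xfull[ok]
      ys[[length(ys) + 1]] <- y[ok]
    }
    short <- lengths(ys) < cfg$min_points_per_fit
    fits <- fit_sigmoid_batch(xs[!short], ys[!short])
    ii <- idx[!short]
    for (i in seq_along(ii)) {
      y <- ys[!short][[i]]
      rss0 <- sum((y - mean(y))^2)
      conv <- fits[i, "converged"] > 0 && is.finite(fits[i, "rss"]) &&
        fits[i, "rss"] <= rss0 + 1e-12
      if (conv) {
        Fv[ii[i]] <- f_component(rss0, fits[i, "rss"])
        ev[ii[i]] <- fits[i, "e"]
      }
    }
  }
  Fv[is.infinite(Fv)] <- max(c(Fv[is.finite(Fv)], 1))
  list(F = Fv, e = ev, mmfc = mmfc, triggered = triggered)
}

#' Call SPP hits with permutation FDR and assign pEC50,s
#'
#' Proteins showing at least the gate fold change at one or more doses
#' (median across replicates `>= h`, or `<= 1/h` for loss of solubility)
#' are fitted and scored; the FDR is estimated from permutations of the
#' fold changes across proteins and doses within qupm strata (vehicle
#' reference untouched). Hits require both FDR at or below the cutoff and
#' the fold-change gate; hits get `pEC50_s = -e` from the joint fit,
#' clipped to the tested dose range plus one decade on either side.
#'
#' @param spp An `"spp_table"`.
#' @param cfg An [analysis_config()].
#' @return A data frame: `protein_id`, `max_median_fc`, `F`, `fdr`, `hit`,
#'   `direction`, `pEC50_s`; the FDR table is attached as attribute
#'   `fdr_table`.
#' @export
spp_call_hits <- function(spp, cfg = analysis_config()) {
  eng <- spp_scores_engine(spp$fc, spp$doses_mM, spp$qupm, cfg)
  perm <- vector("list", cfg$n_permutations)
  strata <- split(seq_along(spp$qupm), spp$qupm)
  for (b in seq_len(cfg$n_permutations)) {
    set.seed(cfg$seed + b)
    pf <- spp$fc
    flat <- matrix(pf[, -1, , drop = FALSE], nrow = dim(pf)[1]) # P x (doses*reps)
    for (s in strata) {
      v <- as.vector(flat[s, ])
      keep <- !is.na(v)
      v[keep] <- v[keep][sample.int(sum(keep))]
      flat[s, ] <- v
    }
    pf[, -1, ] <- array(flat, c(dim(pf)[1], dim(pf)[2] - 1, dim(pf)[3]))
    perm[[b]] <- spp_scores_engine(pf, spp$doses_mM, spp$qupm, cfg)$F
  }
  fdr_tab <- fdr_estimate(eng$F, perm, cfg)
  fdr <- fdr_at_score(eng$F, fdr_tab)
  nz <- spp$doses_mM[spp$doses_mM > 0] / 1000
  clip <- c(-log10(max(nz)) - 1, -log10(min(nz)) + 1)
  hit <- !is.na(fdr) & fdr <= cfg$fdr_cutoff & eng$F > 0 & eng$triggered
  out <- data.frame(
    protein_id = spp$proteins,
    max_median_fc = eng$mmfc,
    F = eng$F, fdr = fdr, hit = hit,
    direction = ifelse(!hit, "none",
                ifelse(eng$mmfc >= cfg$h, "solubilized", "desolubilized")),
    pEC50_s = ifelse(hit, pmin(pmax(-eng$e, clip[1]), clip[2]), NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "fdr_table") <- fdr_tab
  out
}

#' Run the full SPP analysis
#'
#' Normalizes intensities, classifies the insoluble proteome, detects
#' dose-dependent solubility changes with the permutation FDR and assigns
#' pEC50,s values.
#'
#' @param quant Long SPP quant table (intensities).
#' @param meta Sample metadata describing an SPP layout.
#' @param cfg An [analysis_config()].
#' @return An object of class `"spp_result"` with `profiles` (per-protein
#'   data frame combining the insolubility classification and hit calls),
#'   `fdr_table`, `spp` (the normalized table) and `cfg`.
#' @examples
#' sim <- simulate_spp(sim_config("SPP", n_proteins = 40, seed = 3))
#' res <- spp(sim$quant, sim$meta, analysis_config(n_permutations = 10, seed = 3))
#' head(res$profiles)
#' @export
spp <- function(quant, meta, cfg = analysis_config()) {
  tab <- normalize_spp(quant, meta, cfg)
  ins <- classify_insoluble(tab, cfg)
  hits <- spp_call_hits(tab, cfg)
  profiles <- merge(ins, hits, by = "protein_id", sort = FALSE)
  profiles <- profiles[match(tab$proteins, profiles$protein_id), ]
  rownames(profiles) <- NULL
  ts_log(cfg$verbose, "SPP: %d proteins, %d insoluble, %d hits",
         nrow(profiles), sum(profiles$insoluble), sum(profiles$hit))
  structure(list(profiles = profiles, fdr_table = attr(hits, "fdr_table"),
                 spp = tab, cfg = cfg),
            class = "spp_result")
}

#' @export
print.spp_result <- function(x, ...) {
  p <- x$profiles
  cat(sprintf("SPP analysis: %d proteins, %d insoluble (SDS/NP40 >= %g), %d hits at FDR <= %g\n",
              nrow(p), sum(p$insoluble), x$cfg$insoluble_ratio,
              sum(p$hit), x$cfg$fdr_cutoff))
  tab <- table(p$direction[p$hit])
  if (length(tab))
    cat("  directions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
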