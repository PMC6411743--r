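#' @name tpp2d-pipeline
#' @title 2D-TPP analysis: preprocessing, sliding-window F-statistics,
#'   permutation FDR and pEC50 assignment
#'
#' @description
#' The 2D-TPP analysis detects dose-dependent (de)stabilization from a grid
#' of ligand doses times temperatures. Per protein, replicate and pair of
#' neighboring temperatures, a four-parameter logistic dose-response model
#' and an intercept null model are fitted to the pooled fold changes of the
#' window; the per-replicate statistic `(RSS_H0 - RSS_H1)/RSS_H1` is
#' median-aggregated over replicates into a window score, and window scores
#' of windows whose extreme fold change passes the gate (`> h` or `< 1/h`)
#' are combined on the log scale into a per-protein score. Significance is
#' assessed by permuting fold changes across proteins and doses within
#' (temperature x qupm) strata and averaging `2 v_b / (r + v_b)` over
#' permutations at every candidate threshold.
NULL

# ---- fold-change cube -------------------------------------------------------

# internal representation of a FoldChangeTable: a [protein x temperature x
# concentration x replicate] array of fold changes vs the matched vehicle
# (concentration index 1), plus per-protein qupm strata
#' @noRd
new_fc_table <- function(phi, proteins, temperatures, concentrations, replicates, qupm) {
  structure(list(phi = phi, proteins = proteins, temperatures = temperatures,
                 concentrations = concentrations, replicates = replicates,
                 qupm = qupm),
            class = "fc_table")
}

#' @export
print.fc_table <- function(x, ...) {
  cat(sprintf("fold-change table: %d proteins x %d temperatures x %d concentrations x %d replicate(s)\n",
              length(x$proteins), length(x$temperatures),
              length(x$concentrations), length(x$replicates)))
  invisible(x)
}

#' @export
as.data.frame.fc_table <- function(x, ...) {
  g <- expand.grid(protein_id = x$proteins, temperature = x$temperatures,
                   concentration_mM = x$concentrations, replicate = x$replicates,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$fold_change <- as.vector(x$phi)
  g$qupm <- x$qupm[match(g$protein_id, x$proteins)]
  g
}

#' Preprocess a 2D-TPP quant table into fold changes
#'
#' Computes, per protein, the ratio of the treated intensity to the vehicle
#' intensity at the same temperature, plex and replicate, then median-centers
#' the log2 fold changes within each TMT label (each label is one sample of
#' one plex) and re-pins the vehicle at exactly 1. If the vehicle is missing
#' at a temperature of a plex, that temperature is dropped for the affected
#' plex and logged.
#'
#' @param quant Long quant table (see [read_quant_table()]); intensities or
#'   precomputed fold changes.
#' @param meta Sample metadata.
#' @param cfg An [analysis_config()].
#' @return An `"fc_table"` object; convert with `as.data.frame()` for the
#'   long view.
#' @export
preprocess_2dtpp <- function(quant, meta, cfg = analysis_config()) {
  layout <- validate_layout(meta, "TPP_2D")
  temps <- layout$temperatures
  concs <- layout$concentrations # sorted; [1] == 0 vehicle
  reps <- sort(unique(meta$replicate))
  proteins <- unique(quant$protein_id)
  P <- length(proteins)

  mi <- match(quant$sample_id, meta$sample_id)
  pi <- match(quant$protein_id, proteins)
  ti <- match(meta$temperature[mi], temps)
  ci <- match(meta$concentration_mM[mi], concs)
  ri <- match(meta$replicate[mi], reps)

  intens <- array(NA_real_, c(P, length(temps), length(concs), length(reps)))
  intens[cbind(pi, ti, ci, ri)] <- quant$value
  qupm <- bin_qupm(quant$qupm[match(proteins, quant$protein_id)])

  is_fc <- all(quant$value_kind == "fold_change")
  if (is_fc) {
    phi <- intens
  } else {
    veh <- intens[, , 1, , drop = FALSE]
    dropped <- sum(is.na(veh[, , 1, ]) & apply(!is.na(intens), c(1, 2, 4), any))
    if (dropped > 0)
      ts_log(cfg$verbose, "dropped %d protein x temperature x replicate cells lacking a vehicle", dropped)
    phi <- intens / veh[, , rep(1, length(concs)), , drop = FALSE]
  }

  # median normalization within one TMT label: each (temperature,
  # concentration, replicate) cell is one labelled sample
  lphi <- log2(phi)
  for (jt in seq_along(temps)) for (jc in seq_along(concs)) for (jr in seq_along(reps)) {
    v <- lphi[, jt, jc, jr]
    m <- median(v, na.rm = TRUE)
    if (is.finite(m)) lphi[, jt, jc, jr] <- v - m
  }
  phi <- 2^lphi
  phi[, , 1, ] <- ifelse(is.na(phi[, , 1, ]), NA_real_, 1) # vehicle re-pinned

  ts_log(cfg$verbose, "2D preprocessing: %d proteins in, %d with complete vehicle anchors",
         P, sum(apply(!is.na(phi[, , 1, , drop = FALSE]), 1, all)))
  new_fc_table(phi, proteins, temps, concs, reps, qupm)
}

# ---- window scores ----------------------------------------------------------

# extreme fold change (largest |log|) per protein for a window, plus gating
#' @noRd
window_phimax <- function(phi, j, h) {
  d <- dim(phi) # P, T, C, R
  m <- cbind(matrix(phi[, j, -1, ], d[1]), matrix(phi[, j + 1, -1, ], d[1]))
  la <- abs(log(m))
  la[is.na(la)] <- -Inf
  k <- max.col(la, ties.method = "first")
  pm <- m[cbind(seq_len(d[1]), k)]
  pm[!is.finite(la[cbind(seq_len(d[1]), k)])] <- NA_real_
  pm
}

# dose axis template for a two-temperature window
#' @noRd
window_x <- function(concs, include_vehicle) {
  nz <- concs[concs > 0]
  pseudo <- min(nz) / 100
  x1 <- log10(c(pseudo, nz) / 1000)
  if (!include_vehicle) x1 <- x1[-1]
  list(x = rep(x1, 2), pseudo_x = log10(pseudo / 1000), keep_vehicle = include_vehicle)
}

#' Sliding-window F-statistics for a 2D-TPP fold-change table
#'
#' For every protein and pair of adjacent temperatures, pools the
#' (dose, fold change) points of both temperatures per replicate, fits the
#' sigmoid and intercept models and computes the per-replicate component
#' `(RSS_H0 - RSS_H1)/RSS_H1`; the window score is the median over
#' replicates. Replicates with fewer than `min_points_per_fit` points are
#' excluded from the median; infinite components (perfect sigmoid fits) are
#' replaced by the largest finite component in the dataset before
#' aggregation. The extreme fold change of the window (`phi_max`, the value
#' with the largest absolute log) is recorded for gating.
#'
#' @param fc An `"fc_table"` from [preprocess_2dtpp()].
#' @param cfg An [analysis_config()].
#' @param gated_only Only fit windows whose `phi_max` passes the gate
#'   (`> h` or `< 1/h`). Ungated windows never contribute to the combined
#'   score, so this is a pure optimization used by [tpp2d()]; their `F` is
#'   reported as `NA`.
#' @return A data frame with one row per protein x window: `protein_id`,
#'   `window`, `t_lo`, `t_hi`, `phi_max`, `gated`, `F`, `n_reps`; per-
#'   replicate components and fitted `e` are attached as attributes
#'   `rep_F` and `rep_e`.
#' @export
window_scores <- function(fc, cfg = analysis_config(), gated_only = FALSE) {
  stopifnot(inherits(fc, "fc_table"))
  phi <- fc$phi
  d <- dim(phi)
  P <- d[1]; Tn <- d[2]; Cn <- d[3]; R <- d[4]
  if (Tn < 2) stopf("need at least 2 temperatures for sliding windows")
  xt <- window_x(fc$concentrations, cfg$include_vehicle_point)

  rows <- list(); xs <- list(); ys <- list(); map <- list()
  for (j in seq_len(Tn - 1)) {
    pm <- window_phimax(phi, j, cfg$h)
    gated <- !is.na(pm) & (pm > cfg$h | pm < 1 / cfg$h)
    fit_idx <- if (gated_only) which(gated) else seq_len(P)
    rows[[j]] <- data.frame(protein_id = fc$proteins, window = j,
                            t_lo = fc$temperatures[j], t_hi = fc$temperatures[j + 1],
                            phi_max = pm, gated = gated, stringsAsFactors = FALSE)
    for (p in fit_idx) {
      for (r in seq_len(R)) {
        y1 <- phi[p, j, , r]; y2 <- phi[p, j + 1, , r]
        if (cfg$include_vehicle_point) {
          y <- c(y1[1], y1[-1], y2[1], y2[-1])
        } else {
          y <- c(y1[-1], y2[-1])
        }
        ok <- is.finite(y)
        if (sum(ok) < cfg$min_points_per_fit) next
        xs[[length(xs) + 1]] <- xt$x[ok]
        ys[[length(ys) + 1]] <- y[ok]
        map[[length(map) + 1]] <- c(j, p, r)
      }
    }
  }
  win <- do.call(rbind, rows)
  win_key <- paste(win$window, win$protein_id)

  rep_F <- matrix(NA_real_, nrow(win), R)
  rep_e <- matrix(NA_real_, nrow(win), R)
  if (length(xs)) {
    fits <- fit_sigmoid_batch(xs, ys)
    mp <- do.call(rbind, map)
    rkey <- match(paste(mp[, 1], fc$proteins[mp[, 2]]), win_key)
    for (i in seq_along(xs)) {
      y <- ys[[i]]
      rss0 <- sum((y - mean(y))^2)
      conv <- fits[i, "converged"] > 0 && is.finite(fits[i, "rss"]) &&
        fits[i, "rss"] <= rss0 + 1e-12
      rss1 <- if (conv) fits[i, "rss"] else rss0
      rep_F[rkey[i], mp[i, 3]] <- f_component(rss0, rss1)
      rep_e[rkey[i], mp[i, 3]] <- if (conv) fits[i, "e"] else NA_real_
    }
  }
  # infinity sentinel: a perfect fit would dominate the median; cap at the
  # largest finite component observed in this dataset
  fin <- rep_F[is.finite(rep_F)]
  cap <- if (length(fin)) max(fin, 1) else 1
  rep_F[is.infinite(rep_F)] <- cap

  win$F <- apply(rep_F, 1, function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  win$n_reps <- rowSums(!is.na(rep_F))
  attr(win, "rep_F") <- rep_F
  attr(win, "rep_e") <- rep_e
  win
}

#' Combine window scores into per-protein scores
#'
#' Sums `ln(F)` over the gated windows of each protein (those whose extreme
#' fold change exceeds `h` or falls below `1/h`). By default terms below
#' zero are floored at zero - a window whose sigmoid fit is barely better
#' than the intercept model carries no evidence and should not cancel
#' signal from other windows; set `allow_negative_log_terms` in the config
#' to sum the raw logs. Proteins without gated windows score 0. The
#' direction is `stabilized` when gating fired through `phi_max > h`,
#' `destabilized` through `phi_max < 1/h`; if both fire, the window with
#' the larger `|log2 phi_max|` decides.
#'
#' @param windows Window-score data frame from [window_scores()].
#' @param cfg An [analysis_config()].
#' @return One row per protein: `protein_id`, `F_comb`, `direction`,
#'   `n_gated`, `phi_extreme`.
#' @export
combined_score <- function(windows, cfg = analysis_config()) {
  prot <- unique(windows$protein_id)
  g <- windows[windows$gated & !is.na(windows$F), , drop = FALSE]
  out <- data.frame(protein_id = prot, F_comb = 0, direction = "none",
                    n_gated = 0L, phi_extreme = NA_real_, stringsAsFactors = FALSE)
  if (nrow(g)) {
    terms <- ifelse(g$F > 0, log(g$F), NA_real_)
    if (!cfg$allow_negative_log_terms) terms <- pmax(terms, 0)
    terms[is.na(terms)] <- if (cfg$allow_negative_log_terms) NA_real_ else 0
    sp <- split(seq_len(nrow(g)), g$protein_id)
    for (id in names(sp)) {
      i <- sp[[id]]
      k <- match(id, out$protein_id)
      out$F_comb[k] <- sum(terms[i], na.rm = TRUE)
      out$n_gated[k] <- length(i)
      pm <- g$phi_max[i]
      l2 <- abs(log2(pm))
      out$phi_extreme[k] <- pm[which.max(l2)]
      up <- any(pm > cfg$h); down <- any(pm < 1 / cfg$h)
      out$direction[k] <- if (up && down) {
        if (max(l2[pm > cfg$h]) >= max(l2[pm < 1 / cfg$h])) "stabilized" else "destabilized"
      } else if (up) "stabilized" else "destabilized"
    }
  }
  out
}

# ---- permutation ------------------------------------------------------------

# indices into the phi array grouped by permutation stratum
# (temperature x qupm bin), non-vehicle cells only
#' @noRd
strata_indices <- function(fc) {
  d <- dim(fc$phi)
  idx <- which(array(TRUE, d))
  ai <- arrayInd(idx, d)
  keep <- ai[, 3] != 1 & !is.na(fc$phi[idx])
  idx <- idx[keep]; ai <- ai[keep, , drop = FALSE]
  strat <- paste(ai[, 2], fc$qupm[ai[, 1]])
  split(idx, strat)
}

#' Permute a fold-change table within (temperature x qupm) strata
#'
#' Shuffles all non-vehicle fold changes jointly across proteins, doses and
#' replicates within each stratum of identical temperature and qupm
#' category; vehicle (reference) values are untouched. Each stratum keeps
#' exactly its original multiset of values, so the permuted dataset is
#' exchangeable with the original under the null hypothesis of no
#' dose-dependent effect.
#'
#' @param fc An `"fc_table"`.
#' @param seed Integer seed; the same seed reproduces the permutation.
#' @return A permuted `"fc_table"`.
#' @export
permute_dataset <- function(fc, seed) {
  stopifnot(inherits(fc, "fc_table"))
  set.seed(as.integer(seed))
  strata <- strata_indices(fc)
  phi <- fc$phi
  for (idx in strata) phi[idx] <- phi[idx[sample.int(length(idx))]]
  out <- fc
  out$phi <- phi
  out
}

# ---- FDR --------------------------------------------------------------------

#' Permutation-based FDR over score thresholds
#'
#' For every distinct original score `theta`, counts how many original
#' scores (`r`) and how many scores of each permutation `b` (`v_b`) lie at
#' or above it (ties on the permuted side count as hits, which is
#' conservative), and averages `2 v_b / (r + v_b)` over the `B`
#' permutations; a threshold where both counts are zero contributes 0. The raw curve
#' is monotonized by a cumulative minimum running from the loosest to the
#' most stringent threshold, so the final FDR is non-increasing in the
#' threshold, then clipped to `[0, 1]`.
#'
#' @param original Numeric vector of per-protein scores (or a data frame
#'   with an `F_comb` column).
#' @param permuted List of `B` numeric score vectors from permuted datasets.
#' @param cfg An [analysis_config()].
#' @return A data frame of class `"fdr_table"`: `theta`, `r`, `v_mean`,
#'   `fdr_raw`, `fdr`, ordered by increasing threshold.
#' @export
fdr_estimate <- function(original, permuted, cfg = analysis_config()) {
  if (is.data.frame(original)) original <- original$F_comb
  stopifnot(length(permuted) >= 1)
  th <- sort(unique(original)) # ascending: loosest first
  r <- vapply(th, function(t) sum(original >= t), numeric(1))
  v <- vapply(permuted, function(p) vapply(th, function(t) sum(p >= t), numeric(1)),
              numeric(length(th)))
  v <- matrix(v, nrow = length(th))
  term <- 2 * v / (r + v)
  term[(r + v) == 0] <- 0
  fdr_raw <- rowMeans(term)
  fdr <- pmin(pmax(cummin(fdr_raw), 0), 1)
  out <- data.frame(theta = th, r = r, v_mean = rowMeans(v),
                    fdr_raw = fdr_raw, fdr = fdr)
  class(out) <- c("fdr_table", "data.frame")
  out
}

# FDR of each score at its own threshold
#' @noRd
fdr_at_score <- function(scores, fdr_table) {
  fdr_table$fdr[match(scores, fdr_table$theta)]
}

#' Call hits at an FDR cutoff
#'
#' Hits are proteins whose FDR (at their own score used as the threshold)
#' is at or below the cutoff and whose combined score is nonzero.
#'
#' @param scores Per-protein score data frame from [combined_score()].
#' @param fdr_table An `"fdr_table"` from [fdr_estimate()].
#' @param cfg An [analysis_config()].
#' @return The score data frame augmented with `fdr` and `hit` columns.
#' @export
call_hits <- function(scores, fdr_table, cfg = analysis_config()) {
  scores$fdr <- fdr_at_score(scores$F_comb, fdr_table)
  scores$hit <- !is.na(scores$fdr) & scores$fdr <= cfg$fdr_cutoff & scores$F_comb > 0
  scores
}

# ---- pEC50 ------------------------------------------------------------------

#' Assign pEC50 values to 2D-TPP hits
#'
#' For each hit, finds the lowest temperature at which the gate fold change
#' (`>= h` for stabilized, `<= 1/h` for destabilized) was reached in at
#' least two replicates, fits the dose-response model per replicate in the
#' temperature window starting there, and reports the median of the
#' per-replicate `-e` estimates, clipped to `[min tested pEC50 - 1,
#' pseudo-vehicle pEC50]`. Proteins without a qualifying temperature keep
#' `pEC50 = NA`.
#'
#' @param scores Score data frame with `hit` and `direction` columns (from
#'   [call_hits()]).
#' @param fc The `"fc_table"` the scores were computed from.
#' @param cfg An [analysis_config()].
#' @return `scores` with a `pEC50` column added.
#' @export
assign_pec50 <- function(scores, fc, cfg = analysis_config()) {
  phi <- fc$phi
  d <- dim(phi); Tn <- d[2]; R <- d[4]
  xt <- window_x(fc$concentrations, cfg$include_vehicle_point)
  nzx <- log10(fc$concentrations[fc$concentrations > 0] / 1000)
  clip_lo <- -max(nzx) - 1
  clip_hi <- -xt$pseudo_x
  scores$pEC50 <- NA_real_
  for (k in which(scores$hit)) {
    p <- match(scores$protein_id[k], fc$proteins)
    up <- scores$direction[k] == "stabilized"
    qual <- sapply(seq_len(Tn), function(j) {
      nq <- sum(sapply(seq_len(R), function(r) {
        v <- phi[p, j, -1, r]
        if (all(is.na(v))) return(FALSE)
        if (up) max(v, na.rm = TRUE) >= cfg$h else min(v, na.rm = TRUE) <= 1 / cfg$h
      }))
      nq >= 2
    })
    if (!any(qual)) next
    e_lo <- min(xt$x) - 2; e_hi <- max(xt$x) + 2
    for (j in which(qual)) { # lowest qualifying temperature first
      w <- if (j < Tn) j else Tn - 1
      evals <- c()
      for (r in seq_len(R)) {
        y1 <- phi[p, w, , r]; y2 <- phi[p, w + 1, , r]
        y <- if (cfg$include_vehicle_point) c(y1[1], y1[-1], y2[1], y2[-1]) else c(y1[-1], y2[-1])
        ok <- is.finite(y)
        if (sum(ok) < cfg$min_points_per_fit) next
        f <- .fit4pl_one(xt$x[ok], y[ok])
        # fits stuck at the inflection-location box are not identified
        usable <- f[["converged"]] > 0 && is.finite(f[["e"]]) &&
          f[["e"]] > e_lo + 0.1 && f[["e"]] < e_hi - 0.1
        if (usable) evals <- c(evals, -f[["e"]])
      }
      if (length(evals) >= 1) {
        scores$pEC50[k] <- min(max(median(evals), clip_lo), clip_hi)
        break
      }
    }
  }
  scores
}

# ---- full pipeline ----------------------------------------------------------

# engine: per-protein combined scores from a fold-change cube, fitting only
# gated windows. Equivalent to combined_score(window_scores(fc, cfg, TRUE), cfg)
# (asserted in the tests) but avoids data-frame bookkeeping: the permutation
# loop calls this B times per dataset.
#' @noRd
tpp2d_engine <- function(fc, cfg) {
  phi <- fc$phi
  d <- dim(phi)
  P <- d[1]; Tn <- d[2]; R <- d[4]
  xt <- window_x(fc$concentrations, cfg$include_vehicle_point)
  gp <- integer(0); gw <- integer(0); gpm <- numeric(0)
  for (j in seq_len(Tn - 1)) {
    pm <- window_phimax(phi, j, cfg$h)
    g <- which(!is.na(pm) & (pm > cfg$h | pm < 1 / cfg$h))
    gp <- c(gp, g); gw <- c(gw, rep.int(j, length(g))); gpm <- c(gpm, pm[g])
  }
  out <- data.frame(protein_id = fc$proteins, F_comb = 0, direction = "none",
                    n_gated = 0L, phi_extreme = NA_real_, stringsAsFactors = FALSE)
  if (!length(gp)) return(out)
  xs <- list(); ys <- list(); row_of <- integer(0)
  for (k in seq_along(gp)) {
    p <- gp[k]; j <- gw[k]
    for (r in seq_len(R)) {
      y1 <- phi[p, j, , r]; y2 <- phi[p, j + 1, , r]
      y <- if (cfg$include_vehicle_point) c(y1[1], y1[-1], y2[1], y2[-1]) else c(y1[-1], y2[-1])
      ok <- is.finite(y)
      if (sum(ok) < cfg$min_points_per_fit) next
      xs[[length(xs) + 1]] <- xt$x[ok]
      ys[[length(ys) + 1]] <- y[ok]
      row_of <- c(row_of, k)
    }
  }
  Fmat <- matrix(NA_real_, length(gp), R)
  if (length(xs)) {
    fits <- fit_sigmoid_batch(xs, ys)
    slot <- integer(length(gp))
    for (i in seq_along(xs)) {
      y <- ys[[i]]
      rss0 <- sum((y - mean(y))^2)
      conv <- fits[i, "converged"] > 0 && is.finite(fits[i, "rss"]) &&
        fits[i, "rss"] <= rss0 + 1e-12
      rss1 <- if (conv) fits[i, "rss"] else rss0
      k <- row_of[i]
      slot[k] <- slot[k] + 1L
      Fmat[k, slot[k]] <- f_component(rss0, rss1)
    }
  }
  fin <- Fmat[is.finite(Fmat)]
  cap <- if (length(fin)) max(fin, 1) else 1
  Fmat[is.infinite(Fmat)] <- cap
  Fw <- vapply(seq_along(gp), function(k) {
    v <- Fmat[k, ]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }, numeric(1))
  terms <- ifelse(!is.na(Fw) & Fw > 0, log(Fw), NA_real_)
  if (!cfg$allow_negative_log_terms) { terms <- pmax(terms, 0); terms[is.na(terms)] <- 0 }
  for (p in unique(gp)) {
    sel <- gp == p & !is.na(Fw)
    if (!any(sel)) next
    out$F_comb[p] <- sum(terms[sel], na.rm = TRUE)
    out$n_gated[p] <- sum(sel)
    pm <- gpm[sel]
    l2 <- abs(log2(pm))
    out$phi_extreme[p] <- pm[which.max(l2)]
    up <- any(pm > cfg$h); down <- any(pm < 1 / cfg$h)
    out$direction[p] <- if (up && down) {
      if (max(l2[pm > cfg$h]) >= max(l2[pm < 1 / cfg$h])) "stabilized" else "destabilized"
    } else if (up) "stabilized" else "destabilized"
  }
  out
}

#' Run the full 2D-TPP analysis
#'
#' Preprocesses intensities into normalized fold changes, computes
#' sliding-window F-statistics and combined per-protein scores, estimates
#' the FDR from `B` stratified permutations (child seeds derived from the
#' master seed by counter, so results do not depend on execution order),
#' calls hits at the configured FDR cutoff and assigns pEC50 values.
#'
#' @param quant Long quant table.
#' @param meta Sample metadata describing a 2D-TPP layout.
#' @param cfg An [analysis_config()].
#' @return An object of class `"tpp2d_result"` with elements `scores`
#'   (per-protein data frame: `F_comb`, `direction`, `fdr`, `hit`,
#'   `pEC50`), `windows`, `fdr_table`, `fc` and `cfg`.
#' @examples
#' sim <- simulate_2dtpp(sim_config("TPP_2D", n_proteins = 30, seed = 7))
#' res <- tpp2d(sim$quant, sim$meta, analysis_config(n_permutations = 10, seed = 7))
#' head(res$scores)
#' @export
tpp2d <- function(quant, meta, cfg = analysis_config()) {
  fc <- preprocess_2dtpp(quant, meta, cfg)
  ts_log(cfg$verbose, "scoring %d proteins", length(fc$proteins))
  win <- window_scores(fc, cfg, gated_only = TRUE)
  scores <- combined_score(win, cfg)
  perm_scores <- vector("list", cfg$n_permutations)
  for (b in seq_len(cfg$n_permutations)) {
    pfc <- permute_dataset(fc, cfg$seed + b)
    perm_scores[[b]] <- tpp2d_engine(pfc, cfg)$F_comb
  }
  fdr_tab <- fdr_estimate(scores$F_comb, perm_scores, cfg)
  scores <- call_hits(scores, fdr_tab, cfg)
  scores <- assign_pec50(scores, fc, cfg)
  ts_log(cfg$verbose, "hits at FDR <= %g: %d of %d proteins",
         cfg$fdr_cutoff, sum(scores$hit), nrow(scores))
  structure(list(scores = scores, windows = win, fdr_table = fdr_tab,
                 fc = fc, cfg = cfg),
            class = "tpp2d_result")
}

#' @export
print.tpp2d_result <- function(x, ...) {
  cat(sprintf("2D-TPP analysis: %d proteins, %d hits at FDR <= %g\n",
              nrow(x$scores), sum(x$scores$hit), x$cfg$fdr_cutoff))
  tab <- table(x$scores$direction[x$scores$hit])
  if (length(tab))
    cat("  directions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tpp2d_result <- function(object, ...) {
  s <- object$scores
  out <- list(n_proteins = nrow(s), n_hits = sum(s$hit),
              directions = table(s$direction[s$hit]),
              pec50 = summary(s$pEC50[s$hit]))
  cat(sprintf("2D-TPP: %d proteins, %d hits (FDR <= %g)\n",
              out$n_proteins, out$n_hits, object$cfg$fdr_cutoff))
  if (out$n_hits > 0) {
    print(out$directions)
    cat("pEC50 of hits:\n"); print(out$pec50)
  }
  invisible(out)
}
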