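#' @name melting-analysis
#' @title Melting-curve fitting, melting points, co-melting and
#'   heating-solubilization analysis
#'
#' @description
#' TPP-TR experiments measure the fraction of each protein remaining
#' soluble over a temperature gradient. The melting model is the
#' three-parameter plateau sigmoid in inverse temperature,
#' `f(T) = (1 - p) / (1 + exp(b - a/T)) + p`, whose melting point Tm is the
#' temperature at which the fitted curve crosses 0.5. Complex co-melting is
#' quantified by the average squared per-temperature deviation between two
#' melting profiles, compared against random protein subsets by a
#' randomization test.
NULL

#' Plateau-sigmoid melting model
#'
#' `f(T) = (1 - p) / (1 + exp(b - a/T)) + p`: fraction non-denatured at
#' temperature `T` (degrees C), with steepness `a`, shift `b` and
#' high-temperature plateau `p`.
#'
#' @param temperature Temperature(s) in degrees C.
#' @param a Steepness parameter of the `a/T` term.
#' @param b Shift parameter.
#' @param p Plateau in `[0, 1)`.
#' @return Fractions in `(p, 1)`.
#' @export
melt_model <- function(temperature, a, b, p) {
  (1 - p) / (1 + exp(b - a / temperature)) + p
}

#' @rdname melt_model
#' @details `melt_tm()` solves `f(Tm) = 0.5` analytically:
#'   `Tm = a / (b - log(0.5 / (0.5 - p)))`, defined for `p < 0.5`.
#' @export
melt_tm <- function(a, b, p) {
  ifelse(p < 0.5, a / (b - log(0.5 / (0.5 - p))), NA_real_)
}

#' @rdname melt_model
#' @param tm Target melting point (degrees C).
#' @details `melt_b_for_tm()` returns the shift `b` that places the melting
#'   point at `tm` for given `a` and `p`.
#' @export
melt_b_for_tm <- function(a, tm, p) {
  a / tm + log(0.5 / (0.5 - p))
}

#' Fit a melting curve and extract the melting point
#'
#' Least-squares fit of the plateau-sigmoid melting model by multi-start
#' Levenberg-Marquardt (steepness starts spanning shallow to steep curves,
#' shift initialized from the temperature where the profile crosses 0.5).
#' The fit is flagged valid when it converged with `r2 >= r2_min`, plateau
#' `< plateau_max`, and a melting point inside the measured range plus 5
#' degrees C on either side; a curve that never crosses 0.5 has no Tm.
#'
#' @param temperature Temperatures in degrees C (at least 5).
#' @param fraction Fraction non-denatured at each temperature (the profile
#'   is expected to be normalized so the value at the lowest temperature
#'   is 1).
#' @param r2_min,plateau_max Validity filters.
#' @return An object of class `"melt_fit"`: `a`, `b`, `plateau`, `Tm`
#'   (or `NA`), `r2`, `rss`, `converged`, `valid`.
#' @examples
#' tt <- c(37, 40.4, 44, 46.9, 49.8, 52.9, 55.5, 58.6, 62, 66.3)
#' y <- melt_model(tt, 550, melt_b_for_tm(550, 50, 0.05), 0.05)
#' fit_melting_curve(tt, y)$Tm
#' @export
fit_melting_curve <- function(temperature, fraction, r2_min = 0.8, plateau_max = 0.3) {
  ok <- is.finite(temperature) & is.finite(fraction)
  temperature <- temperature[ok]; fraction <- fraction[ok]
  if (length(temperature) < 5)
    return(invalid_melt_fit(temperature, fraction))
  p0 <- min(max(min(fraction), 0), 0.29)
  # temperature nearest the half-denatured level seeds the shift
  tm0 <- temperature[which.min(abs(fraction - (1 + p0) / 2))]
  best <- NULL
  for (a0 in c(250, 550, 1100)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(a = a0, b = melt_b_for_tm(a0, tm0, p0), p = p0),
        fn = function(par) fraction - melt_model(temperature, par$a, par$b, par$p),
        lower = c(1e-3, -50, 0), upper = c(1e5, 1e4, 0.999),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) return(invalid_melt_fit(temperature, fraction))
  par <- as.list(coef(best))
  rss <- best$deviance
  tss <- sum((fraction - mean(fraction))^2)
  r2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss < 1e-12)
  tm <- melt_tm(par$a, par$b, par$p)
  pred <- melt_model(temperature, par$a, par$b, par$p)
  crosses <- min(pred) <= 0.5 && max(pred) >= 0.5
  in_range <- !is.na(tm) && tm >= min(temperature) - 5 && tm <= max(temperature) + 5
  if (!crosses || !in_range) tm <- NA_real_
  structure(list(a = par$a, b = par$b, plateau = par$p, Tm = tm,
                 r2 = r2, rss = rss, converged = TRUE,
                 valid = r2 >= r2_min && par$p < plateau_max && !is.na(tm),
                 temperature = temperature, fraction = fraction),
            class = "melt_fit")
}

#' @noRd
invalid_melt_fit <- function(temperature, fraction) {
  structure(list(a = NA_real_, b = NA_real_, plateau = NA_real_, Tm = NA_real_,
                 r2 = NA_real_, rss = NA_real_, converged = FALSE, valid = FALSE,
                 temperature = temperature, fraction = fraction),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("melting-curve fit: Tm = %s degC, plateau = %.3f, r2 = %.3f%s\n",
                if (is.na(x$Tm)) "NA" else sprintf("%.2f", x$Tm),
                x$plateau, x$r2, if (x$valid) "" else " (invalid)"))
  } else cat("melting-curve fit: not converged\n")
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(a = object$a, b = object$b, plateau = object$plateau)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$temperature else newdata
  melt_model(tt, object$a, object$b, object$plateau)
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$fraction - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  plot(x$temperature, x$fraction, xlab = "temperature (degC)",
       ylab = "fraction non-denatured", pch = 19, ylim = c(0, max(1, x$fraction)), ...)
  tt <- seq(min(x$temperature), max(x$temperature), length.out = 200)
  lines(tt, predict(x, tt), col = "firebrick")
  if (!is.na(x$Tm)) abline(v = x$Tm, lty = 2, col = "grey50")
  invisible(x)
}

#' Melting-point shift between two conditions
#'
#' `Tm(treated) - Tm(vehicle)`; `NA` unless both fits are valid with a
#' melting point.
#'
#' @param treated,vehicle `"melt_fit"` objects.
#' @return Shift in degrees C, or `NA`.
#' @export
delta_tm <- function(treated, vehicle) {
  if (!inherits(treated, "melt_fit") || !inherits(vehicle, "melt_fit"))
    stopf("delta_tm expects melt_fit objects")
  if (!treated$valid || !vehicle$valid || is.na(treated$Tm) || is.na(vehicle$Tm))
    return(NA_real_)
  treated$Tm - vehicle$Tm
}

#' Co-melting distance between two melting profiles
#'
#' Average squared per-temperature deviation between two profiles on a
#' shared temperature grid (the scale on which the 0.02 proximity cutoff is
#' calibrated for 10-point profiles on `[0, 1]`); `metric = "rss"` gives
#' the root-sum-square instead.
#'
#' @param a,b Numeric fraction profiles on the same temperature grid.
#' @param metric `"mean_sq"` (default) or `"rss"`.
#' @return Distance `>= 0`, or `NA` if fewer than 5 shared finite points.
#' @examples
#' comelt_distance(rep(0.5, 10), rep(0.6, 10))  # 0.01
#' @export
comelt_distance <- function(a, b, metric = c("mean_sq", "rss")) {
  metric <- match.arg(metric)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 5) return(NA_real_)
  d2 <- (a[ok] - b[ok])^2
  if (metric == "mean_sq") mean(d2) else sqrt(sum(d2))
}

#' Randomization test for complex co-melting
#'
#' The observed statistic is the mean pairwise co-melting distance among
#' the subunits of a complex (at least 3 required). The null distribution
#' is the same statistic over `n_rand` random same-size subsets of the
#' background (all quantified proteins); the p-value is
#' `(1 + #\{null <= observed\}) / (1 + n_rand)`, which is valid
#' (stochastically at least uniform under the null) by construction.
#'
#' @param complex_profiles Matrix of subunit profiles (rows) on a shared
#'   temperature grid.
#' @param background_profiles Matrix of background profiles (rows), at
#'   least as many rows as the complex.
#' @param n_rand Number of random subsets.
#' @param seed Integer seed.
#' @param cfg An [analysis_config()] (proximity cutoff, distance metric).
#' @return A list of class `"comelt_test"`: `mean_distance`, `p_value`,
#'   `pair_distances` (data frame with the proximity flag), `n_subunits`.
#' @export
complex_comelt_test <- function(complex_profiles, background_profiles,
                                n_rand = 999, seed = 1L, cfg = analysis_config()) {
  cm <- as.matrix(complex_profiles)
  bg <- as.matrix(background_profiles)
  n <- nrow(cm)
  if (n < 3) stopf("a complex needs at least 3 quantified subunits (got %d)", n)
  if (nrow(bg) < n) stopf("background (%d) smaller than complex (%d)", nrow(bg), n)
  mean_pairwise <- function(m) {
    ij <- utils::combn(nrow(m), 2)
    mean(apply(ij, 2, function(k) comelt_distance(m[k[1], ], m[k[2], ], cfg$comelt_metric)),
         na.rm = TRUE)
  }
  obs <- mean_pairwise(cm)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_rand), function(i) {
    mean_pairwise(bg[sample.int(nrow(bg), n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(null <= obs, na.rm = TRUE)) / (1 + n_rand)
  ij <- utils::combn(n, 2)
  pairs <- data.frame(
    i = ij[1, ], j = ij[2, ],
    distance = apply(ij, 2, function(k) comelt_distance(cm[k[1], ], cm[k[2], ], cfg$comelt_metric)))
  pairs$in_proximity <- !is.na(pairs$distance) & pairs$distance < cfg$comelt_cutoff
  structure(list(mean_distance = obs, p_value = p, pair_distances = pairs,
                 n_subunits = n, n_rand = n_rand),
            class = "comelt_test")
}

#' @export
print.comelt_test <- function(x, ...) {
  cat(sprintf("co-melting test: %d subunits, mean distance %.4g, p = %.4g (%d randomizations)\n",
              x$n_subunits, x$mean_distance, x$p_value, x$n_rand))
  cat(sprintf("  %d of %d pairs in proximity\n",
              sum(x$pair_distances$in_proximity), nrow(x$pair_distances)))
  invisible(x)
}

#' Maximal fold change on heating
#'
#' For a profile of fold changes relative to the lowest-temperature
#' reference (37 degrees C in the published design), returns the maximum
#' over all non-reference temperatures, its log2, and the temperature at
#' which it peaks. Insoluble proteins that partially solubilize on heating
#' show positive log2 maxima.
#'
#' @param temperature Temperatures in degrees C.
#' @param fold_change Fold change vs the reference temperature.
#' @param reference Reference temperature (default 37).
#' @return A list: `max_fc`, `log2_max_fc`, `t_max`.
#' @examples
#' max_fold_change_on_heating(c(37, 42, 58, 66), c(1, 1.3, 2, 0.4))
#' @export
max_fold_change_on_heating <- function(temperature, fold_change, reference = 37) {
  if (!reference %in% temperature) stopf("reference temperature %g not present", reference)
  sel <- temperature != reference & is.finite(fold_change)
  if (!any(sel)) stopf("no non-reference temperatures")
  mx <- max(fold_change[sel])
  list(max_fc = mx, log2_max_fc = log2(mx),
       t_max = temperature[sel][which.max(fold_change[sel])])
}

#' Correct a melting profile for a solubility change
#'
#' Divides a treated intensity profile pointwise by the protein's SPP
#' solubility fold change at the matching dose before fraction
#' normalization, separating thermal-stability from solubility effects. A
#' missing fold change returns the profile uncorrected and flagged; a zero
#' fold change is an error.
#'
#' @param temperature Temperatures (degrees C).
#' @param treated Treated intensity (or fraction) profile.
#' @param spp_fc SPP solubility fold change of this protein at the
#'   treatment dose.
#' @return A data frame `temperature`, `fraction` (corrected and normalized
#'   to the lowest temperature), with attribute `corrected` (logical).
#' @export
solubility_corrected_curve <- function(temperature, treated, spp_fc) {
  if (!is.na(spp_fc) && spp_fc == 0) stopf("spp_fc = 0: correction undefined")
  corrected <- !is.na(spp_fc)
  y <- if (corrected) treated / spp_fc else treated
  o <- order(temperature)
  y <- y[o] / y[o][1]
  out <- data.frame(temperature = temperature[o], fraction = y)
  attr(out, "corrected") <- corrected
  out
}

#' Wilcoxon group-shift test
#'
#' Paired signed-rank or unpaired rank-sum test, as used for comparisons of
#' melting-point shifts or solubilization between protein groups.
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param paired Use the signed-rank test on pairwise differences.
#' @return A list: `statistic`, `p_value` (`NA` when all paired differences
#'   are tied at zero), `method`.
#' @export
group_shift_test <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) == 0 || length(values_b) == 0) stopf("empty group")
  if (paired && length(values_a) != length(values_b))
    stopf("paired test needs equal lengths")
  if (paired && all(values_a - values_b == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "Wilcoxon signed rank (all differences tied)"))
  wt <- suppressWarnings(wilcox.test(values_a, values_b, paired = paired, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}

#' Run the TPP-TR melting analysis
#'
#' Normalizes intensities to the lowest temperature per protein, condition
#' and replicate, fits melting curves, and tabulates melting points and
#' (when both conditions are present) per-replicate and median
#' treated-minus-vehicle Tm shifts.
#'
#' @param quant Long TPP-TR quant table (intensities).
#' @param meta Sample metadata describing a TPP-TR layout.
#' @param cfg An [analysis_config()].
#' @return An object of class `"tpp_tr_result"` with `curves` (one row per
#'   protein x condition x replicate: model parameters, `Tm`, `r2`,
#'   `valid`), `delta_tm` (per protein: median shift, n valid replicate
#'   pairs), `profiles` (the normalized fraction profiles, as a list of
#'   matrices per condition x replicate) and `cfg`.
#' @export
tpp_tr <- function(quant, meta, cfg = analysis_config()) {
  layout <- validate_layout(meta, "TPP_TR")
  temps <- layout$temperatures
  proteins <- unique(quant$protein_id)
  P <- length(proteins)
  conds <- sort(unique(meta$condition))
  reps <- sort(unique(meta$replicate))

  mi <- match(quant$sample_id, meta$sample_id)
  key <- paste(meta$condition[mi], meta$replicate[mi])
  profiles <- list()
  curves <- list()
  for (cond in conds) for (r in reps) {
    sel <- key == paste(cond, r)
    if (!any(sel)) next
    q <- quant[sel, , drop = FALSE]
    ti <- match(meta$temperature[mi][sel], temps)
    m <- matrix(NA_real_, P, length(temps), dimnames = list(proteins, temps))
    m[cbind(match(q$protein_id, proteins), ti)] <- q$value
    frac <- m / m[, 1]
    profiles[[paste(cond, r, sep = "_")]] <- frac
    for (p in seq_len(P)) {
      f <- fit_melting_curve(temps, frac[p, ])
      curves[[length(curves) + 1]] <- data.frame(
        protein_id = proteins[p], condition = cond, replicate = r,
        a = f$a, b = f$b, plateau = f$plateau, Tm = f$Tm, r2 = f$r2,
        valid = f$valid, stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, curves)
  ts_log(cfg$verbose, "TPP-TR: %d proteins, %d curves, %d valid",
         P, nrow(curves), sum(curves$valid))

  dtm <- NULL
  if (all(c("treated", "vehicle") %in% conds)) {
    dtm <- do.call(rbind, lapply(proteins, function(id) {
      shifts <- vapply(reps, function(r) {
        tr <- curves[curves$protein_id == id & curves$condition == "treated" &
                       curves$replicate == r, ]
        vh <- curves[curves$protein_id == id & curves$condition == "vehicle" &
                       curves$replicate == r, ]
        if (nrow(tr) == 1 && nrow(vh) == 1 && tr$valid && vh$valid &&
            !is.na(tr$Tm) && !is.na(vh$Tm)) tr$Tm - vh$Tm else NA_real_
      }, numeric(1))
      data.frame(protein_id = id, delta_tm = median(shifts, na.rm = TRUE),
                 n_replicates = sum(!is.na(shifts)), stringsAsFactors = FALSE)
    }))
  }
  structure(list(curves = curves, delta_tm = dtm, profiles = profiles,
                 temperatures = temps, cfg = cfg),
            class = "tpp_tr_result")
}

#' @export
print.tpp_tr_result <- function(x, ...) {
  cat(sprintf("TPP-TR analysis: %d curves (%d valid) over %d temperatures\n",
              nrow(x$curves), sum(x$curves$valid), length(x$temperatures)))
  if (!is.null(x$delta_tm))
    cat(sprintf("  median |delta Tm| across proteins: %.2f degC\n",
                median(abs(x$delta_tm$delta_tm), na.rm = TRUE)))
  invisible(x)
}
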