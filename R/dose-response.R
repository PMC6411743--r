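#' Build a dose series for sigmoid fitting
#'
#' Converts concentrations in mM to the log10-molar axis used by the
#' dose-response model. The vehicle (0 mM) point, whose fold change is 1 by
#' construction, is placed at a pseudo-dose two decades below the lowest
#' nonzero dose - the standard convention for anchoring the lower asymptote.
#'
#' @param concentrations_mM Doses in mM, may include 0 (vehicle).
#' @param fold_changes Relative fold changes (strictly positive), same length.
#' @param min_points Minimum number of points required; with fewer the
#'   series is skipped (returns `NULL` rather than raising, so pipelines can
#'   drop under-observed fits silently).
#' @param include_vehicle Include the vehicle pseudo-dose point(s).
#' @return A list of class `"dose_series"` with `x` (log10 molar) and `y`,
#'   or `NULL` if fewer than `min_points` usable points remain.
#' @examples
#' to_dose_series(c(0, 0.005, 0.05, 0.5, 2), c(1, 1.1, 1.8, 2.6, 2.9))
#' @export
to_dose_series <- function(concentrations_mM, fold_changes, min_points = 5,
                           include_vehicle = TRUE) {
  stopifnot(length(concentrations_mM) == length(fold_changes))
  ok <- is.finite(concentrations_mM) & is.finite(fold_changes)
  concentrations_mM <- concentrations_mM[ok]
  fold_changes <- fold_changes[ok]
  if (any(fold_changes <= 0)) stopf("fold changes must be strictly positive")
  nz <- concentrations_mM > 0
  if (!any(nz)) return(NULL)
  pseudo <- min(concentrations_mM[nz]) / 100
  x <- log10(ifelse(nz, concentrations_mM, pseudo) / 1000)
  y <- fold_changes
  if (!include_vehicle) {
    x <- x[nz]; y <- y[nz]
  }
  if (length(x) < min_points) return(NULL)
  structure(list(x = x, y = y, pseudo_x = log10(pseudo / 1000)),
            class = "dose_series")
}

#' Intercept (null) model fit
#'
#' The least-squares intercept model: the fitted level is the arithmetic
#' mean of the responses and the residual sum of squares is exact.
#'
#' @param series A `"dose_series"` (or any list with a numeric `y`).
#' @return A list with `c` (mean level) and `rss`.
#' @examples
#' fit_null(list(y = c(1, 2, 3)))  # c = 2, rss = 2
#' @export
fit_null <- function(series) {
  y <- series$y
  if (length(y) == 0) stopf("empty response vector")
  cc <- mean(y)
  list(c = cc, rss = sum((y - cc)^2))
}

#' Fit the four-parameter logistic dose-response model
#'
#' Least-squares fit of `mu(x) = c + (d - c) / (1 + exp(b (x - e)))` by a
#' deterministic multi-start Levenberg-Marquardt optimization (starts for
#' `e` at every distinct observed dose and at the median; slope sign from
#' the rank correlation of dose and response; `c`, `d` from the response
#' range), with box constraints `c, d` in `[0, 10 max(y)]`, `|b| <= 50`,
#' `e` in `[min(x) - 2, max(x) + 2]`. The reported affinity is
#' `pEC50 = -e` on the log10-molar dose axis.
#'
#' If the optimizer fails, the dose axis is degenerate, or the sigmoid RSS
#' exceeds the intercept-model RSS, the fit is returned flagged
#' not-converged with its RSS set to the null RSS, so the derived
#' F-statistic component is zero.
#'
#' @param series A `"dose_series"` from [to_dose_series()].
#' @return An object of class `"dr_fit"`: coefficients `b, c, d, e`, `rss`,
#'   `rss_null`, `pEC50`, `converged`.
#' @examples
#' s <- to_dose_series(c(0, 0.005, 0.05, 0.5, 2),
#'                     1 + 2 / (1 + exp(-(log10(c(5e-8, 5e-6, 5e-5, 5e-4, 2e-3)) + 4))))
#' fit <- fit_sigmoid(s)
#' coef(fit)
#' @export
fit_sigmoid <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  x <- series$x; y <- series$y
  nf <- fit_null(series)
  res <- .fit4pl_one(x, y)
  conv <- is.finite(res[["rss"]]) && res[["converged"]] > 0
  rss <- res[["rss"]]
  if (!conv || !is.finite(rss) || rss > nf$rss) {
    fit <- list(b = NA_real_, c = nf$c, d = nf$c, e = NA_real_,
                rss = nf$rss, rss_null = nf$rss, pEC50 = NA_real_,
                converged = FALSE, x = x, y = y)
  } else {
    fit <- list(b = res[["b"]], c = res[["c"]], d = res[["d"]], e = res[["e"]],
                rss = rss, rss_null = nf$rss, pEC50 = -res[["e"]],
                converged = TRUE, x = x, y = y)
  }
  class(fit) <- "dr_fit"
  fit
}

#' F-statistic component from nested residual sums of squares
#'
#' `(rss0 - rss1) / rss1`, floored at zero: a sigmoid fit that is no better
#' than the intercept model carries no evidence. A perfect sigmoid fit
#' (`rss1 = 0` with `rss0 > 0`) returns `Inf` as a sentinel; pipelines
#' replace infinite components by the largest finite component in the
#' dataset before aggregating.
#'
#' @param rss0 Residual sum of squares of the intercept (null) model.
#' @param rss1 Residual sum of squares of the sigmoid model.
#' @return A non-negative number (possibly `Inf`).
#' @examples
#' f_component(2, 1)  # 1
#' f_component(1, 2)  # 0 (floored)
#' @export
f_component <- function(rss0, rss1) {
  stopifnot(rss0 >= 0, rss1 >= 0)
  if (rss1 == 0) {
    if (rss0 == 0) return(0)
    return(Inf)
  }
  max((rss0 - rss1) / rss1, 0)
}

# batched 4PL fit used by the pipelines; xs/ys are lists of numeric vectors
#' @noRd
fit_sigmoid_batch <- function(xs, ys) {
  if (length(xs) == 0)
    return(matrix(numeric(0), 0, 6,
                  dimnames = list(NULL, c("b", "c", "d", "e", "rss", "converged"))))
  .fit4pl_batch(xs, ys)
}

#' @export
print.dr_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("4PL dose-response fit: pEC50 = %.3f (b = %.3g, c = %.3g, d = %.3g)\n",
                x$pEC50, x$b, x$c, x$d))
    cat(sprintf("  rss = %.4g, null rss = %.4g, F component = %.4g\n",
                x$rss, x$rss_null, f_component(x$rss_null, x$rss)))
  } else {
    cat("4PL dose-response fit: not converged (reverts to intercept model)\n")
    cat(sprintf("  level c = %.4g, rss = %.4g\n", x$c, x$rss))
  }
  invisible(x)
}

#' @export
coef.dr_fit <- function(object, ...) {
  c(b = object$b, c = object$c, d = object$d, e = object$e)
}

#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  if (!object$converged) return(rep(object$c, length(x)))
  object$c + (object$d - object$c) / (1 + exp(object$b * (x - object$e)))
}

#' @export
residuals.dr_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.dr_fit <- function(x, ...) {
  plot(x$x, x$y, xlab = "log10 dose (M)", ylab = "fold change",
       pch = 19, ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  lines(xx, predict(x, xx), col = "firebrick")
  if (x$converged) abline(v = x$e, lty = 2, col = "grey50")
  invisible(x)
}
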