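# internal helpers shared across the pipeline stages

#' @noRd
ts_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[thermsol] ", sprintf(...))
  invisible(NULL)
}

# lognormal multiplicative noise with a given coefficient of variation,
# mean exactly 1 so expected values are preserved
#' @noRd
rnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# qupm (quantified unique peptides) capped category used as permutation stratum
#' @noRd
bin_qupm <- function(q) {
  if (is.character(q) || is.factor(q)) {
    q <- as.character(q)
    bad <- !q %in% c("2", "3", "4", "5+")
    if (any(bad)) stop("invalid qupm category: ", paste(unique(q[bad]), collapse = ", "))
    return(q)
  }
  if (any(!is.finite(q) | q < 2)) stop("qupm must be an integer >= 2")
  ifelse(q >= 5, "5+", as.character(as.integer(q)))
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)
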