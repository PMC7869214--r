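# Growth-curve variable extraction (lag, maximum specific growth rate,
# growth efficiency) and CFU survival rates.

#' Extract growth variables from an OD600 time series
#'
#' Implements the classic graphical reading of a microbial growth curve:
#' \enumerate{
#'   \item transform to natural-log OD (specific growth rate scale);
#'   \item fit a least-squares line over every contiguous window of
#'     `window_size` points;
#'   \item the maximum slope is the growth rate (earliest window on ties);
#'   \item the lag is where that tangent crosses the initial density level,
#'     i.e. `(log(od_initial) - intercept) / slope`, with `od_initial` the
#'     mean of the first `max(2, window_size %/% 2)` readings;
#'   \item the growth efficiency is `max(od) - od_initial` on the linear
#'     scale (total density change to stationary phase).
#' }
#' Negative lags (a curve already growing at its first reading) are clipped
#' to 0 and flagged. Flat or declining curves yield rate 0 and an undefined
#' (NA) lag.
#'
#' @param times Time points in hours, strictly increasing.
#' @param od OD600 readings, same length, at least 5 points. Readings at or
#'   below `od_floor` are clipped to `od_floor` and flagged (log of a blank
#'   is undefined).
#' @param window_size Points per regression window (default 4; use a longer
#'   window for noisy plates).
#' @param log_scale Fit on natural-log OD (default). `FALSE` fits the raw
#'   OD, in which case the "rate" is a linear slope in OD/h.
#' @param median_filter Apply a 3-point running median to the OD series
#'   before fitting (off by default).
#' @param od_floor Lower clip for OD readings (default 1e-4).
#' @return List of class `growth_variables`: `lag` (h, `NA` if undefined),
#'   `rate` (per hour), `efficiency` (delta OD600), `window` (index range
#'   of the tangent window), `od_initial`, and `flags` (character vector).
#' @examples
#' t <- 0:12
#' gv <- growth_variables(t, 0.05 * exp(0.4 * t))
#' gv$rate  # 0.4
#' @export
growth_variables <- function(times, od, window_size = 4L, log_scale = TRUE,
                             median_filter = FALSE, od_floor = 1e-4) {
  stopifnot(is.numeric(times), is.numeric(od), length(times) == length(od))
  n <- length(times)
  if (n < 5L) stop("need at least 5 points to extract growth variables")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  window_size <- as.integer(window_size)
  if (window_size < 3L) stop("window_size must be at least 3")
  if (window_size > n) stop("window_size exceeds number of points")
  flags <- character(0)
  if (any(od <= od_floor)) {
    flags <- c(flags, "od_clipped_to_floor")
    od <- pmax(od, od_floor)
  }
  if (median_filter && n >= 3L) {
    od <- stats::runmed(od, 3L, endrule = "keep")
    flags <- c(flags, "median_filtered")
  }
  n0 <- max(2L, window_size %/% 2L)
  od_initial <- mean(od[seq_len(min(n0, n))])
  efficiency <- max(max(od) - od_initial, 0)

  y <- if (log_scale) log(od) else od
  fit <- .window_slopes(times, y, window_size)
  best <- which.max(fit$slope)              # which.max takes earliest tie
  rate <- fit$slope[best]
  # slopes within rounding of zero are no growth, not a tangent
  if (!is.finite(rate) || rate <= 1e-10) {
    return(structure(list(lag = NA_real_, rate = 0, efficiency = efficiency,
                          window = c(NA_integer_, NA_integer_),
                          od_initial = od_initial,
                          flags = c(flags, "no_growth")),
                     class = "growth_variables"))
  }
  intercept <- fit$intercept[best]
  y0 <- if (log_scale) log(od_initial) else od_initial
  lag <- (y0 - intercept) / rate
  if (lag < 0) {
    flags <- c(flags, "negative_lag_clipped")
    lag <- 0
  }
  structure(list(lag = lag, rate = rate, efficiency = efficiency,
                 window = c(best, best + window_size - 1L),
                 od_initial = od_initial, flags = flags),
            class = "growth_variables")
}

# Least-squares slope and intercept over every contiguous window of w
# points, via rolling sums (handles unevenly spaced times).
.window_slopes <- function(x, y, w) {
  n <- length(x)
  roll <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  }
  sx <- roll(x); sy <- roll(y); sxx <- roll(x * x); sxy <- roll(x * y)
  denom <- w * sxx - sx * sx
  slope <- (w * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / w
  list(slope = slope, intercept = intercept)
}

#' @export
print.growth_variables <- function(x, ...) {
  cat(sprintf("growth variables: lag %.2f h, rate %.4f /h, efficiency %.3f\n",
              x$lag, x$rate, x$efficiency))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Compare growth variables between two conditions
#'
#' @param a,b `growth_variables` objects (e.g. stressed vs unstressed).
#' @return List with `rate_ratio` (a/b), `efficiency_ratio` (a/b) and
#'   `lag_difference` (a - b, hours; `NA` propagates from an undefined lag).
#' @export
compare_growth <- function(a, b) {
  stopifnot(inherits(a, "growth_variables"), inherits(b, "growth_variables"))
  list(rate_ratio = if (b$rate > 0) a$rate / b$rate else NA_real_,
       efficiency_ratio = if (b$efficiency > 0)
         a$efficiency / b$efficiency else NA_real_,
       lag_difference = a$lag - b$lag)
}

#' Survival rate from CFU counts
#'
#' Percentage of colony-forming units at each time point relative to the
#' starting count; the first time point is by definition 100 percent.
#' Multiplying all counts by a dilution constant leaves percentages
#' unchanged.
#'
#' @param times Time points in hours (first is the starting time).
#' @param cfu Dilution-corrected CFU per mL, non-negative; the starting
#'   count must be positive.
#' @return Data frame with columns `time` and `percent`.
#' @export
survival_rate <- function(times, cfu) {
  stopifnot(is.numeric(times), is.numeric(cfu), length(times) == length(cfu))
  if (length(times) == 0L) stop("empty survival series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(cfu < 0)) stop("CFU counts must be non-negative")
  if (cfu[1L] <= 0) stop("starting CFU must be positive")
  data.frame(time = times, percent = 100 * cfu / cfu[1L])
}
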