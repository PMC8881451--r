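#' Log-normal summary of an AFM wire-length sample
#'
#' AFM ridge lengths of self-assembled wires follow a log-normal
#' distribution. This fits the log-normal by maximum likelihood (via
#' [MASS::fitdistr()]) and reports, alongside `meanlog`/`sdlog`, the
#' arithmetic mean with its standard error (sd/sqrt(N)), the maximum
#' detected length, and histogram bin edges.
#'
#' @param samples_nm positive ridge lengths in nm, at least 20 values.
#' @param bins suggested number of histogram bins (Sturges-style `pretty`
#'   edges are reported).
#' @return An object of class `length_distribution`.
#' @export
fit_length_distribution <- function(samples_nm, bins = 30L) {
  if (!is.numeric(samples_nm) || length(samples_nm) < 20L) {
    stop("need at least 20 numeric length samples")
  }
  bad <- which(!is.finite(samples_nm) | samples_nm <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or non-finite sample at index %d", bad[1L]))
  }
  ml <- MASS::fitdistr(samples_nm, "lognormal")
  n <- length(samples_nm)
  structure(
    list(samples_nm = samples_nm,
         meanlog = unname(ml$estimate["meanlog"]),
         sdlog = unname(ml$estimate["sdlog"]),
         meanlog_se = unname(ml$sd["meanlog"]),
         sdlog_se = unname(ml$sd["sdlog"]),
         mean_nm = mean(samples_nm),
         sem_nm = sd(samples_nm) / sqrt(n),
         max_nm = max(samples_nm),
         n = n,
         breaks_nm = pretty(range(samples_nm), n = bins),
         tip_offset_nm = attr(samples_nm, "tip_offset_nm") %||% 0),
    class = "length_distribution"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.length_distribution <- function(x, ...) {
  cat("Wire length distribution\n")
  cat(sprintf("  N = %d, mean = %.1f +/- %.1f nm (SEM), max = %.1f nm\n",
              x$n, x$mean_nm, x$sem_nm, x$max_nm))
  cat(sprintf("  log-normal MLE: meanlog = %.3f (%.3f), sdlog = %.3f (%.3f)\n",
              x$meanlog, x$meanlog_se, x$sdlog, x$sdlog_se))
  if (x$tip_offset_nm > 0) {
    cat(sprintf("  tip correction applied: -%.1f nm\n", x$tip_offset_nm))
  }
  invisible(x)
}

#' Correct AFM lengths for the finite tip-size effect
#'
#' Probe-sample convolution makes wires appear systematically longer in AFM
#' than they are; here the overestimate is about 10 nm for a nominal 7-nm
#' tip radius. The correction subtracts a constant offset from every
#' observed length, flooring at zero (with a warning naming how many samples
#' were floored). The applied offset is recorded in the
#' `"tip_offset_nm"` attribute so downstream summaries can report it.
#'
#' @param samples_nm observed ridge lengths, nm.
#' @param tip_offset_nm offset to subtract, nm (>= 0, default 10).
#' @return Corrected lengths with attribute `tip_offset_nm`.
#' @examples
#' mean(tip_correct(c(22.1, 30, 40)))   # ~10 nm shorter
#' @export
tip_correct <- function(samples_nm, tip_offset_nm = 10) {
  if (!is.numeric(samples_nm) || any(!is.finite(samples_nm))) {
    stop("`samples_nm` must be finite numeric")
  }
  if (!is.numeric(tip_offset_nm) || length(tip_offset_nm) != 1L ||
      tip_offset_nm < 0) {
    stop("`tip_offset_nm` must be a single number >= 0")
  }
  corrected <- samples_nm - tip_offset_nm
  floored <- corrected < 0
  if (any(floored)) {
    warning(sprintf("%d sample(s) shorter than the tip offset floored at 0",
                    sum(floored)))
    corrected[floored] <- 0
  }
  attr(corrected, "tip_offset_nm") <- tip_offset_nm
  corrected
}

#' Mean and standard error of AFM height measurements
#'
#' @param samples_nm height samples in nm, at least 2 values.
#' @return A list with `mean_nm`, `sem_nm` (sd/sqrt(N)), `sd_nm`, `n`.
#' @examples
#' summarize_heights(c(1.9, 2.0, 2.1))
#' @export
summarize_heights <- function(samples_nm) {
  if (!is.numeric(samples_nm) || length(samples_nm) < 2L) {
    stop("need at least 2 numeric height samples")
  }
  bad <- which(!is.finite(samples_nm))
  if (length(bad)) stop(sprintf("non-finite sample at index %d", bad[1L]))
  n <- length(samples_nm)
  list(mean_nm = mean(samples_nm), sem_nm = sd(samples_nm) / sqrt(n),
       sd_nm = sd(samples_nm), n = n)
}

#' Read an AFM ridge measurement table
#'
#' CSV layout: one row per detected ridge, columns `length_nm, height_nm`;
#' `#` lines are comments.
#'
#' @param path file path.
#' @return data.frame with columns `length_nm`, `height_nm`.
#' @export
read_afm_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("length_nm", "height_nm") %in% names(df))) {
    stop("AFM CSV must have columns `length_nm` and `height_nm`")
  }
  df
}

#' UV melting curve container
#'
#' Absorbance at 295 nm versus temperature for a thermal unfolding
#' experiment. Unfolding of quadruplex structures produces a hypochromic
#' transition at 295 nm, so the melting midpoint is the extremum of the
#' first derivative of A295(T).
#'
#' @param temperature_C temperatures in degrees C, strictly increasing, at
#'   least 10 points.
#' @param a295 absorbance values at 295 nm.
#' @param smoothing_window moving-average window (points, odd) applied
#'   before differentiation.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature_C, a295, smoothing_window = 5L) {
  if (!is.numeric(temperature_C) || !is.numeric(a295) ||
      length(temperature_C) != length(a295)) {
    stop("`temperature_C` and `a295` must be numeric vectors of equal length")
  }
  if (length(temperature_C) < 10L) stop("a melting curve needs at least 10 points")
  if (any(diff(temperature_C) <= 0)) stop("`temperature_C` must be strictly increasing")
  if (any(!is.finite(a295))) stop("`a295` values must be finite")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("`smoothing_window` must be a positive odd integer")
  structure(
    list(temperature_C = temperature_C, a295 = a295, smoothing_window = w),
    class = "melting_curve"
  )
}

#' Read a UV melting curve from CSV (`temp_C, A295` columns)
#'
#' @param path file path.
#' @param smoothing_window see [melting_curve()].
#' @return A `melting_curve`.
#' @export
read_melting_csv <- function(path, smoothing_window = 5L) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("temp_C", "A295") %in% names(df))) {
    stop("melting CSV must have columns `temp_C` and `A295`")
  }
  melting_curve(df$temp_C, df$A295, smoothing_window)
}

#' Mid-transition temperature from the derivative of a melting curve
#'
#' Estimates T1/2 as the temperature of the extremum of the first derivative
#' of A295 versus temperature: the absorbance trace is smoothed with a
#' moving average (default 5 points), differentiated by centred differences,
#' and the temperature of the largest-magnitude derivative is reported.
#' When that extremum falls within one smoothing window of either end of
#' the measured range the transition is not bracketed by the data (e.g. a
#' curve that never reaches its high-temperature plateau) and the result
#' carries the flag `"edge: transition not fully covered"`.
#'
#' @param curve a [melting_curve()].
#' @return A list of class `melting_fit` with `t_half_C`, `flags`,
#'   `derivative` (data.frame `temperature_C`, `dA_dT`).
#' @export
melting_midpoint <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  Tc <- curve$temperature_C
  A <- curve$a295
  if (diff(range(A)) < 1e-10 * max(1, abs(mean(A)))) {
    stop("no transition: absorbance is flat over the measured range")
  }
  w <- curve$smoothing_window
  As <- if (w > 1L) {
    sm <- stats::filter(A, rep(1 / w, w), sides = 2)
    # moving average leaves (w-1)/2 NAs at each end; keep raw values there
    ifelse(is.na(sm), A, as.numeric(sm))
  } else A
  n <- length(Tc)
  idx <- 2:(n - 1L)
  dA <- (As[idx + 1L] - As[idx - 1L]) / (Tc[idx + 1L] - Tc[idx - 1L])
  Tm_grid <- Tc[idx]
  k <- which.max(abs(dA))
  t_half <- Tm_grid[k]
  flags <- character()
  half_w <- (w - 1L) / 2L + 1L
  if (k <= half_w || k > length(dA) - half_w) {
    flags <- c(flags, "edge: transition not fully covered by the temperature range")
  }
  structure(
    list(t_half_C = t_half, flags = flags,
         derivative = data.frame(temperature_C = Tm_grid, dA_dT = dA)),
    class = "melting_fit"
  )
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("Melting midpoint T1/2 = %.1f C\n", x$t_half_C))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
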