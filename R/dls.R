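#' Light-scattering experimental setup
#'
#' Geometry and optics of the DLS experiment: laser wavelength (default
#' 532 nm, a frequency-doubled Nd:YAG source), scattering angle (default
#' 90 degrees), solvent refractive index (default 1.33, water), and the
#' solvent conditions used for hydrodynamic conversions.
#'
#' @param wavelength_m in-vacuo laser wavelength, m.
#' @param angle_deg scattering angle in degrees, in (0, 180).
#' @param refractive_index solvent refractive index.
#' @param conditions a [solvent_conditions()] object.
#' @return An object of class `scattering_setup`.
#' @export
scattering_setup <- function(wavelength_m = 532e-9, angle_deg = 90,
                             refractive_index = 1.33,
                             conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(wavelength_m) || length(wavelength_m) != 1L || wavelength_m <= 0) {
    stop("`wavelength_m` must be a single positive number")
  }
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L ||
      angle_deg <= 0 || angle_deg >= 180) {
    stop("`angle_deg` must lie strictly between 0 and 180 degrees")
  }
  if (!is.numeric(refractive_index) || length(refractive_index) != 1L ||
      refractive_index <= 0) {
    stop("`refractive_index` must be a single positive number")
  }
  structure(
    list(wavelength_m = wavelength_m, angle_deg = angle_deg,
         refractive_index = refractive_index, conditions = conditions),
    class = "scattering_setup"
  )
}

#' Scattering vector magnitude
#'
#' `q = 4 pi n sin(theta/2) / lambda`, the momentum transfer that sets the
#' decay rate `q^2 D` of a diffusive mode in the autocorrelation function.
#'
#' @param setup a [scattering_setup()].
#' @return q in m^-1.
#' @examples
#' scattering_vector(scattering_setup())   # ~2.22e7 m^-1 at 90 degrees
#' @export
scattering_vector <- function(setup = scattering_setup()) {
  stopifnot(inherits(setup, "scattering_setup"))
  4 * pi * setup$refractive_index * sin(setup$angle_deg * pi / 360) /
    setup$wavelength_m
}

#' Intensity autocorrelation trace
#'
#' Container for a measured (or simulated) DLS intensity autocorrelation
#' function g2(t): lag times in seconds (strictly increasing, at least 20
#' points) with their dimensionless g2 values.
#'
#' @param lag_s lag times, s.
#' @param g2 intensity autocorrelation values.
#' @return An object of class `correlation_trace` (also a data.frame with
#'   columns `lag_s`, `g2`).
#' @export
correlation_trace <- function(lag_s, g2) {
  if (!is.numeric(lag_s) || !is.numeric(g2) || length(lag_s) != length(g2)) {
    stop("`lag_s` and `g2` must be numeric vectors of equal length")
  }
  if (length(lag_s) < 20L) stop("a correlation trace needs at least 20 points")
  if (any(!is.finite(lag_s)) || any(lag_s <= 0) || any(diff(lag_s) <= 0)) {
    stop("`lag_s` must be positive, finite and strictly increasing")
  }
  if (any(!is.finite(g2))) stop("`g2` values must be finite")
  structure(data.frame(lag_s = lag_s, g2 = g2),
            class = c("correlation_trace", "data.frame"))
}

#' Read / write a correlation trace as CSV
#'
#' CSV layout: columns `lag_s, g2`; lines starting with `#` are treated as
#' comments (generators record their seed there).
#'
#' @param path file path.
#' @param trace a [correlation_trace()].
#' @param comment optional character vector of comment lines (written with a
#'   leading `# `).
#' @return `read_trace_csv()` returns a `correlation_trace`;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("lag_s", "g2") %in% names(df))) {
    stop("trace CSV must have columns `lag_s` and `g2`")
  }
  correlation_trace(df$lag_s, df$g2)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path, comment = NULL) {
  stopifnot(inherits(trace, "correlation_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  writeLines("lag_s,g2", con)
  writeLines(sprintf("%.12e,%.12e", trace$lag_s, trace$g2), con)
  invisible(path)
}

#' Fit a two-mode exponential decay to an intensity autocorrelation
#'
#' Least-squares fit of the Siegert-relation model
#' \deqn{g_2(t) = 1 + \beta \left(A_f e^{-q^2 D_f t} +
#'   A_s e^{-q^2 D_s t}\right)^2}
#' with `A_f + A_s = 1`, directly on g2 (fitting the square root g1 would
#' rectify noise near the baseline, biasing the slow mode). Initialisation
#' is deterministic and data-driven: the intercept beta from the zero-lag
#' extrapolation, decay rates from the lags where the normalised field
#' correlation first drops below 80% and 20%, amplitudes 0.5/0.5. The fit
#' uses Levenberg-Marquardt least squares with the amplitude fraction kept
#' in [0, 1] and diffusivities positive.
#'
#' @param trace a [correlation_trace()], ideally spanning >= 3 decades of
#'   lag time.
#' @param setup a [scattering_setup()]; its scattering vector converts decay
#'   rates to diffusion coefficients.
#' @return An object of class `two_mode_fit` with the mode-assigned
#'   parameters: `beta`, `D_f`, `D_s` (m^2 s^-1, `D_f > D_s`), `A_f`, `A_s`,
#'   `residual_norm`, `converged`, and the raw `fit` object.
#' @export
fit_two_mode <- function(trace, setup = scattering_setup()) {
  stopifnot(inherits(trace, "correlation_trace"),
            inherits(setup, "scattering_setup"))
  t <- trace$lag_s
  y <- trace$g2
  if (log10(max(t) / min(t)) < 3) {
    warning("trace spans fewer than 3 decades of lag time; fit may be poorly constrained")
  }
  q2 <- scattering_vector(setup)^2

  beta0 <- max(mean(y[seq_len(min(3L, length(y)))]) - 1, 1e-6)
  g1 <- sqrt(pmax((y - 1) / beta0, 0))
  if (diff(range(y)) < 1e-10) stop("degenerate (flat) trace: nothing to fit")
  first_below <- function(frac) {
    i <- which(g1 < frac)[1L]
    if (is.na(i)) length(t) else i
  }
  t80 <- t[first_below(0.8)]
  t20 <- t[first_below(0.2)]
  G_f0 <- -log(0.8) / t80
  G_s0 <- -log(0.2) / t20
  if (!is.finite(G_s0) || G_s0 >= G_f0) G_s0 <- G_f0 / 100

  if (G_s0 > G_f0 / 10) G_s0 <- G_f0 / 100  # enforce separated starting modes
  # model residuals; D parameterised in units of 1e-10 m^2/s for conditioning
  model_resid <- function(par) {
    g1m <- par["af"] * exp(-q2 * par["df10"] * 1e-10 * t) +
      (1 - par["af"]) * exp(-q2 * par["ds10"] * 1e-10 * t)
    y - (1 + par["beta"] * g1m^2)
  }
  start <- c(beta = beta0, af = 0.5,
             df10 = G_f0 / q2 * 1e10, ds10 = G_s0 / q2 * 1e10)
  fit <- minpack.lm::nls.lm(
    par = start, fn = model_resid,
    lower = c(beta = 1e-6, af = 0, df10 = 1e-12, ds10 = 1e-12),
    upper = c(beta = 10, af = 1, df10 = Inf, ds10 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$info %in% 1:4) {
    stop(sprintf(
      "two-mode fit did not converge (nls.lm info %d: %s); start was beta=%.3g, af=0.5, D=(%.3g, %.3g)",
      fit$info, fit$message, beta0, G_f0 / q2, G_s0 / q2))
  }
  cf <- coef(fit)
  res <- structure(
    list(beta = unname(cf["beta"]),
         D = unname(c(cf["df10"], cf["ds10"])) * 1e-10,
         A = unname(c(cf["af"], 1 - cf["af"])),
         residual_norm = sqrt(sum(fit$fvec^2)),
         converged = TRUE,
         fit = fit),
    class = "two_mode_fit"
  )
  assign_modes(res)
}

#' Assign fast/slow labels to the two fitted diffusive modes
#'
#' Orders the two diffusion coefficients so that `D_f > D_s` (amplitudes
#' follow), labelling the fast mode as the structure of interest (individual
#' quadruplexes and wires) and the slow mode as large unspecific clusters.
#' Warns when `D_f / D_s < 10`: the two modes of a well-resolved measurement
#' differ by roughly two orders of magnitude, and poorly separated modes
#' make the assignment unreliable.
#'
#' @param fit a `two_mode_fit`, or any list with numeric fields `D`
#'   (2 diffusion coefficients) and `A` (2 amplitudes).
#' @return The fit with ordered `D`/`A` and convenience fields `D_f`, `D_s`,
#'   `A_f`, `A_s`, `mode_ratio`.
#' @export
assign_modes <- function(fit) {
  if (!is.list(fit) || is.null(fit$D) || is.null(fit$A) ||
      length(fit$D) != 2L || length(fit$A) != 2L) {
    stop("`fit` must carry two diffusion coefficients `D` and amplitudes `A`")
  }
  ord <- order(fit$D, decreasing = TRUE)
  fit$D <- fit$D[ord]
  fit$A <- fit$A[ord]
  fit$D_f <- fit$D[1L]
  fit$D_s <- fit$D[2L]
  fit$A_f <- fit$A[1L]
  fit$A_s <- fit$A[2L]
  fit$mode_ratio <- fit$D_f / fit$D_s
  if (is.finite(fit$mode_ratio) && fit$mode_ratio < 10) {
    warning(sprintf(
      "fast/slow modes poorly separated (D_f/D_s = %.2f < 10); assignment unreliable",
      fit$mode_ratio))
  }
  if (!inherits(fit, "two_mode_fit")) class(fit) <- c("two_mode_fit", class(fit))
  fit
}

#' @export
print.two_mode_fit <- function(x, ...) {
  cat("Two-mode DLS fit\n")
  cat(sprintf("  beta  = %.4f\n", x$beta))
  cat(sprintf("  fast:  D_f = %.4e m^2/s, A_f = %.3f\n", x$D_f, x$A_f))
  cat(sprintf("  slow:  D_s = %.4e m^2/s, A_s = %.3f\n", x$D_s, x$A_s))
  cat(sprintf("  residual norm = %.3e, converged = %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' Full wire-length report from a trace or a fast-mode diffusion coefficient
#'
#' Chains the pipeline: (fit the trace and take the fast mode, if a trace is
#' given) -> classify the hydrodynamic regime -> invert the rod model (or
#' Stokes-Einstein for sphere-regime species) -> count stacked building
#' blocks. All validity flags and the solvent conditions used are carried in
#' the report.
#'
#' @param x either a [correlation_trace()] or a single fast-mode diffusion
#'   coefficient (m^2 s^-1).
#' @param setup a [scattering_setup()]; supplies both q (trace fitting) and
#'   the solvent conditions.
#' @param model a [building_block_model()]; its hydrodynamic diameter feeds
#'   the rod model.
#' @return An object of class `wire_estimate` with fields `dt`, `regime`,
#'   `length_nm` and `n_units` (rod regime), `radius_nm` (sphere regime),
#'   `axial_ratio`, `flags`, `conditions`, and `fit` when fitted from a
#'   trace.
#' @examples
#' wire_length_report(0.33e-10)   # rod regime, ~45 nm, ~33 units
#' wire_length_report(1.55e-10)   # sphere regime, R_h ~1.6 nm
#' @export
wire_length_report <- function(x, setup = scattering_setup(),
                               model = building_block_model()) {
  stopifnot(inherits(setup, "scattering_setup"),
            inherits(model, "building_block_model"))
  cond <- setup$conditions
  fit <- NULL
  if (inherits(x, "correlation_trace")) {
    fit <- fit_two_mode(x, setup)
    dt <- fit$D_f
  } else if (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0) {
    dt <- x
  } else {
    stop("`x` must be a correlation_trace or a single positive diffusion coefficient")
  }
  d <- model$hydro_diameter_nm
  regime <- classify_regime(dt, d, cond)
  out <- list(dt = dt, regime = regime, conditions = cond,
              diameter_nm = d, flags = character(), fit = fit,
              length_nm = NA_real_, n_units = NA_integer_,
              axial_ratio = NA_real_, radius_nm = NA_real_)
  if (regime == "sphere") {
    out$radius_nm <- invert_sphere_diffusion(dt, cond)
    out$flags <- c(out$flags,
                   "above rod-regime boundary: Stokes-Einstein sphere model used")
  } else {
    inv <- invert_rod_diffusion(dt, d, cond)
    out$length_nm <- inv$length_nm
    out$axial_ratio <- inv$axial_ratio
    out$flags <- c(out$flags, inv$flags)
    out$n_units <- count_units(inv$length_nm, model)
  }
  structure(out, class = "wire_estimate")
}

#' @export
print.wire_estimate <- function(x, ...) {
  cat("Wire estimate\n")
  cat(sprintf("  D_t = %.3e m^2/s, regime = %s\n", x$dt, x$regime))
  if (x$regime == "sphere") {
    cat(sprintf("  hydrodynamic radius R_h = %.2f nm\n", x$radius_nm))
  } else {
    cat(sprintf("  effective length L = %.1f nm (p = %.1f), n_units = %d\n",
                x$length_nm, x$axial_ratio, x$n_units))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$conditions)
  invisible(x)
}
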