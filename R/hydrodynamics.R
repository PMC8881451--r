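#' Solvent conditions for hydrodynamic conversions
#'
#' Temperature and viscosity context used by every diffusion-coefficient
#' conversion in the package. The default profile is room-temperature water
#' (298.15 K, 8.90e-4 Pa s); both values can be overridden and are echoed in
#' every downstream report so that the conditions actually used are always
#' visible.
#'
#' @param temperature_K absolute temperature in kelvin (> 0).
#' @param viscosity_Pa_s dynamic viscosity in Pa s (> 0).
#' @return An object of class `solvent_conditions`.
#' @examples
#' solvent_conditions()                      # room-temperature water
#' solvent_conditions(293.15, 1.002e-3)     # 20 C water
#' @export
solvent_conditions <- function(temperature_K = 298.15, viscosity_Pa_s = 8.90e-4) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive number (kelvin)")
  }
  if (!is.numeric(viscosity_Pa_s) || length(viscosity_Pa_s) != 1L ||
      !is.finite(viscosity_Pa_s) || viscosity_Pa_s <= 0) {
    stop("`viscosity_Pa_s` must be a single positive number (Pa s)")
  }
  structure(
    list(temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s),
    class = "solvent_conditions"
  )
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat(sprintf("Solvent conditions: T = %.2f K, eta = %.3e Pa s\n",
              x$temperature_K, x$viscosity_Pa_s))
  invisible(x)
}

#' End-effect correction for a translating rigid rod
#'
#' The end-effect term nu(p) of the Tirado-de la Torre cylinder model for
#' translational diffusion,
#' \deqn{\nu(p) = 0.312 + 0.565/p - 0.100/p^2,}
#' where `p = L/d` is the axial ratio. The polynomial is the standard
#' interpolation for cylinders and is bounded on the validity range
#' `2 <= p <= 30`; as `p` grows nu tends to the constant 0.312.
#'
#' @param p axial ratio (length over diameter), `p >= 1`; vectorised.
#' @return nu(p), dimensionless.
#' @examples
#' end_correction(2)      # 0.5695
#' end_correction(1e6)    # ~0.312
#' @export
end_correction <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) stop("`p` must be finite numeric")
  if (any(p < 1)) {
    stop("axial ratio p must be >= 1 (a rod thinner than its diameter is meaningless)")
  }
  0.312 + 0.565 / p - 0.100 / p^2
}

#' Translational diffusion coefficient of a rigid rod
#'
#' Forward Tirado-de la Torre model for a cylinder of length `L` and
#' diameter `d` diffusing in a solvent:
#' \deqn{D_t = \frac{k_B T (\ln p + \nu(p))}{3 \pi \eta L},}
#' with `p = L/d` and nu(p) the end-effect correction. The rod regime
#' requires `p >= 2`; for `p > 30` the theory is formally outside its
#' validity range and a warning is raised (the value is still returned).
#'
#' @param length_nm rod length in nm (vectorised).
#' @param diameter_nm rod diameter in nm (default 3.0, the hydrodynamic
#'   diameter of a G-quadruplex including loops and hydration shell).
#' @param conditions a [solvent_conditions()] object.
#' @return D_t in m^2 s^-1; strictly decreasing in `length_nm` at fixed
#'   diameter.
#' @examples
#' rod_diffusion(6, 3)    # ~1.03e-10, the sphere/rod regime boundary
#' rod_diffusion(67, 3)   # ~0.25e-10, a ~49-unit G-wire
#' @export
rod_diffusion <- function(length_nm, diameter_nm = 3.0,
                          conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(length_nm) || any(!is.finite(length_nm)) || any(length_nm <= 0)) {
    stop("`length_nm` must be positive and finite")
  }
  if (!is.numeric(diameter_nm) || length(diameter_nm) != 1L || diameter_nm <= 0) {
    stop("`diameter_nm` must be a single positive number")
  }
  p <- length_nm / diameter_nm
  if (any(p < 2)) {
    stop("axial ratio p < 2: rod model inapplicable, use sphere_diffusion()")
  }
  if (any(p > 30)) {
    warning("axial ratio p > 30 exceeds the validity range of the rod model")
  }
  L_m <- length_nm * 1e-9
  .kB * conditions$temperature_K * (log(p) + end_correction(p)) /
    (3 * pi * conditions$viscosity_Pa_s * L_m)
}

#' Invert the rigid-rod model: length from a diffusion coefficient
#'
#' Finds the unique rod length whose forward diffusion coefficient equals
#' `dt` by bracketed root search on `[2d, 1e4]` nm (the forward model is
#' strictly decreasing in length, so the root is unique when it exists).
#' Lengths with axial ratio above 30 are still returned but carry the flag
#' `"p > 30: exceeds the range of theory validity"`, mirroring the treatment
#' of the longest wires whose lengths cannot be accurately calculated.
#'
#' @param dt translational diffusion coefficient, m^2 s^-1.
#' @param diameter_nm rod diameter in nm (default 3.0).
#' @param conditions a [solvent_conditions()] object.
#' @return A list of class `rod_inversion` with elements `length_nm`,
#'   `axial_ratio`, `dt`, `flags` (character, possibly empty) and
#'   `conditions`.
#' @examples
#' invert_rod_diffusion(0.33e-10)$length_nm   # ~45 nm G-wire
#' @export
invert_rod_diffusion <- function(dt, diameter_nm = 3.0,
                                 conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive diffusion coefficient (m^2 s^-1)")
  }
  lower <- 2 * diameter_nm
  upper <- 1e4
  f <- function(L) rod_diffusion(L, diameter_nm, conditions) - dt
  f_lo <- f(lower)
  f_hi <- suppressWarnings(f(upper))
  if (f_lo < 0) {
    stop(sprintf(paste0(
      "dt = %.3e exceeds the rod-regime boundary %.3e at L = 2d = %.1f nm; ",
      "rod model inapplicable (p < 2), use invert_sphere_diffusion()"),
      dt, dt + f_lo, lower))
  }
  if (f_hi > 0) {
    stop(sprintf(
      "no root in bracket [%g, %g] nm: f(lower) = %.3e, f(upper) = %.3e",
      lower, upper, f_lo, f_hi))
  }
  root <- uniroot(function(L) suppressWarnings(f(L)),
                  interval = c(lower, upper),
                  tol = 1e-8, maxiter = 1000L)
  L <- root$root
  p <- L / diameter_nm
  flags <- character()
  if (p > 30) flags <- c(flags, "p > 30: exceeds the range of theory validity")
  structure(
    list(length_nm = L, axial_ratio = p, dt = dt, diameter_nm = diameter_nm,
         flags = flags, conditions = conditions),
    class = "rod_inversion"
  )
}

#' @export
print.rod_inversion <- function(x, ...) {
  cat(sprintf("Rod inversion: D_t = %.3e m^2/s -> L = %.2f nm (p = %.2f)\n",
              x$dt, x$length_nm, x$axial_ratio))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$conditions)
  invisible(x)
}

#' Stokes-Einstein diffusion of a sphere
#'
#' `sphere_diffusion()` gives the translational diffusion coefficient of a
#' sphere of hydrodynamic radius `radius_nm`; `invert_sphere_diffusion()` is
#' its exact closed-form inverse. Used for species below the rod-regime
#' boundary (short quadruplexes such as the dimeric building blocks), for
#' which no rod model applies.
#'
#' @param radius_nm hydrodynamic radius in nm (vectorised).
#' @param dt translational diffusion coefficient, m^2 s^-1 (vectorised).
#' @param conditions a [solvent_conditions()] object.
#' @return D_t in m^2 s^-1, or R_h in nm.
#' @examples
#' sphere_diffusion(1)                    # ~2.45e-10
#' invert_sphere_diffusion(1.55e-10)      # ~1.6 nm (a 4-quartet dimer)
#' @export
sphere_diffusion <- function(radius_nm, conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(radius_nm) || any(!is.finite(radius_nm)) || any(radius_nm <= 0)) {
    stop("`radius_nm` must be positive and finite")
  }
  .kB * conditions$temperature_K /
    (6 * pi * conditions$viscosity_Pa_s * radius_nm * 1e-9)
}

#' @rdname sphere_diffusion
#' @export
invert_sphere_diffusion <- function(dt, conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(dt) || any(!is.finite(dt)) || any(dt <= 0)) {
    stop("`dt` must be positive and finite")
  }
  .kB * conditions$temperature_K / (6 * pi * conditions$viscosity_Pa_s * dt) * 1e9
}

#' Classify the hydrodynamic regime of a measured diffusion coefficient
#'
#' A species is in the rod regime when its diffusion coefficient is below
#' the forward rod model evaluated at the shortest admissible rod,
#' `L = 2d` (about 1.04e-10 m^2 s^-1 for d = 3.0 nm in room-temperature
#' water -- the boundary is computed from the model, never hard-coded).
#' Faster species are classified as spheres. Rod-regime species whose
#' inverted length gives an axial ratio above 30 are `"out_of_validity"`.
#'
#' @param dt translational diffusion coefficient, m^2 s^-1.
#' @param diameter_nm rod diameter in nm.
#' @param conditions a [solvent_conditions()] object.
#' @return One of `"sphere"`, `"rod"`, `"out_of_validity"`.
#' @examples
#' classify_regime(0.33e-10)   # "rod": a G-wire
#' classify_regime(1.55e-10)   # "sphere": a single building block
#' @export
classify_regime <- function(dt, diameter_nm = 3.0,
                            conditions = solvent_conditions()) {
  stopifnot(inherits(conditions, "solvent_conditions"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  boundary <- rod_diffusion(2 * diameter_nm, diameter_nm, conditions)
  if (dt >= boundary) return("sphere")
  inv <- invert_rod_diffusion(dt, diameter_nm, conditions)
  if (inv$axial_ratio > 30) "out_of_validity" else "rod"
}

#' Sphere/rod regime boundary diffusion coefficient
#'
#' The forward rod model evaluated at the shortest admissible rod
#' (`L = 2d`); species diffusing faster than this are treated as spheres.
#'
#' @inheritParams classify_regime
#' @return D_t in m^2 s^-1.
#' @export
regime_boundary <- function(diameter_nm = 3.0, conditions = solvent_conditions()) {
  rod_diffusion(2 * diameter_nm, diameter_nm, conditions)
}
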