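#' Geometry of the stacked G-quadruplex building block
#'
#' Constants of the structural model used to convert an effective wire
#' length into a number of stacked building blocks. The default unit is the
#' all-parallel, thermodynamically favoured quadruplex of four stacked
#' G-quartets; successive quartets are 0.34 nm apart (the canonical stacking
#' rise), so one unit spans 1.36 nm along the wire axis. Two diameters are
#' carried: the hydrodynamic diameter (3.0 nm, including side loops and the
#' hydration sphere, used in all DLS conversions) and the bare geometric
#' solution diameter (~2.8 nm).
#'
#' @param quartets_per_unit integer >= 1, G-quartets per building block.
#' @param rise_nm axial rise per quartet step, nm.
#' @param hydro_diameter_nm hydrodynamic diameter used by the rod model, nm.
#' @param geom_diameter_nm geometric solution diameter, nm.
#' @return An object of class `building_block_model`.
#' @export
building_block_model <- function(quartets_per_unit = 4L, rise_nm = 0.34,
                                 hydro_diameter_nm = 3.0,
                                 geom_diameter_nm = 2.8) {
  q <- quartets_per_unit
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 1 || q != round(q)) {
    stop("`quartets_per_unit` must be a single integer >= 1")
  }
  for (nm in c("rise_nm", "hydro_diameter_nm", "geom_diameter_nm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm))
    }
  }
  structure(
    list(quartets_per_unit = as.integer(q), rise_nm = rise_nm,
         hydro_diameter_nm = hydro_diameter_nm,
         geom_diameter_nm = geom_diameter_nm),
    class = "building_block_model"
  )
}

#' @export
print.building_block_model <- function(x, ...) {
  cat(sprintf(
    "Building block: %d quartets x %.2f nm rise = %.2f nm/unit; d_hydro = %.1f nm, d_geom = %.1f nm\n",
    x$quartets_per_unit, x$rise_nm, unit_length(x),
    x$hydro_diameter_nm, x$geom_diameter_nm))
  invisible(x)
}

#' Axial length of one building block
#'
#' @param model a [building_block_model()].
#' @return Unit length in nm (1.36 nm for the defaults).
#' @export
unit_length <- function(model = building_block_model()) {
  stopifnot(inherits(model, "building_block_model"))
  model$quartets_per_unit * model$rise_nm
}

#' Number of stacked building blocks in a wire of given length
#'
#' Floor division of the effective length by the unit length. Floor (rather
#' than nearest-integer) rounding counts only complete stacked units: a wire
#' of 28 nm holds 20 full 1.36-nm units (28/1.36 = 20.6), a 67 nm wire 49.
#'
#' @param length_nm effective wire length, nm (vectorised).
#' @param model a [building_block_model()].
#' @return Integer count(s) of stacked units.
#' @examples
#' count_units(c(28, 67))   # 20, 49
#' @export
count_units <- function(length_nm, model = building_block_model()) {
  stopifnot(inherits(model, "building_block_model"))
  if (!is.numeric(length_nm) || any(!is.finite(length_nm)) || any(length_nm <= 0)) {
    stop("`length_nm` must be positive and finite")
  }
  # tiny additive guard so exact unit multiples are not floored down by
  # floating-point representation (e.g. 13 * 1.36 / 1.36)
  as.integer(floor(length_nm / unit_length(model) + 1e-9))
}

#' Wire length of a given number of stacked building blocks
#'
#' Inverse convenience of [count_units()]: `n` units span `n` times the unit
#' length.
#'
#' @param n integer count of stacked units, >= 1 (vectorised).
#' @param model a [building_block_model()].
#' @return Length in nm.
#' @export
length_of <- function(n, model = building_block_model()) {
  stopifnot(inherits(model, "building_block_model"))
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be integer(s) >= 1")
  }
  n * unit_length(model)
}
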