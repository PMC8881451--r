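#' Simulate a two-mode DLS intensity autocorrelation trace
#'
#' Forward model of the two-exponential decay actually fitted by
#' [fit_two_mode()]:
#' \deqn{g_2(t) = 1 + \beta (A_f e^{-q^2 D_f t} + (1-A_f) e^{-q^2 D_s t})^2,}
#' evaluated on a log-spaced lag grid and perturbed by multiplicative
#' Gaussian noise, `g2 * (1 + noise * N(0,1))`. The default mode magnitudes
#' are the two decades-apart diffusivities typical of wire solutions: a
#' fast mode near 1e-10 m^2 s^-1 (individual quadruplexes and wires) and a
#' slow mode near 1e-12 m^2 s^-1 (large unspecific clusters). All
#' randomness is governed by the explicit `seed`; the global RNG state is
#' left untouched.
#'
#' @param d_f,d_s fast and slow diffusion coefficients, m^2 s^-1
#'   (`d_f > d_s > 0`).
#' @param a_f fast-mode amplitude fraction in `[0, 1]`.
#' @param beta Siegert intercept factor.
#' @param noise fractional multiplicative noise level (>= 0).
#' @param t_min_s shortest lag, s.
#' @param decades decades of lag time covered.
#' @param points_per_decade grid density.
#' @param setup a [scattering_setup()] supplying q.
#' @param seed integer seed.
#' @return A [correlation_trace()] with attribute `truth` (the generating
#'   parameters).
#' @export
simulate_g2 <- function(d_f = 1.0e-10, d_s = 1.0e-12, a_f = 0.6, beta = 0.9,
                        noise = 0.01, t_min_s = 1e-7, decades = 8,
                        points_per_decade = 20,
                        setup = scattering_setup(), seed = 1L) {
  if (!(d_f > d_s && d_s > 0)) stop("need d_f > d_s > 0")
  if (a_f < 0 || a_f > 1) stop("`a_f` must lie in [0, 1]")
  if (noise < 0) stop("`noise` must be >= 0")
  q2 <- scattering_vector(setup)^2
  t <- t_min_s * 10^seq(0, decades, length.out = round(decades * points_per_decade) + 1L)
  g1 <- a_f * exp(-q2 * d_f * t) + (1 - a_f) * exp(-q2 * d_s * t)
  g2 <- 1 + beta * g1^2
  if (noise > 0) {
    g2 <- withr::with_seed(as.integer(seed), g2 * (1 + noise * rnorm(length(g2))))
  }
  out <- correlation_trace(t, g2)
  attr(out, "truth") <- list(d_f = d_f, d_s = d_s, a_f = a_f, beta = beta,
                             noise = noise, seed = as.integer(seed))
  out
}

#' Sample a synthetic AFM ridge measurement table
#'
#' Emulates the measurement table produced by ridge detection on AFM
#' images of a wire population: true lengths are log-normal, the observed
#' length adds a constant tip-broadening offset, and heights are Gaussian.
#' The default (`meanlog`, `sdlog`) are calibrated so that, after the
#' 10 nm tip broadening, a sample of 907 wires has arithmetic mean near
#' 22.1 nm with standard error near 0.4 nm -- the shape of a typical
#' single-image-set wire population.
#'
#' @param n number of detected ridges.
#' @param meanlog,sdlog log-normal parameters of the true (tip-free)
#'   lengths, nm.
#' @param tip_offset_nm constant apparent elongation from the finite tip.
#' @param height_mean_nm,height_sd_nm Gaussian height parameters, nm.
#' @param seed integer seed.
#' @return data.frame with columns `length_nm` (observed), `height_nm`,
#'   and attribute `truth`.
#' @export
sample_afm_table <- function(n = 907L, meanlog = log(12.1) - 0.83^2 / 2,
                             sdlog = 0.83, tip_offset_nm = 10,
                             height_mean_nm = 2.0, height_sd_nm = 0.1,
                             seed = 1L) {
  if (n < 1L) stop("`n` must be >= 1")
  if (sdlog < 0 || height_sd_nm < 0 || tip_offset_nm < 0) {
    stop("`sdlog`, `height_sd_nm` and `tip_offset_nm` must be >= 0")
  }
  df <- withr::with_seed(as.integer(seed), {
    true_len <- exp(rnorm(n, meanlog, sdlog))
    data.frame(length_nm = true_len + tip_offset_nm,
               height_nm = rnorm(n, height_mean_nm, height_sd_nm))
  })
  attr(df, "truth") <- list(meanlog = meanlog, sdlog = sdlog,
                            tip_offset_nm = tip_offset_nm,
                            height_mean_nm = height_mean_nm,
                            height_sd_nm = height_sd_nm, n = as.integer(n),
                            seed = as.integer(seed))
  df
}

#' Write an AFM ridge table to CSV
#'
#' @param table data.frame with `length_nm`, `height_nm` (e.g. from
#'   [sample_afm_table()]).
#' @param path file path.
#' @param comment optional comment lines (seed provenance); written with a
#'   leading `# `.
#' @return `path`, invisibly.
#' @export
write_afm_csv <- function(table, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(comment) && !is.null(attr(table, "truth"))) {
    comment <- sprintf("seed=%d", attr(table, "truth")$seed)
  }
  if (length(comment)) writeLines(paste("#", comment), con)
  writeLines("length_nm,height_nm", con)
  writeLines(sprintf("%.6f,%.6f", table$length_nm, table$height_nm), con)
  invisible(path)
}

## radius (nm) of the circle on which four points realise the four chord
## lengths w (nm) exactly once around: sum of subtended angles = 2*pi
.ring_radius <- function(widths_nm) {
  f <- function(r) sum(2 * asin(pmin(widths_nm / (2 * r), 1))) - 2 * pi
  lo <- max(widths_nm) / 2 * (1 + 1e-12)
  if (f(lo) < 0) stop("groove widths not realisable on a single circle")
  uniroot(f, c(lo, 100 * max(widths_nm)), tol = 1e-12)$root
}

#' Build an idealised stacked-quadruplex coordinate ensemble
#'
#' Constructs a minimal pseudo-atomic model of a stack of four-stranded
#' building blocks: per building block, two rings of four loop-residue
#' phosphates (local residue numbers 3 and 8 on chains A-D) placed on a
#' circle whose four chords equal the requested per-groove widths, stacked
#' at the quartet rise with a fixed twist per quartet step. Each frame adds
#' isotropic Gaussian jitter to every coordinate, emulating thermal motion
#' in a trajectory. Only P atoms are emitted -- exactly the roster the
#' groove analysis consumes.
#'
#' @param n_units number of stacked building blocks (1-4 labelled in
#'   summaries).
#' @param rise_nm axial rise per quartet step, nm.
#' @param twist_deg twist per quartet step, degrees.
#' @param groove_widths_nm four target chord widths, nm (groove k lies
#'   between chains k and k+1).
#' @param jitter_sd_A per-coordinate Gaussian jitter, angstrom.
#' @param frames number of frames. The default 490 matches a 9.8 ns
#'   trajectory sampled every 20 ps.
#' @param seed integer seed.
#' @return A `coordinate_ensemble` (see [read_ensemble()]) with attribute
#'   `truth`.
#' @export
build_ideal_ensemble <- function(n_units = 4L, rise_nm = 0.34, twist_deg = 30,
                                 groove_widths_nm = rep(1.7, 4),
                                 jitter_sd_A = 0.5, frames = 490L,
                                 seed = 1L) {
  if (n_units < 1L) stop("`n_units` must be >= 1")
  if (frames < 1L) stop("`frames` must be >= 1")
  if (length(groove_widths_nm) != 4L || any(groove_widths_nm <= 0)) {
    stop("`groove_widths_nm` must be four positive widths")
  }
  if (jitter_sd_A < 0) stop("`jitter_sd_A` must be >= 0")
  r_nm <- .ring_radius(groove_widths_nm)
  # cumulative chord angles; chain k sits at angle theta[k]
  step <- 2 * asin(groove_widths_nm / (2 * r_nm))
  theta <- cumsum(c(0, step[1:3]))
  chains <- c("A", "B", "C", "D")
  atoms <- NULL
  base <- NULL  # 3N base coordinates, angstrom
  for (u in seq_len(n_units)) {
    for (pos in c(3L, 8L)) {
      # loop position 3 flanks the bottom quartet of the unit, 8 the top
      q_global <- (u - 1L) * 4L + if (pos == 3L) 1L else 4L
      z_A <- (q_global - 1L) * rise_nm * 10
      twist <- (q_global - 1L) * twist_deg * pi / 180
      for (k in 1:4) {
        ang <- theta[k] + twist
        atoms <- rbind(atoms, data.frame(
          name = "P", resid = "GWR", resno = (u - 1L) * 10L + pos,
          chain = chains[k], stringsAsFactors = FALSE))
        base <- c(base, r_nm * 10 * cos(ang), r_nm * 10 * sin(ang), z_A)
      }
    }
  }
  n3 <- length(base)
  xyz <- withr::with_seed(as.integer(seed), {
    jit <- if (jitter_sd_A > 0) {
      matrix(rnorm(frames * n3, 0, jitter_sd_A), nrow = frames)
    } else matrix(0, nrow = frames, ncol = n3)
    sweep(jit, 2L, base, "+")
  })
  structure(
    list(atoms = atoms, xyz = xyz, n_frames = as.integer(frames)),
    class = "coordinate_ensemble",
    truth = list(n_units = as.integer(n_units), rise_nm = rise_nm,
                 twist_deg = twist_deg, groove_widths_nm = groove_widths_nm,
                 ring_radius_nm = r_nm, jitter_sd_A = jitter_sd_A,
                 frames = as.integer(frames), seed = as.integer(seed))
  )
}

#' Default groove pair table for the generated stacked ensemble
#'
#' Enumerates the P-P pairs spanning each groove of an ensemble built by
#' [build_ideal_ensemble()]: within every building block, the four chords
#' of the lower loop ring (intra-quadruplex grooves, one per adjacent chain
#' pair), and across every stacking interface the four pairs joining the
#' top ring of one unit to the bottom ring of the next. Interfaces
#' alternate 3'-3' / 5'-5' starting from 3'-3', matching the assembly in
#' which dimers form by 3'-3' stacking and multimerise via their free
#' 5'-quartets.
#'
#' @param n_units number of stacked building blocks.
#' @return data.frame suitable for [groove_analysis()].
#' @export
default_groove_pairs <- function(n_units = 4L) {
  chains <- c("A", "B", "C", "D")
  nxt <- c(2:4, 1)
  rows <- list()
  for (u in seq_len(n_units)) {
    lo <- (u - 1L) * 10L + 3L
    for (k in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("unit%d groove%d", u, k), unit = u,
        interface = "intra",
        chain_a = chains[k], resno_a = lo,
        chain_b = chains[nxt[k]], resno_b = lo,
        stringsAsFactors = FALSE)
    }
  }
  if (n_units > 1L) {
    for (u in seq_len(n_units - 1L)) {
      hi <- (u - 1L) * 10L + 8L
      lo_next <- u * 10L + 3L
      tag <- if (u %% 2L == 1L) "3'-3'" else "5'-5'"
      for (k in 1:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          label = sprintf("interface%d groove%d", u, k), unit = u,
          interface = tag,
          chain_a = chains[k], resno_a = hi,
          chain_b = chains[nxt[k]], resno_b = lo_next,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Emits MODEL/ATOM/ENDMDL records for every frame; the minimal P-only
#' pseudo-residue roster of the generator round-trips through
#' [read_ensemble()]. Generating parameters (including the seed) are
#' recorded in REMARK lines.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  truth <- attr(ensemble, "truth")
  if (!is.null(truth)) {
    writeLines(sprintf("REMARK   6 GWIREKIT SYNTHETIC ENSEMBLE SEED %d",
                       truth$seed), con)
    writeLines(sprintf("REMARK   6 GROOVE WIDTHS NM %s",
                       paste(format(truth$groove_widths_nm), collapse = " ")), con)
  }
  at <- ensemble$atoms
  n <- nrow(at)
  for (f in seq_len(ensemble$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$xyz[f, ]
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n), at$name, at$resid, at$chain, at$resno,
      xyz[3 * seq_len(n) - 2], xyz[3 * seq_len(n) - 1], xyz[3 * seq_len(n)],
      1, 0, "P"), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Simulate a two-state UV melting curve
#'
#' Two-state sigmoid between linear folded and unfolded baselines with
#' additive Gaussian noise:
#' \deqn{A(T) = (1-\theta)(a_f + b_f T) + \theta (a_u + b_u T),\qquad
#'   \theta = 1/(1 + e^{-(T - T_m)/w}).}
#' The folded baseline sits above the unfolded one, reproducing the
#' hypochromic transition at 295 nm on quadruplex unfolding.
#'
#' @param midpoint_C transition midpoint, degrees C.
#' @param width_C transition width parameter, degrees C.
#' @param t_min_C,t_max_C,step_C temperature grid.
#' @param folded_intercept,folded_slope folded baseline `a_f + b_f T`.
#' @param unfolded_intercept,unfolded_slope unfolded baseline.
#' @param noise additive Gaussian noise sd (absorbance units).
#' @param smoothing_window passed to [melting_curve()].
#' @param seed integer seed.
#' @return A [melting_curve()] with attribute `truth`.
#' @export
simulate_melting <- function(midpoint_C = 85, width_C = 3,
                             t_min_C = 5, t_max_C = 95, step_C = 0.5,
                             folded_intercept = 1.0, folded_slope = -5e-4,
                             unfolded_intercept = 0.78, unfolded_slope = -2e-4,
                             noise = 0.002, smoothing_window = 5L, seed = 1L) {
  if (width_C <= 0) stop("`width_C` must be > 0")
  if (noise < 0) stop("`noise` must be >= 0")
  Tc <- seq(t_min_C, t_max_C, by = step_C)
  theta <- 1 / (1 + exp(-(Tc - midpoint_C) / width_C))
  A <- (1 - theta) * (folded_intercept + folded_slope * Tc) +
    theta * (unfolded_intercept + unfolded_slope * Tc)
  if (noise > 0) {
    A <- withr::with_seed(as.integer(seed), A + rnorm(length(A), 0, noise))
  }
  out <- melting_curve(Tc, A, smoothing_window)
  attr(out, "truth") <- list(midpoint_C = midpoint_C, width_C = width_C,
                             noise = noise, seed = as.integer(seed))
  out
}

#' Write a melting curve to CSV (`temp_C, A295` columns)
#'
#' @param curve a [melting_curve()].
#' @param path file path.
#' @param comment optional comment lines.
#' @return `path`, invisibly.
#' @export
write_melting_csv <- function(curve, path, comment = NULL) {
  stopifnot(inherits(curve, "melting_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(comment) && !is.null(attr(curve, "truth"))) {
    comment <- sprintf("seed=%d", attr(curve, "truth")$seed)
  }
  if (length(comment)) writeLines(paste("#", comment), con)
  writeLines("temp_C,A295", con)
  writeLines(sprintf("%.4f,%.8f", curve$temperature_C, curve$a295), con)
  invisible(path)
}
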