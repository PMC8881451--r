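#' Read a multi-model PDB file as a coordinate ensemble
#'
#' Wraps [bio3d::read.pdb()] with `multi = TRUE` and validates that every
#' MODEL block carries the same atom roster (same number of ATOM/HETATM
#' records); divergent rosters are rejected with the index of the first
#' offending model. Model records map to frames in file order.
#'
#' @param path path to a (multi-model) PDB file.
#' @return An object of class `coordinate_ensemble` with `atoms`
#'   (data.frame: `name`, `resid`, `resno`, `chain`), `xyz` (frames x 3N
#'   matrix, angstrom, bio3d layout) and `n_frames`.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("malformed multi-model PDB: unbalanced MODEL/ENDMDL records")
    }
    counts <- mapply(function(s, e) {
      sum(grepl("^(ATOM  |HETATM)", lines[s:e]))
    }, model_starts, model_ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop(sprintf(
        "atom roster mismatch: model %d has %d atoms, model 1 has %d",
        bad, counts[bad], counts[1L]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  atoms <- data.frame(name = pdb$atom$elety, resid = pdb$atom$resid,
                      resno = pdb$atom$resno, chain = pdb$atom$chain,
                      stringsAsFactors = FALSE)
  if (3L * nrow(atoms) != ncol(xyz)) {
    stop("coordinate block inconsistent with atom roster")
  }
  structure(
    list(atoms = atoms, xyz = xyz, n_frames = nrow(xyz)),
    class = "coordinate_ensemble"
  )
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  cat(sprintf("Coordinate ensemble: %d frame(s), %d atoms\n",
              x$n_frames, nrow(x$atoms)))
  invisible(x)
}

## index (row) of a named atom in a (chain, resno) residue
.atom_row <- function(ensemble, chain, resno, name = "P") {
  hit <- which(ensemble$atoms$chain == chain &
               ensemble$atoms$resno == resno &
               ensemble$atoms$name == name)
  if (!length(hit)) {
    stop(sprintf("no atom '%s' in residue %s/%d", name, chain, resno))
  }
  hit[1L]
}

#' Per-frame phosphate-phosphate distance series for one groove
#'
#' The groove dimension is the Euclidean distance between the P atoms of
#' the two loop residues flanking the groove, measured in every frame of
#' the ensemble. Coordinates are in angstrom in the file; distances are
#' reported in nm.
#'
#' @param ensemble a [read_ensemble()] result (or the output of
#'   [build_ideal_ensemble()]).
#' @param chain_a,resno_a chain id and residue number of the first loop
#'   residue.
#' @param chain_b,resno_b chain id and residue number of the second.
#' @param label groove label for reports.
#' @param unit building-block index the groove belongs to (1-4 in a Q4t
#'   stack), or `NA`.
#' @param interface one of `"intra"`, `"3'-3'"`, `"5'-5'"`.
#' @param atom atom name holding the phosphate position (default `"P"`).
#' @return An object of class `groove_series` with `distances_nm` (one
#'   value per frame) plus the labelling fields.
#' @export
groove_series <- function(ensemble, chain_a, resno_a, chain_b, resno_b,
                          label = sprintf("%s%d-%s%d", chain_a, resno_a,
                                          chain_b, resno_b),
                          unit = NA_integer_, interface = "intra",
                          atom = "P") {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  interface <- match.arg(interface, c("intra", "3'-3'", "5'-5'"))
  ia <- .atom_row(ensemble, chain_a, resno_a, atom)
  ib <- .atom_row(ensemble, chain_b, resno_b, atom)
  ca <- ensemble$xyz[, (3L * ia - 2L):(3L * ia), drop = FALSE]
  cb <- ensemble$xyz[, (3L * ib - 2L):(3L * ib), drop = FALSE]
  d_nm <- sqrt(rowSums((ca - cb)^2)) / 10
  structure(
    list(label = label, unit = unit, interface = interface,
         pair = list(a = c(chain = chain_a, resno = resno_a),
                     b = c(chain = chain_b, resno = resno_b)),
         distances_nm = as.numeric(d_nm)),
    class = "groove_series"
  )
}

#' Per-groove means, dispersions and the periodicity score
#'
#' Summarises a set of groove distance series: mean and standard deviation
#' per groove (one value per frame enters each), grouped by building-block
#' index and stacking-interface tag. A single scalar, the periodicity
#' score, condenses how uniform the grooves are: the maximum over grooves
#' of the absolute deviation of the groove mean from the grand mean. A
#' perfectly periodic stack (all grooves equal) scores 0; structures whose
#' loops distort the grooves score higher.
#'
#' @param series a list of [groove_series()] objects (at least one, each
#'   with >= 2 frames).
#' @return An object of class `groove_summary`: data.frame `per_groove`
#'   (`label`, `unit`, `interface`, `mean_nm`, `sd_nm`, `n`), plus
#'   `grand_mean_nm` and `periodicity_score_nm`.
#' @export
groove_summary <- function(series) {
  if (inherits(series, "groove_series")) series <- list(series)
  if (!length(series) || !all(vapply(series, inherits, TRUE, "groove_series"))) {
    stop("`series` must be a non-empty list of groove_series objects")
  }
  for (s in series) {
    if (length(s$distances_nm) < 2L) {
      stop(sprintf("groove '%s' has fewer than 2 frames", s$label))
    }
  }
  per <- data.frame(
    label = vapply(series, `[[`, "", "label"),
    unit = vapply(series, function(s) as.integer(s$unit), 1L),
    interface = vapply(series, `[[`, "", "interface"),
    mean_nm = vapply(series, function(s) mean(s$distances_nm), 1),
    sd_nm = vapply(series, function(s) sd(s$distances_nm), 1),
    n = vapply(series, function(s) length(s$distances_nm), 1L),
    stringsAsFactors = FALSE
  )
  grand <- mean(per$mean_nm)
  structure(
    list(per_groove = per, grand_mean_nm = grand,
         periodicity_score_nm = max(abs(per$mean_nm - grand))),
    class = "groove_summary"
  )
}

#' @export
print.groove_summary <- function(x, ...) {
  cat("Groove summary\n")
  print(x$per_groove, row.names = FALSE)
  cat(sprintf("grand mean = %.3f nm, periodicity score = %.3f nm\n",
              x$grand_mean_nm, x$periodicity_score_nm))
  invisible(x)
}

#' Groove analysis of an ensemble from an explicit pair table
#'
#' Convenience wrapper: one [groove_series()] per row of `pairs`, then
#' [groove_summary()]. The pairing of loop-residue phosphates to grooves is
#' explicit configuration (see [default_groove_pairs()] for the layout
#' matching the built-in ensemble generator): which P-P pairs span which
#' groove depends on the fold and is not inferred from coordinates.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param pairs data.frame with columns `label`, `unit`, `interface`,
#'   `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @return A list with `series` (list of `groove_series`) and `summary`
#'   (a `groove_summary`).
#' @export
groove_analysis <- function(ensemble, pairs) {
  need <- c("label", "unit", "interface", "chain_a", "resno_a", "chain_b", "resno_b")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    stop("`pairs` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  series <- lapply(seq_len(nrow(pairs)), function(i) {
    groove_series(ensemble,
                  chain_a = pairs$chain_a[i], resno_a = pairs$resno_a[i],
                  chain_b = pairs$chain_b[i], resno_b = pairs$resno_b[i],
                  label = pairs$label[i], unit = pairs$unit[i],
                  interface = pairs$interface[i])
  })
  list(series = series, summary = groove_summary(series))
}

#' Write groove distance series to CSV
#'
#' Long format: columns `groove_label, frame, distance_nm`.
#'
#' @param series a list of [groove_series()] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_groove_csv <- function(series, path) {
  if (inherits(series, "groove_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(groove_label = s$label,
               frame = seq_along(s$distances_nm),
               distance_nm = s$distances_nm)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
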