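# build a coordinate_ensemble directly from per-frame coordinates
# coords: list of n_atoms x 3 matrices (angstrom), one per frame
make_ensemble <- function(atoms, coords) {
  xyz <- do.call(rbind, lapply(coords, function(m) as.numeric(t(m))))
  structure(list(atoms = atoms, xyz = xyz, n_frames = length(coords)),
            class = "coordinate_ensemble")
}

two_atom_roster <- function() {
  data.frame(name = "P", resid = "GWR", resno = c(3L, 3L),
             chain = c("A", "B"), stringsAsFactors = FALSE)
}

# random proper rotation matrix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
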