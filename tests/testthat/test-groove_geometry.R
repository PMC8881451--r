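test_that("a fixed 18 angstrom separation gives a constant 1.80 nm series", {
  coords <- replicate(12, rbind(c(0, 0, 0), c(18, 0, 0)), simplify = FALSE)
  ens <- make_ensemble(two_atom_roster(), coords)
  s <- groove_series(ens, "A", 3, "B", 3)
  expect_equal(s$distances_nm, rep(1.80, 12))
})

test_that("jittered separations average to the true width", {
  set.seed(11)
  coords <- replicate(2000, {
    rbind(c(0, 0, 0), c(18, 0, 0)) + matrix(rnorm(6, 0, 0.5), 2, 3)
  }, simplify = FALSE)
  ens <- make_ensemble(two_atom_roster(), coords)
  s <- groove_series(ens, "A", 3, "B", 3)
  expect_equal(mean(s$distances_nm), 1.80, tolerance = 0.02 / 1.80)
})

test_that("series distances match a brute-force recomputation exactly", {
  ens <- build_ideal_ensemble(frames = 30L, seed = 5)
  s <- groove_series(ens, "A", 3, "B", 3)
  set.seed(2)
  for (f in sample(30, 5)) {
    ia <- which(ens$atoms$chain == "A" & ens$atoms$resno == 3)
    ib <- which(ens$atoms$chain == "B" & ens$atoms$resno == 3)
    a <- ens$xyz[f, (3 * ia - 2):(3 * ia)]
    b <- ens$xyz[f, (3 * ib - 2):(3 * ib)]
    expect_equal(s$distances_nm[f], sqrt(sum((a - b)^2)) / 10,
                 tolerance = 1e-12)
  }
})

test_that("distances are invariant under per-frame rotation and translation", {
  ens <- build_ideal_ensemble(frames = 10L, seed = 8)
  set.seed(9)
  n <- nrow(ens$atoms)
  xyz2 <- ens$xyz
  for (f in seq_len(10)) {
    R <- random_rotation()
    t3 <- rnorm(3, 0, 50)
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    xyz2[f, ] <- as.numeric(t(m %*% t(R) + rep(t3, each = n)))
  }
  ens2 <- ens
  ens2$xyz <- xyz2
  s1 <- groove_series(ens, "B", 3, "C", 3)
  s2 <- groove_series(ens2, "B", 3, "C", 3)
  expect_equal(s1$distances_nm, s2$distances_nm, tolerance = 1e-9)
})

test_that("summary statistics respond correctly to identical and inflated grooves", {
  mk <- function(label, values) {
    structure(list(label = label, unit = 1L, interface = "intra",
                   pair = NULL, distances_nm = values),
              class = "groove_series")
  }
  same <- lapply(1:5, function(i) mk(paste0("g", i), rep(1.7, 40)))
  s <- groove_summary(same)
  expect_equal(s$per_groove$sd_nm, rep(0, 5))
  expect_equal(s$periodicity_score_nm, 0)
  # inflate one groove by +0.3 nm: score = 0.3 * (1 - 1/G)
  G <- 5
  inflated <- same
  inflated[[2]] <- mk("g2", rep(2.0, 40))
  s2 <- groove_summary(inflated)
  expect_equal(s2$periodicity_score_nm, 0.3 * (1 - 1 / G), tolerance = 1e-12)
})

test_that("summaries are invariant to frame order", {
  ens <- build_ideal_ensemble(frames = 25L, seed = 13)
  s <- groove_series(ens, "A", 3, "B", 3)
  perm <- s
  set.seed(1)
  perm$distances_nm <- sample(s$distances_nm)
  a <- groove_summary(list(s))
  b <- groove_summary(list(perm))
  expect_equal(a$per_groove$mean_nm, b$per_groove$mean_nm)
  expect_equal(a$per_groove$sd_nm, b$per_groove$sd_nm)
})

test_that("imposed per-groove widths are recovered from a generated ensemble", {
  widths <- c(1.6, 1.8, 1.7, 1.9)
  ens <- build_ideal_ensemble(groove_widths_nm = widths, frames = 200L,
                              jitter_sd_A = 0.5, seed = 21)
  ga <- groove_analysis(ens, default_groove_pairs(4))
  intra <- ga$summary$per_groove[ga$summary$per_groove$interface == "intra", ]
  sigma_nm <- 0.05
  for (i in seq_len(nrow(intra))) {
    g <- as.integer(sub(".*groove", "", intra$label[i]))
    # first-order jitter convolution bias: E[d] ~ w + 2 sigma^2 / w
    expected <- widths[g] + 2 * sigma_nm^2 / widths[g]
    tol <- 3 * intra$sd_nm[i] / sqrt(intra$n[i])
    expect_lt(abs(intra$mean_nm[i] - expected), tol)
  }
})

test_that("multi-model PDB files round-trip through write and read", {
  ens <- build_ideal_ensemble(n_units = 2L, frames = 3L, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_identical(back$n_frames, 3L)
  expect_identical(nrow(back$atoms), nrow(ens$atoms))
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  s1 <- groove_series(ens, "A", 3, "B", 3)
  s2 <- groove_series(back, "A", 3, "B", 3)
  expect_equal(s1$distances_nm, s2$distances_nm, tolerance = 1e-3)
})

test_that("single-model files read as one frame", {
  ens <- build_ideal_ensemble(n_units = 1L, frames = 1L, jitter_sd_A = 0,
                              seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  expect_identical(read_ensemble(path)$n_frames, 1L)
})

test_that("divergent atom rosters across models are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(i, x) sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    i, "P", "GWR", "A", i, x, 0, 0, 1, 0, "P")
  writeLines(c("MODEL        1", atom(1, 0), atom(2, 18), "ENDMDL",
               "MODEL        2", atom(1, 0), "ENDMDL", "END"), path)
  expect_error(read_ensemble(path), "roster mismatch.*model 2")
})

test_that("missing phosphate atoms give a lookup error", {
  ens <- build_ideal_ensemble(frames = 2L, seed = 1)
  expect_error(groove_series(ens, "A", 99, "B", 3), "no atom 'P'")
})
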