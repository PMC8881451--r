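test_that("generators are pure functions of their seed", {
  t1 <- simulate_g2(noise = 0.01, seed = 5)
  t2 <- simulate_g2(noise = 0.01, seed = 5)
  t3 <- simulate_g2(noise = 0.01, seed = 6)
  expect_identical(t1$g2, t2$g2)
  expect_false(identical(t1$g2, t3$g2))

  a1 <- sample_afm_table(n = 50, seed = 3)
  a2 <- sample_afm_table(n = 50, seed = 3)
  expect_identical(a1$length_nm, a2$length_nm)

  m1 <- simulate_melting(seed = 4)
  m2 <- simulate_melting(seed = 4)
  expect_identical(m1$a295, m2$a295)

  e1 <- build_ideal_ensemble(frames = 5L, seed = 9)
  e2 <- build_ideal_ensemble(frames = 5L, seed = 9)
  expect_identical(e1$xyz, e2$xyz)
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123)
  expected <- runif(1)
  set.seed(123)
  invisible(simulate_g2(noise = 0.01, seed = 99))
  invisible(sample_afm_table(n = 10, seed = 99))
  invisible(build_ideal_ensemble(frames = 2L, seed = 99))
  invisible(simulate_melting(seed = 99))
  expect_identical(runif(1), expected)
})

test_that("seeded trace files are byte-identical across re-runs", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(simulate_g2(noise = 0.01, seed = 8), p1, comment = "seed=8")
  write_trace_csv(simulate_g2(noise = 0.01, seed = 8), p2, comment = "seed=8")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every generator output passes the matching reader unmodified", {
  expect_s3_class(simulate_g2(seed = 1), "correlation_trace")
  expect_s3_class(simulate_melting(seed = 1), "melting_curve")

  afm <- sample_afm_table(n = 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_afm_csv(afm, path)
  back <- read_afm_csv(path)
  expect_equal(back$length_nm, afm$length_nm, tolerance = 1e-6)

  mc <- simulate_melting(seed = 2)
  write_melting_csv(mc, path)
  mcb <- read_melting_csv(path)
  expect_equal(mcb$a295, mc$a295, tolerance = 1e-7)
})

test_that("degenerate generator settings behave as constructed", {
  afm <- sample_afm_table(n = 30, sdlog = 0, height_sd_nm = 0, seed = 1)
  expect_equal(length(unique(afm$length_nm)), 1L)
  ens <- build_ideal_ensemble(jitter_sd_A = 0, frames = 4L, seed = 1)
  ga <- groove_analysis(ens, default_groove_pairs(4))
  expect_equal(ga$summary$per_groove$sd_nm, rep(0, nrow(ga$summary$per_groove)),
               tolerance = 1e-12)
})

test_that("the default AFM population reproduces the target summary shape", {
  afm <- sample_afm_table(seed = 17)   # N = 907, tip-broadened
  fit <- fit_length_distribution(afm$length_nm)
  expect_equal(fit$mean_nm, 22.1, tolerance = 3 * 0.4 / 22.1)
  # removing the tip offset recovers the generating log-normal parameters
  fit0 <- fit_length_distribution(tip_correct(afm$length_nm))
  truth <- attr(afm, "truth")
  expect_equal(fit0$meanlog, truth$meanlog, tolerance = 0.1)
  expect_equal(fit0$sdlog, truth$sdlog, tolerance = 0.1)
})

test_that("log-normal parameters are recovered across a seed and parameter grid", {
  for (mu in c(2.0, 2.6)) {
    for (sigma in c(0.4, 0.7)) {
      errs_mu <- errs_sg <- numeric(0)
      for (s in 1:5) {
        afm <- sample_afm_table(n = 500, meanlog = mu, sdlog = sigma,
                                tip_offset_nm = 0, seed = s)
        fit <- fit_length_distribution(afm$length_nm)
        errs_mu <- c(errs_mu, fit$meanlog - mu)
        errs_sg <- c(errs_sg, fit$sdlog - sigma)
      }
      expect_lt(abs(mean(errs_mu)), 3 * sigma / sqrt(500 * 5) * 3)
      expect_lt(abs(mean(errs_sg)), 0.05)
    }
  }
})

test_that("unrealisable groove widths are rejected", {
  expect_error(build_ideal_ensemble(groove_widths_nm = c(10, 0.1, 0.1, 0.1)),
               "not realisable")
  expect_error(build_ideal_ensemble(groove_widths_nm = c(1, 1)), "four")
})
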