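test_that("impulse response functions match their closed forms", {
  t <- seq(0, 600, by = 0.01)
  # Tofts at t = 0 equals K_trans; its integral over time equals Ve
  expect_equal(irf("tofts", list(K_trans = 1, Ve = 0.3), 0), 1)
  y <- irf("tofts", list(K_trans = 1.4, Ve = 0.3), t)
  integral <- sum((y[-1] + y[-length(y)]) / 2) * 0.01 / 60   # dt in minutes
  expect_equal(integral, 0.3, tolerance = 1e-6)
  # sharp Fermi edge: plateau at F before MTT, cliff after
  f <- irf("fermi", list(F = 2.5, k = 50, MTT = 6), t)
  expect_equal(f[t < 5.5][1], 2.5, tolerance = 1e-9)
  expect_lt(max(f[t > 6.5]), 1e-9)
  expect_error(irf("spam", list(), t), "unknown")
  expect_error(irf("tofts", list(K_trans = 1, Ve = 0), t), "Ve")
  expect_error(irf("modified_tofts",
                   list(K_trans = 1, Ve = 0.7, Vp = 0.4), t), "<=")
})

test_that("trapezoidal convolution matches the closed form at O(dt^2)", {
  tau <- 20; kt <- 0.8; ve <- 0.25; kep <- kt / ve
  errs <- sapply(c(1, 0.5, 0.25), function(dt) {
    t <- seq(0, 59, by = dt)
    aif <- aif_curve(t, exp(-t / tau))
    num <- forward_model(aif, "tofts", list(K_trans = kt, Ve = ve))
    tm <- t / 60; tau_m <- tau / 60
    ana <- kt * (exp(-kep * tm) - exp(-tm / tau_m)) / (1 / tau_m - kep)
    max(abs(num - ana)) / max(abs(ana))
  })
  expect_lt(errs[2], 1e-4)                     # dt = 0.5 s
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.1)   # halving dt: /4
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.1)
})

test_that("modified-Tofts collapses onto Tofts at Vp = 0", {
  a <- std_aif()
  p <- list(K_trans = 1.6, Ve = 0.3)
  ct <- forward_model(a, "tofts", p, delay = 2)
  cm <- forward_model(a, "modified_tofts", c(p, Vp = 0), delay = 2)
  expect_identical(ct, cm)
})

test_that("forward model is causal and shifts exactly by grid delays", {
  a <- std_aif()
  p <- params_for_mbf("fermi", 3)
  c0 <- forward_model(a, "fermi", p, delay = 0)
  c3 <- forward_model(a, "fermi", p, delay = 3)
  expect_equal(c3[4:60], c0[1:57], tolerance = 1e-12)
  expect_true(all(abs(c3[1:3]) < 1e-12))
  expect_error(forward_model(aif_curve(c(0, 1, 3, 7), rep(1, 4)), "tofts",
                             list(K_trans = 1, Ve = 0.2)), "uniform")
})

test_that("fitting a self-generated curve recovers the parameters", {
  a <- std_aif()
  tc <- simulate_tissue_curve(a, "tofts", list(K_trans = 0.8, Ve = 0.15),
                              delay = 2)
  f <- fit_curve(tc, a, "tofts", list(delay_max = 6))
  expect_true(f$converged)
  expect_equal(f$params$K_trans, 0.8, tolerance = 0.01)
  expect_equal(f$params$Ve, 0.15, tolerance = 0.01)
  expect_equal(f$delay, 2)
  expect_equal(f$mbf, 0.8 / 1.05, tolerance = 0.01)
  tf <- simulate_tissue_curve(a, "fermi", list(F = 3, k = 0.4, MTT = 6),
                              delay = 2)
  ff <- fit_curve(tf, a, "fermi", list(delay_max = 6))
  expect_equal(ff$params$F, 3, tolerance = 0.01)
  # reported flow is the initial IRF amplitude F / (1 + exp(-k MTT))
  expect_equal(ff$mbf, 3 / (1 + exp(-0.4 * 6)), tolerance = 0.01)
})

test_that("degenerate flat curves are flagged with zero flow", {
  a <- std_aif()
  f <- fit_curve(rep(0, 60), a, "tofts")
  expect_false(f$converged)
  expect_equal(f$mbf, 0)
  expect_equal(f$flag, "flat")
  expect_error(fit_curve(rep(0, 5), aif_curve(0:4, rep(1, 5)), "tofts"),
               "10 frames")
})

test_that("halving the AIF amplitude doubles the fitted flow", {
  a <- std_aif()
  tc <- simulate_tissue_curve(a, "tofts", params_for_mbf("tofts", 2),
                              delay = 2)
  half <- aif_curve(a$times, a$blood / 2, a$hematocrit)
  f_full <- fit_curve(tc, a, "tofts", list(delay_max = 4))
  f_half <- fit_curve(tc, half, "tofts", list(delay_max = 4))
  expect_equal(f_half$mbf / f_full$mbf, 2, tolerance = 0.01)
})

test_that("reported MBF increases strictly with the generating flow", {
  a <- std_aif()
  flows <- seq(0.5, 4.5, by = 0.5)
  for (m in c("tofts", "fermi")) {
    mbf <- vapply(flows, function(fl) {
      tc <- simulate_tissue_curve(a, m, params_for_mbf(m, fl), delay = 2)
      fit_curve(tc, a, m, list(delay_grid = 2))$mbf
    }, numeric(1))
    expect_true(all(diff(mbf) > 0))
    expect_equal(mbf, flows, tolerance = 0.01)
  }
})

test_that("fit_map recovers a noise-free phantom and respects the mask", {
  ph <- small_phantom(noise_sd = 0)
  m <- fit_map(ph$stress, ph$aif, "tofts", ph$mask,
               list(delay_grid = c(0, 1, 2, 3, 4)))
  rel <- abs(m$values[ph$mask] - ph$truth$stress$values[ph$mask]) /
    ph$truth$stress$values[ph$mask]
  expect_lt(max(rel), 0.02)
  expect_equal(m$meta$n_failed, 0)
  expect_true(all(is.na(m$values[!ph$mask])))
  # one-pixel mask reproduces the single-curve fit
  one <- array(FALSE, dim(ph$mask))
  px <- which(ph$mask, arr.ind = TRUE)[1, ]
  one[px[1], px[2], px[3]] <- TRUE
  m1 <- fit_map(ph$stress, ph$aif, "tofts", one, list(delay_grid = 2))
  f1 <- fit_curve(ph$stress$data[px[1], px[2], px[3], ], ph$aif, "tofts",
                  list(delay_grid = 2))
  expect_equal(m1$values[px[1], px[2], px[3]], f1$mbf)
  expect_error(fit_map(ph$stress, ph$aif, "tofts",
                       array(FALSE, dim(ph$mask))), "empty")
})

test_that("MPR maps are stress/rest ratios with a rest floor", {
  vals <- array(NA_real_, c(4, 4, 1))
  mask <- array(TRUE, c(4, 4, 1))
  rest <- vals; rest[] <- 1.2; rest[1, 1, 1] <- 0.05   # below floor
  stress <- vals; stress[] <- 2.4; stress[1, 1, 1] <- 2.4
  mpr <- compute_mpr(parametric_map(stress, mask),
                     parametric_map(rest, mask))
  expect_equal(unique(mpr$values[mpr$mask]), 2)
  expect_false(mpr$mask[1, 1, 1])
  expect_equal(mpr$meta$n_floor_excluded, 1)
  empty <- parametric_map(vals, array(FALSE, c(4, 4, 1)))
  expect_error(compute_mpr(parametric_map(stress, mask), empty), "disjoint")
})
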