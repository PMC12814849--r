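test_that("saturation-recovery signal model is normalised, monotone, saturating", {
  sq <- seq_params(saturation_delay = 0.110)
  expect_equal(sr_signal(0, sq), 1)
  grid <- seq(0, 10, by = 0.01)
  s <- sr_signal(grid, sq)
  expect_true(all(diff(s) > 0))
  ceiling_val <- 1 / (1 - exp(-sq$saturation_delay / sq$baseline_T1))
  expect_true(all(s < ceiling_val))
  expect_gt(sr_signal(50, sq), 0.99 * ceiling_val)
  # long saturation delay: fully recovered, signal ~ 1 regardless of C
  long <- seq_params(saturation_delay = 50)
  expect_equal(sr_signal(c(0, 2, 8), long), c(1, 1, 1), tolerance = 1e-6)
})

test_that("signal inversion is exact over the invertible range", {
  set.seed(21)
  for (i in 1:20) {
    sq <- seq_params(saturation_delay = runif(1, 0.02, 0.3),
                     relaxivity_r1 = runif(1, 2, 6),
                     baseline_T1 = runif(1, 0.8, 2))
    conc <- runif(8, 0, 8)
    inv <- sr_signal_inverse(sr_signal(conc, sq), sq)
    expect_true(all(inv$invertible))
    expect_equal(inv$conc, conc, tolerance = 1e-10)
  }
  sq <- seq_params()
  ceiling_val <- 1 / (1 - exp(-sq$saturation_delay / sq$baseline_T1))
  bad <- sr_signal_inverse(ceiling_val * 1.01, sq)
  expect_false(bad$invertible)
  expect_true(is.na(bad$conc))
})

test_that("concentration_from_signal recovers known concentrations", {
  sq <- seq_params(baseline_frames = 3)
  times <- seq(0, 19)
  conc_true <- c(rep(0, 3), rep(1.5, 17))
  sig <- sr_signal(conc_true, sq) * 350          # arbitrary scanner gain
  arr <- array(rep(sig, each = 4), c(2, 2, 1, 20))
  ser <- dynamic_series(arr, times, domain = "signal")
  out <- concentration_from_signal(ser, sq)
  expect_equal(out$data[1, 1, 1, ], conc_true, tolerance = 1e-10)
  expect_equal(out$meta$n_noninvertible, 0)
  # constant-at-baseline series converts to all-zero concentration
  flat <- dynamic_series(array(120, c(2, 2, 1, 20)), times, domain = "signal")
  expect_true(all(abs(concentration_from_signal(flat, sq)$data) < 1e-12))
  # saturated samples are flagged non-invertible
  ceiling_val <- 1 / (1 - exp(-sq$saturation_delay / sq$baseline_T1))
  sat <- sig; sat[10] <- 350 * ceiling_val * 1.05
  arr2 <- array(rep(sat, each = 1), c(1, 1, 1, 20))
  out2 <- concentration_from_signal(dynamic_series(arr2, times,
                                                   domain = "signal"), sq)
  expect_gt(out2$meta$n_noninvertible, 0)
  expect_true(is.na(out2$data[1, 1, 1, 10]))
})

test_that("proton-density normalisation removes a multiplicative shading field", {
  times <- seq(0, 9)
  base <- array(rep(seq(1, 2, length.out = 16), 10), c(4, 4, 1, 10))
  shade <- matrix(runif(16, 0.5, 2), 4, 4)
  shaded <- sweep(base, 1:3, array(shade, c(4, 4, 1)), `*`)
  ser <- dynamic_series(shaded, times, domain = "signal")
  out <- pd_normalize(ser, shade)
  expect_equal(out$data, base, tolerance = 1e-12)
  one <- pd_normalize(ser, matrix(1, 4, 4))
  expect_equal(one$data, shaded)
  half <- pd_normalize(ser, matrix(2, 4, 4))
  expect_equal(half$data, shaded / 2)
  expect_error(pd_normalize(ser, matrix(0, 4, 4)), "zero")
})

test_that("normalisation cancels in the baseline division", {
  # concentration_from_signal commutes with pd_normalize
  sq <- seq_params(baseline_frames = 3)
  times <- seq(0, 14)
  conc_true <- c(rep(0, 3), seq(0.2, 2.4, length.out = 12))
  sig <- sr_signal(conc_true, sq) * 200
  arr <- array(rep(sig, each = 9), c(3, 3, 1, 15))
  shade <- matrix(runif(9, 0.5, 2), 3, 3)
  ser <- dynamic_series(sweep(arr, 1:3, array(shade, c(3, 3, 1)), `*`),
                        times, domain = "signal")
  direct <- concentration_from_signal(ser, sq)
  via_pd <- concentration_from_signal(pd_normalize(ser, shade), sq)
  expect_equal(direct$data, via_pd$data, tolerance = 1e-10)
})

test_that("AIF extraction averages the in-disk pixels and plasma-corrects", {
  times <- seq(0, 9)
  arr <- array(3, c(21, 21, 1, 10))
  ser <- dynamic_series(arr, times, pixdim = 1, domain = "concentration")
  a <- extract_aif(ser, aif_roi(c(11, 11), diameter = 10), hematocrit = 0.5)
  expect_equal(a$blood, rep(3, 10))
  expect_equal(a$plasma, rep(6, 10))    # uniform value v, Hct 0.5 -> 2v
  # ROI mean equals the brute-force mean over enumerated in-disk pixels
  set.seed(8)
  arr2 <- array(rnorm(21 * 21 * 10, 5), c(21, 21, 1, 10))
  ser2 <- dynamic_series(arr2, times, pixdim = 1.5, domain = "concentration")
  roi <- aif_roi(c(10, 12), diameter = 9)
  a2 <- extract_aif(ser2, roi, hematocrit = 0.42)
  inside <- which(outer((1:21 - 10)^2, (1:21 - 12)^2, `+`) * 1.5^2 <=
                    (9 / 2)^2, arr.ind = TRUE)
  brute <- sapply(1:10, function(f) mean(arr2[cbind(inside, 1, f)]))
  expect_equal(a2$blood, brute, tolerance = 1e-12)
  # sub-pixel ROI degenerates to the single nearest pixel
  tiny <- extract_aif(ser2, aif_roi(c(10, 12), diameter = 0.5), 0.42)
  expect_equal(tiny$blood, arr2[10, 12, 1, ])
  expect_error(extract_aif(ser2, aif_roi(c(1, 1), diameter = 12), 0.42),
               "outside")
  expect_error(extract_aif(ser2, roi, hematocrit = 1.2), "hematocrit")
})
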