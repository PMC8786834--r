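test_that("SNR definition: forced analytic values and validation", {
  dim2 <- c(20, 20)
  roi <- rect_mask(dim2, 11:20, 1:20)
  nroi <- rect_mask(dim2, 1:10, 1:20)

  # noise block standardised to mean 0 / sd exactly 1; ROI constant 10
  set.seed(1)
  noise <- matrix(as.numeric(scale(rnorm(200))), 10, 20)
  m <- rbind(noise, matrix(10, 10, 20))
  res <- compute_snr(m, roi, nroi)
  expect_equal(res$roi_mean_snr, 10 / sqrt(2), tolerance = 1e-12)

  # ROI mean equal to noise mean gives exactly zero
  m0 <- rbind(noise, matrix(0, 10, 20))
  expect_equal(compute_snr(m0, roi, nroi)$roi_mean_snr, 0, tolerance = 1e-12)

  expect_error(compute_snr(m, roi, roi), "disjoint")
  expect_error(compute_snr(rbind(matrix(1, 10, 20), matrix(5, 10, 20)),
                           roi, nroi), "zero variance")
})

test_that("SNR is invariant under joint rescaling and linear over the ROI", {
  set.seed(2)
  m <- matrix(abs(rnorm(400, 5)), 20, 20)
  roi <- rect_mask(c(20, 20), 11:20, 1:20)
  nroi <- rect_mask(c(20, 20), 1:10, 1:20)
  r1 <- compute_snr(m, roi, nroi)
  r2 <- compute_snr(7.3 * m, roi, nroi)
  expect_equal(r1$roi_mean_snr, r2$roi_mean_snr, tolerance = 1e-12)

  # mean over the ROI of the voxelwise map equals SNR of the ROI mean signal
  by_map <- mean(r1$snr_map[roi])
  of_mean <- (mean(m[roi]) - r1$noise_mean) / (sqrt(2) * r1$noise_sd)
  expect_equal(by_map, of_mean, tolerance = 1e-12)
})

test_that("pure Rician noise yields a near-zero mean ROI SNR over 100 seeds", {
  vals <- vapply(seq_len(100), function(i)
    hp13c:::rician_null_snr(seed = 1e4 + i), 0)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("time summation and total carbon arithmetic", {
  sig <- array(0, c(4, 4, 20, 2),
               dimnames = list(NULL, NULL, NULL, c("pyruvate", "lactate")))
  sig[1, 1, , "pyruvate"] <- 1:20          # linear ramp voxel
  sig[2, 2, , "pyruvate"] <- 3             # constant voxel
  ser <- structure(list(signal = sig, times = seq(0, 76, by = 4),
                        schedule = acquisition_schedule(matrix_size = c(4L, 4L)),
                        sigma = 0, seed = NULL, truth = NULL),
                   class = "dynamic_series")
  summed <- sum_time(ser)
  expect_equal(summed$pyruvate[1, 1], 210)      # 1 + 2 + ... + 20
  expect_equal(summed$pyruvate[2, 2], 60)
  expect_equal(summed$lactate, matrix(0, 4, 4), ignore_attr = TRUE)

  # one-frame series: summation is the identity
  one <- ser
  one$signal <- sig[, , 1, , drop = FALSE]
  expect_equal(sum_time(one)$pyruvate, sig[, , 1, "pyruvate"],
               ignore_attr = TRUE)

  # two equal constant metabolite maps sum to twice either
  sig2 <- array(2, c(4, 4, 3, 2),
                dimnames = list(NULL, NULL, NULL, c("pyruvate", "lactate")))
  ser2 <- ser
  ser2$signal <- sig2
  summed2 <- sum_time(ser2)
  total <- apply(ser2$signal, c(1, 2), sum)
  expect_equal(total, summed2$pyruvate + summed2$lactate)
  expect_equal(total, 2 * summed2$pyruvate)
})

test_that("total carbon SNR is at least the pyruvate SNR on a shared noise basis", {
  ph <- small_lesion_phantom(kpl = 0.012, amplitude = 30)
  ser <- add_noise(simulate_dynamic_series(ph), 1, seed = 11)
  roi <- ph$lesions[[1]]$mask
  nroi <- default_noise_roi(c(32L, 32L))
  tot <- total_carbon_map(ser, roi, nroi)
  # recompute pyruvate-only SNR against the same final-frame noise estimate
  summed <- sum_time(ser)
  pyr_same_noise <- (mean(summed$pyruvate[roi]) - tot$snr$noise_mean) /
    (sqrt(2) * tot$snr$noise_sd)
  expect_gte(tot$snr$roi_mean_snr, pyr_same_noise)

  # noiseless series with residual final-frame signal inside the noise ROI
  # is flagged as a diagnostic
  ph2 <- phantom(c(32L, 32L),
                 lesions = list(phantom_lesion(
                   rect_mask(c(32L, 32L), 1:4, 1:4), 0.01)))
  ser2 <- simulate_dynamic_series(ph2)
  expect_warning(try(total_carbon_map(ser2, roi, nroi), silent = TRUE),
                 "not signal-free")
})

test_that("ADC fit recovers an exact mono-exponential and handles edge cases", {
  b <- c(150, 550, 750, 1000, 1400)
  s <- 100 * exp(-0.0008 * b)
  fit <- fit_adc(s, b)
  expect_equal(fit$adc, 800, tolerance = 1e-9)
  expect_equal(unname(fit$s0), 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_equal(fit_adc(rep(50, 5), b)$adc, 0)
  expect_error(fit_adc(c(1, -1, 1, 1, 1), b), "non-positive")
  expect_error(fit_adc(c(1, 2), c(100, 100)), "distinct")
})

test_that("ADC recovery under Rician noise: median within 5% of truth", {
  b <- c(150, 550, 750, 1000, 1400)
  s0 <- 100
  truth <- 800
  s_clean <- s0 * exp(-truth * 1e-6 * b)
  sigma <- 0.02 * s0
  set.seed(33)
  est <- replicate(500, {
    sn <- sqrt((s_clean + rnorm(5, 0, sigma))^2 + rnorm(5, 0, sigma)^2)
    fit_adc(sn, b)$adc
  })
  expect_lt(abs(stats::median(est) - truth) / truth, 0.05)
})
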