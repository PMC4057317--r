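# Voxelwise fitters: noiseless round trips, degenerate series handling,
# direction averaging, MTR linearity and the noise-level exclusion mask.

test_that("mono-exponential T2 fit recovers noiseless truth", {
  te <- seq(1, 82, length.out = 7)
  with_seed_test(11, {
    T2 <- runif(500, 20, 120)
    S0 <- runif(500, 200, 2000)
  })
  Y <- S0 * exp(-outer(1 / T2, te))
  fit <- fit_t2_monoexp(Y, te)
  expect_true(all(fit$ok))
  expect_lt(max(abs(fit$T2 - T2) / T2), 1e-6)
  expect_lt(max(abs(fit$S0 - S0) / S0), 1e-6)

  # viable-tissue rate 21.7 1/s corresponds to T2 ~ 46.1 ms and round-trips
  t2v <- 1000 / 21.7
  f1 <- fit_t2_monoexp(800 * exp(-te / t2v), te)
  expect_equal(f1$T2, t2v, tolerance = 1e-8)

  # constant series: no decay, flagged with an infinite-T2 sentinel
  fc <- fit_t2_monoexp(rep(500, 7), te)
  expect_false(fc$ok)
  expect_identical(fc$T2, Inf)

  # non-finite series flagged, not an error
  fn <- fit_t2_monoexp(c(NA, 1:6), te)
  expect_false(fn$ok)
})

test_that("ADC fit averages the three directions and is orientation stable", {
  b <- c(0, 100, 200, 400)
  dir_adc <- c(1e-3, 2e-3, 3e-3)
  Y <- array(NA_real_, c(1, 4, 3))
  for (d in 1:3) Y[1, , d] <- 1000 * exp(-b * dir_adc[d])
  fit <- fit_adc(Y, b)
  expect_equal(fit$ADC, 2e-3, tolerance = 1e-10)
  expect_equal(as.vector(fit$ADC_dir), dir_adc, tolerance = 1e-8)

  # permuting direction labels leaves the averaged ADC unchanged
  fit_perm <- fit_adc(Y[, , c(3, 1, 2), drop = FALSE], b)
  expect_equal(fit_perm$ADC, fit$ADC, tolerance = 1e-12)

  # isotropic truth at the viable-tissue value round-trips
  Yi <- array(rep(1000 * exp(-b * 0.84e-3), 3), c(1, 4, 3))
  expect_equal(fit_adc(Yi, b)$ADC, 0.84e-3, tolerance = 1e-8)

  # flat signal: zero ADC; increasing signal: negative ADC but flagged
  Yf <- array(500, c(1, 4, 3))
  expect_equal(fit_adc(Yf, b)$ADC, 0, tolerance = 1e-10)
  Yn <- array(rep(1000 * exp(b * 5e-4), 3), c(1, 4, 3))
  fneg <- fit_adc(Yn, b)
  expect_lt(fneg$ADC, 0)
  expect_true(fneg$flagged)
})

test_that("Look-Locker T1 fit recovers truth and flags degenerate voxels", {
  protocol <- acquisition_protocol()
  tt <- protocol$ir_times_ms
  tau_of <- function(T1) 1 / (1 / T1 - log(cos(20 * pi / 180)) / 400)
  forward <- function(T1, s0 = 1000) {
    tau <- tau_of(T1)
    A <- s0 * tau / T1
    abs(A - (A + s0) * exp(-tt / tau))
  }
  T1s <- c(300, 600, 1000, 1000 / 0.45, 3000, 3500)
  Y <- t(vapply(T1s, forward, numeric(length(tt))))
  fit <- fit_t1_look_locker(Y, tt)
  expect_true(all(fit$ok))
  expect_lt(max(abs(fit$T1 - T1s) / T1s), 1e-4)

  # amplitude scale invariance
  fit2 <- fit_t1_look_locker(2 * Y, tt)
  expect_equal(fit2$T1, fit$T1, tolerance = 1e-6)

  # A = B (saturation-recovery shape): T1* correction collapses to zero
  ysat <- abs(600 * (1 - exp(-tt / 500)))
  fsat <- fit_t1_look_locker(ysat, tt)
  expect_false(fsat$ok)
  expect_equal(fsat$T1, 0, tolerance = 1e-4)

  # flat series flagged
  expect_false(fit_t1_look_locker(rep(100, length(tt)), tt)$ok)
})

test_that("MTR is the exact saturation formula and linear in S", {
  expect_identical(compute_mtr(100, 100), 0)
  expect_identical(compute_mtr(0, 100), 100)
  expect_equal(compute_mtr(73.6, 100), 26.4)
  # linearity: derivative -100/S0
  s <- seq(10, 90, by = 10)
  mtr <- compute_mtr(s, 200)
  expect_equal(diff(mtr) / diff(s), rep(-100 / 200, length(s) - 1))
  expect_true(is.na(compute_mtr(5, 0)))
  expect_true(is.na(compute_mtr(5, -1)))
})

test_that("exclusion mask flags noise-level voxels against the background", {
  dims <- c(20, 20, 3)
  tumor <- array(FALSE, dims)
  tumor[6:15, 6:15, ] <- TRUE
  with_seed_test(4, {
    t2w <- array(abs(rnorm(prod(dims), 0, 1)), dims)  # background noise
    t2w[tumor] <- 500 + rnorm(sum(tumor), 0, 1)
  })
  excl <- build_exclusion_mask(t2w, tumor, k = 3)
  expect_identical(sum(excl), 0L)                     # all far above noise
  # a void region at noise level is excluded
  t2w[8:9, 8:9, 1] <- c(0.5, 1.2, 0.2, 0.9)
  excl2 <- build_exclusion_mask(t2w, tumor, k = 3)
  expect_identical(sum(excl2), 4L)
  expect_true(all(excl2[8:9, 8:9, 1]))
  # k -> Inf excludes nothing
  excl3 <- build_exclusion_mask(t2w, tumor, k = Inf)
  expect_identical(sum(excl3), 0L)
  # an empty background sample is an error
  expect_error(build_exclusion_mask(t2w, tumor,
                                    background_mask = array(FALSE, dims)),
               "background")
})

test_that("generator voids are caught by the exclusion mask under noise", {
  design <- cohort_design(1, 0, 0)
  protocol <- small_protocol()
  cohort <- generate_cohort(design, protocol = protocol,
                            lesion = lesion_spec(fractions = 0.4,
                                                 void_fraction = 0.1),
                            seed = 21)
  sc <- cohort$scans[["T01_1h"]]
  expect_gt(sum(sc$void), 5L)
  ser <- add_rician_noise(simulate_signal_series(sc, protocol),
                          protocol$noise_sd, seed = 3)
  excl <- build_exclusion_mask(ser$t2w, sc$tumor_mask,
                               background_mask = cohort$geometry$background)
  expect_gte(mean(excl[sc$void]), 0.95)
})

test_that("noiseless forward-fit round trip recovers all maps", {
  design <- cohort_design(1, 0, 0)
  protocol <- small_protocol(noise_sd = 0)
  cohort <- generate_cohort(design, protocol = protocol,
                            lesion = lesion_spec(fractions = 0.3,
                                                 void_fraction = 0),
                            seed = 31)
  sc <- cohort$scans[["T01_1h"]]
  ser <- simulate_signal_series(sc, protocol)
  maps <- fit_parameter_maps(ser, protocol, sc$tumor_mask,
                             background_mask = cohort$geometry$background)
  vox <- which(maps$included_mask)
  for (p in c("T1", "T2", "ADC")) {
    rel <- abs(maps[[p]][vox] - sc$maps[[p]][vox]) / sc$maps[[p]][vox]
    expect_gte(mean(rel < 1e-4), 0.999)
  }
  expect_equal(maps$MTR[vox], sc$maps$MTR[vox], tolerance = 1e-9)
})
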