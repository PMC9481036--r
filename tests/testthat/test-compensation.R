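test_that("pre-emphasis duration matches the log formula and a root-find", {
  coil <- ref_coil()
  # ratio 1/3 (overdrive 3): tau0 = T ln(3/2) ~ 6.43 us
  tau0 <- pre_emphasis_duration(120.3e-3, 40.1e-3, coil)
  expect_equal(tau0, coil$T * log(3 / 2), tolerance = 1e-12)
  expect_equal(tau0, 6.43e-6, tolerance = 1e-3)

  # independent check: time at which the envelope under V0 crosses V1
  root <- stats::uniroot(function(t)
    envelope_response(pulse_train(120.3e-3, 1e-3), coil, t) - 40.1e-3,
    c(1e-9, 5e-5), tol = 1e-16)$root
  expect_equal(tau0, root, tolerance = 1e-9)

  # V1/V0 -> 0 makes tau0 -> 0; V0 = V1 is impossible
  expect_lt(pre_emphasis_duration(1, 1e-6, coil), 2e-6 * coil$T)
  expect_error(pre_emphasis_duration(40.1e-3, 40.1e-3, coil), "exceed")
})

test_that("damping duration matches the finite-tau1 formula and a root-find", {
  coil <- ref_coil()
  # V1/V2 = 1/3, tau1 = 40 us: tau2 = T ln(1 + (1/3)(1 - e^{-tau1/T})) ~ 4.24 us
  tau2 <- damping_duration(40.1e-3, 120.3e-3, 40e-6, coil)
  expect_equal(tau2,
               coil$T * log(1 + (1 / 3) * (1 - exp(-40e-6 / coil$T))),
               tolerance = 1e-12)
  expect_equal(tau2, 4.24e-6, tolerance = 1e-3)

  # independent check: drive at V1 for tau1 (rising from rest), then -V2;
  # the envelope must cross zero exactly tau2 into the damping lobe
  root <- stats::uniroot(function(t)
    envelope_response(pulse_train(c(40.1e-3, -120.3e-3), c(40e-6, 2e-5)),
                      coil, 40e-6 + t),
    c(1e-9, 1.9e-5), tol = 1e-16)$root
  expect_equal(tau2, root, tolerance = 1e-9)

  # equilibrium limit: tau1 = Inf gives T ln(1 + V1/V2); equal amplitudes, T ln 2
  expect_equal(damping_duration(1, 1, Inf, coil), coil$T * log(2),
               tolerance = 1e-12)
  # nothing stored, nothing to damp
  expect_equal(damping_duration(1, 1, 0, coil), 0)
  expect_error(damping_duration(-1, 1, 1e-5, coil), "positive")
})

test_that("finite-tau1 damping approaches the equilibrium form as tau1 >> T", {
  coil <- ref_coil()
  lim <- damping_duration(40.1e-3, 120.3e-3, Inf, coil)
  at20 <- damping_duration(40.1e-3, 120.3e-3, 20 * coil$T, coil)
  expect_lt(abs(at20 - lim) / lim, 1e-6)
})

test_that("durations are monotone in the voltage ratios", {
  coil <- ref_coil(36.3)
  v1 <- 1
  v0s <- seq(1.5, 10, length.out = 20)
  tau0s <- vapply(v0s, pre_emphasis_duration, 0, v1 = v1, coil = coil)
  expect_true(all(diff(tau0s) < 0))          # more overdrive, shorter tau0
  ratios <- seq(0.2, 5, length.out = 20)     # V1/V2
  tau2s <- vapply(ratios, function(r)
    damping_duration(r, 1, 40e-6, coil), 0)
  expect_true(all(diff(tau2s) > 0))          # more stored signal, longer tau2
  tau1s <- seq(1e-6, 1e-4, length.out = 20)
  tau2b <- vapply(tau1s, function(t1)
    damping_duration(1, 1, t1, coil), 0)
  expect_true(all(diff(tau2b) > 0))          # longer pulse, longer tau2
})

test_that("compensated square pulse hits V1, holds it, and ends at zero", {
  coil <- ref_coil()
  comp <- compensate_square(v1 = 40.1e-3, tau1 = 40e-6, overdrive = 3,
                            coil = coil)
  expect_equal(comp$v0, 120.3e-3, tolerance = 1e-12)
  expect_equal(comp$v2, 120.3e-3, tolerance = 1e-12)

  env_at <- function(t) envelope_response(comp$train, coil, t)
  expect_equal(env_at(comp$tau0), comp$v1, tolerance = 1e-12)
  hold <- env_at(comp$tau0 + seq(0, comp$tau1, length.out = 50))
  expect_equal(hold, rep(comp$v1, 50), tolerance = 1e-12)
  expect_lt(abs(env_at(comp$tau0 + comp$tau1 + comp$tau2)), 1e-9)

  # property: end-of-train envelope is ~0 for random valid inputs
  set.seed(5)
  for (rep in 1:10) {
    q <- stats::runif(1, 15, 120)
    cl <- ref_coil(q)
    cs <- compensate_square(v1 = stats::runif(1, 0.01, 1),
                            tau1 = stats::runif(1, 5e-6, 1e-4),
                            overdrive = stats::runif(1, 1.5, 6), coil = cl)
    expect_lt(abs(envelope_response(cs$train, cl, train_duration(cs$train))),
              1e-9)
  }
  expect_error(compensate_square(1, 4e-5, overdrive = 1, coil = coil),
               "exceed")
})

test_that("sinc sampling obeys N_S = 4 i N0 + 1 and lands on peaks and zeros", {
  t13 <- sample_sinc(n_zeros = 3, density = 1, bandwidth = 30e3)
  expect_equal(t13$n_samples, 13L)
  expect_length(t13$amplitudes, 12L)          # leading zero sample dropped
  expect_equal(t13$dt, (1 / 30e3) / 2)

  t37 <- sample_sinc(3, 3, 90e3)
  expect_equal(t37$n_samples, 37L)

  # all sinc nulls (multiples of t0 from the center) sample to exactly zero,
  # and the center samples to the peak amplitude
  t0 <- 1 / 30e3
  center <- 3 * t0
  at_null <- abs(((t13$times - center) / t0) - round((t13$times - center) / t0)) < 1e-12
  is_center <- abs(t13$times - center) < 1e-12
  expect_true(all(abs(t13$amplitudes[at_null & !is_center]) < 1e-12))
  expect_equal(t13$amplitudes[is_center], 1)

  # N0 = 1, i = 1: five samples, zeros at the nulls, unity at the center,
  # 2/pi at the half-way points
  t5 <- sample_sinc(1, 1, 50e3)
  expect_equal(t5$n_samples, 5L)
  expect_equal(t5$amplitudes, c(2 / pi, 1, 2 / pi, 0), tolerance = 1e-12)

  expect_error(sample_sinc(0, 1, 30e3), "positive integer")
  expect_error(sample_sinc(3, 1, -1), "positive")
})

test_that("compensation train interpolates any target exactly", {
  coil <- ref_coil()
  # constant target: V1 = A/(1-E), then V_n = A
  A <- 0.7
  tgt <- sampled_target(2e-6, rep(A, 6))
  tr <- compensation_train(tgt, coil)
  E <- exp(-2e-6 / coil$T)
  expect_equal(tr$amplitude[1], A / (1 - E), tolerance = 1e-12)
  expect_equal(tr$amplitude[-1], rep(A, 5), tolerance = 1e-12)

  # zero target needs zero drive
  z <- compensation_train(sampled_target(1e-6, rep(0, 8)), coil)
  expect_equal(max(abs(z$amplitude)), 0)

  # exactness at the sample times, random targets and a spread of Q, dt
  set.seed(17)
  for (rep in 1:8) {
    cl <- ref_coil(stats::runif(1, 10, 150))
    tg <- random_target(sample(3:60, 1), dt = stats::runif(1, 2e-7, 5e-6))
    trn <- compensation_train(tg, cl)
    expect_lt(max(abs(envelope_response(trn, cl, tg$times) - tg$amplitudes)),
              1e-9)
  }

  # sinc targets at N_S in {13, 25, 37} x BW in {30, 90, 150} kHz
  for (i in 1:3) for (bw in c(30e3, 90e3, 150e3)) {
    tg <- sample_sinc(3, i, bw)
    trn <- compensation_train(tg, coil)
    expect_lt(max(abs(envelope_response(trn, coil, tg$times) - tg$amplitudes)),
              1e-9)
  }
})

test_that("incremental recursion and explicit closed form agree", {
  set.seed(23)
  for (rep in 1:6) {
    cl <- ref_coil(stats::runif(1, 10, 120))
    tg <- random_target(200, dt = stats::runif(1, 5e-7, 4e-6))
    v_rec <- compensation_train(tg, cl, method = "recursive")$amplitude
    v_cf <- compensation_train(tg, cl, method = "closed-form")$amplitude
    expect_lt(max(abs(v_rec - v_cf) / pmax(abs(v_cf), 1e-12)), 1e-12)
  }
})

test_that("finer sampling of the same sinc needs larger drive excursions", {
  # the step gain 1 - exp(-dt/T) shrinks with dt, so the densest sampling
  # (N_S = 37) demands at least the drive of the coarsest (N_S = 13); the
  # intermediate step is not asserted because the maximizing lobe can shift
  coil <- ref_coil()
  for (bw in c(30e3, 90e3, 150e3)) {
    peak_v <- vapply(1:3, function(i)
      max(abs(compensation_train(sample_sinc(3, i, bw), coil)$amplitude)), 0)
    expect_gt(peak_v[3], peak_v[1])
    expect_gt(peak_v[2], peak_v[1])
  }
})

test_that("exceeding the amplifier ceiling warns but still returns the train", {
  coil <- ref_coil()
  tgt <- sample_sinc(3, 3, 150e3)
  expect_warning(tr <- compensation_train(tgt, coil, max_amplitude = 1),
                 "ceiling")
  expect_s3_class(tr, "pulse_train")
  expect_silent(compensation_train(tgt, coil, max_amplitude = 100))
})
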