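test_that("peak tracking is exact on a noiseless pattern and unbiased on jitter", {
  g <- rdGeometry(6, 60)
  # noiseless cosine: constant x_p at L/2, sigma = 0
  kf0 <- jitterKymograph(g, jitter_sd = 0, n_samples = 200, seed = 1)
  tr0 <- trackPeak(kf0, species = 2, target_stripes = 3, smooth = 1)
  expect_equal(stats::sd(tr0$x_p[tr0$valid]), 0, tolerance = 1e-12)
  expect_equal(mean(tr0$x_p[tr0$valid]), 3, tolerance = 1e-6)
  expect_equal(tr0$sigma, 0, tolerance = 1e-12)

  # injected Gaussian peak jitter of sd s: recovered sigma within 5%
  s <- 0.05
  kf <- jitterKymograph(g, jitter_sd = s, n_samples = 2000, seed = 3)
  tr <- trackPeak(kf, species = 2, target_stripes = 3, smooth = 1,
                  burnin_frac = 0)
  expect_equal(tr$sigma, s, tolerance = 0.05)

  # translation invariance of the sigma estimator
  expect_equal(stats::sd(tr$x_p[tr$valid] + 1.23),
               stats::sd(tr$x_p[tr$valid]))
})

test_that("tracking flags wrong stripe counts and lost patterns", {
  g <- rdGeometry(6, 60)
  kf <- jitterKymograph(g, jitter_sd = 0.02, n_samples = 300, seed = 5)
  # corrupt a block of samples into a 2-stripe pattern
  bad <- 101:140
  for (ti in bad)
    kf$fields[2, , ti] <- 300 - 100 * cos(2 * pi * 2 / 6 * g$x)
  tr <- trackPeak(kf, species = 2, target_stripes = 3, smooth = 1,
                  burnin_frac = 0)
  expect_true(all(!tr$valid[bad]))
  expect_gt(sum(tr$valid), 100)
  # all samples wrong => pattern lost
  kf2 <- kf
  for (ti in seq_along(kf2$times))
    kf2$fields[2, , ti] <- 300 - 100 * cos(2 * pi * 2 / 6 * g$x)
  expect_error(trackPeak(kf2, species = 2, target_stripes = 3, smooth = 1),
               "pattern lost")
})

test_that("variance reduction factor S(eps) behaves as the phase theory requires", {
  a <- 3
  expect_equal(SofEps(0, a), 1)
  eps <- seq(0, 1, 0.05)
  S <- SofEps(eps, a)
  expect_true(all(diff(S) > 0))
  # continuity of the small-eps limit
  expect_equal(SofEps(1e-12, a), 1, tolerance = 1e-8)
})

test_that("the positional-variance integral matches its closed forms", {
  L <- 6; lambda <- 2; D4 <- 0.01; d2 <- 0.05; Delta0 <- 2e-4
  a <- (L / pi) * sqrt(d2 / D4)
  s0sq <- (lambda / (2 * pi))^2 * Delta0 * L / D4
  # D2 = 0 closed form
  expect_equal(sigmaSquaredIntegral(0, D4, Delta0, L, lambda), s0sq,
               tolerance = 1e-8)
  # sigma0^2 / S(eps) across the eps range, quadrature vs closed form
  for (eps in c(0.01, 0.1, 0.5, 1)) {
    v_quad <- sigmaSquaredIntegral(d2 * eps, D4, Delta0, L, lambda)
    expect_equal(v_quad, s0sq / SofEps(eps, a), tolerance = 1e-6)
  }
  # linear in the noise strength
  expect_equal(sigmaSquaredIntegral(d2, D4, 5 * Delta0, L, lambda),
               5 * sigmaSquaredIntegral(d2, D4, Delta0, L, lambda),
               tolerance = 1e-10)
  # phase-unstable regime refused
  expect_error(sigmaSquaredIntegral(-10 * D4, D4, Delta0, L, lambda),
               "phase-unstable")
})

test_that("simulated phase-field variance matches the spectral prediction", {
  # integrate the linear phase equation with conserved noise on a ring and
  # compare the pattern-position variance with the (q, omega) integral
  set.seed(99)
  L <- 6; lambda <- 2
  nx <- 64; dx <- L / nx
  D2 <- 5e-4; D4 <- 1e-3; Delta0 <- 4e-4
  dt <- 0.2 * dx^4 / (8 * D4)
  nstep <- 60000
  q <- 2 * pi * c(0:(nx / 2), -(nx / 2 - 1):-1) / L
  decay <- D2 * q^2 + D4 * q^4
  phi <- rep(0, nx)
  every <- 50
  keep <- numeric(nstep %/% every)
  for (it in seq_len(nstep)) {
    eta <- stats::rnorm(nx, 0, sqrt(Delta0 / (dx * dt)))
    detadx <- (eta[c(2:nx, 1)] - eta[c(nx, 1:(nx - 1))]) / (2 * dx)
    ph <- stats::fft(phi)
    ph <- ph * exp(-decay * dt)
    phi <- Re(stats::fft(ph, inverse = TRUE)) / nx
    phi <- phi + dt * detadx
    if (it %% every == 0) keep[it %/% every] <- phi[1]
  }
  var_sim <- stats::var(keep[-(1:200)]) * (lambda / (2 * pi))^2
  # theory on the ring: modes q_n = 2 pi n / L, variance per mode
  # Delta0 q^2 / (2 decay) / L  (discrete sum, excluding the zero mode)
  qn <- 2 * pi * (1:(nx / 2 - 1)) / L
  dec <- D2 * qn^2 + D4 * qn^4
  # centred-difference noise derivative attenuates q: sin(q dx)/dx
  qeff <- sin(qn * dx) / dx
  var_th <- (lambda / (2 * pi))^2 * sum(2 * Delta0 * qeff^2 / (2 * dec)) / L
  expect_equal(var_sim, var_th, tolerance = 0.1)
})

test_that("error-energy fits recover parameters and respect scaling", {
  dW <- c(0.2, 0.5, 1, 1.8, 3, 5)
  sig <- 0.04 / (1 - 0.5 * exp(-dW))
  ft <- fitErrorEnergy(sig, dW)
  expect_equal(ft$c1, 0.5, tolerance = 1e-6)
  expect_equal(ft$sigma_min, 0.04, tolerance = 1e-6)
  # rescaling sigma only rescales sigma_min
  ft2 <- fitErrorEnergy(3.7 * sig, dW)
  expect_equal(ft2$c1, 0.5, tolerance = 1e-6)
  expect_equal(ft2$sigma_min, 3.7 * 0.04, tolerance = 1e-6)
  # residuals carry no trend for a correctly specified model (with noise)
  set.seed(7)
  noisy <- sig * exp(stats::rnorm(length(sig), 0, 0.03))
  ft3 <- fitErrorEnergy(noisy, dW)
  expect_lt(abs(stats::cor(ft3$residuals, dW)), 0.9)
  expect_error(fitErrorEnergy(sig[1:3], dW[1:3]))
})
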