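test_that("cycle irreversibility parameters follow the rate-ratio formulas", {
  # equilibrium: all linear rates equal and kt12 = kt21 => Gamma = Gamma' = 1
  r <- rateConstants(k12 = 1, k21 = 1, k23 = 1, k32 = 1, k31 = 1, k13 = 1,
                     kt12 = 1e-4, kt21 = 1e-4)
  th <- computeThermo(r)
  expect_equal(th$Gamma, 1)
  expect_equal(th$GammaPrime, 1)
  expect_equal(th$W, 0)

  # fig3 rate block: Gamma' by direct hand arithmetic of the cycle products
  pr <- fig3()
  th3 <- computeThermo(pr$rates)
  gp_hand <- (0.0139 * 1.39e-5 * 3.6) / (0.5 * 0.0139 * 0.0416)
  expect_equal(th3$GammaPrime, gp_hand, tolerance = 1e-12)
  expect_equal(th3$Wprime, -log(gp_hand))

  # fig4 declares Gamma = 0.011 with kt21, k12, k21 printed; the implied
  # kt12 must round-trip to Gamma = 0.011 exactly
  pr4 <- fig4()
  expect_equal(computeThermo(pr4$rates)$Gamma, 0.011, tolerance = 1e-12)
  expect_equal(pr4$rates$kt12, 1.67e-5 * 0.5 / (0.011 * 3.6),
               tolerance = 1e-12)
})

test_that("thermo state is scale invariant and monotone in kt21", {
  pr <- fig3()
  r <- pr$rates
  scaled <- rateConstants(k12 = 3 * r$k12, k21 = 3 * r$k21, k23 = 3 * r$k23,
                          k32 = 3 * r$k32, k31 = 3 * r$k31, k13 = 3 * r$k13,
                          kt12 = 3 * r$kt12, kt21 = 3 * r$kt21)
  expect_equal(computeThermo(scaled)$Gamma, computeThermo(r)$Gamma)
  expect_equal(computeThermo(scaled)$GammaPrime, computeThermo(r)$GammaPrime)

  W <- vapply(c(1e-7, 1e-6, 1e-5), function(kt21) {
    rr <- r; rr$kt21 <- kt21
    computeThermo(rr)$W
  }, numeric(1))
  expect_true(all(diff(W) < 0))
})

test_that("irreversible limit is refused by thermodynamics but not dynamics", {
  expect_error(rateConstants(k12 = 1, k21 = 1, k23 = 1, k32 = 1, k31 = 1,
                             k13 = 1, kt12 = 1e-4, kt21 = 0),
               "irreversible")
  r0 <- rateConstants(k12 = 1, k21 = 1, k23 = 1, k32 = 1, k31 = 1, k13 = 1,
                      kt12 = 1e-4, kt21 = 0, irreversible = TRUE)
  expect_error(computeThermo(r0), "irreversible limit")
  # dynamics still run: the fixed point exists
  expect_s3_class(homogeneousFixedPoint(r0, 100), "homogeneousFixedPoint")
})

test_that("homogeneous fixed point balances the well-mixed kinetics", {
  # equilibrium rates: pairwise detailed balance at the fixed point
  req <- equilibrium_rates()
  fp <- homogeneousFixedPoint(req, 900)
  u <- c(fp$u1s, fp$u2s, fp$u3s)
  expect_equal(fp$u1s + fp$u2s + fp$u3s, 900, tolerance = 1e-9)
  expect_equal(req$k12 * u[1] + req$kt12 * u[1] * u[2]^2,
               req$k21 * u[2] + req$kt21 * u[2]^3, tolerance = 1e-6)
  expect_equal(req$k23 * u[2], req$k32 * u[3], tolerance = 1e-6)
  expect_equal(req$k31 * u[3], req$k13 * u[1], tolerance = 1e-6)

  # generic sets: agreement with long-time integration of the well-mixed
  # ODEs (one-box PDE) from the equal-partition state
  for (pr in list(fig3(), fig4())) {
    fp <- homogeneousFixedPoint(pr$rates, pr$c_tot)
    net <- threeSpeciesNetwork(pr$rates, pr$diffusion)
    us <- turingcost:::.wellMixedSteady(net, pr$c_tot)
    expect_equal(c(fp$u1s, fp$u2s, fp$u3s), us, tolerance = 1e-5)
  }

  # fig4: v2* strictly increasing in N
  v2 <- vapply(c(1000, 2000, 4000, 8000, 16000), function(N)
    homogeneousFixedPoint(fig4()$rates, N / 6)$v2s, numeric(1))
  expect_true(all(diff(v2) > 0))
})

test_that("fixed point scales linearly with c_tot in the linear network limit", {
  r <- rateConstants(k12 = 0.5, k21 = 3.6, k23 = 0.0139, k32 = 1.39e-5,
                     k31 = 0.0416, k13 = 0.0139, kt12 = 1e-12, kt21 = 1e-12)
  fp1 <- homogeneousFixedPoint(r, 100)
  fp2 <- homogeneousFixedPoint(r, 500)
  expect_equal(5 * c(fp1$u1s, fp1$u2s, fp1$u3s),
               c(fp2$u1s, fp2$u2s, fp2$u3s), tolerance = 1e-6)
})

test_that("effective autocatalytic rates scale as c_tot^2", {
  pr <- fig3()
  expect_equal(effectiveRates(pr$rates, 0), list(beta12 = 0, beta21 = 0))
  b1 <- effectiveRates(pr$rates, 600)
  b2 <- effectiveRates(pr$rates, 1200)
  expect_equal(b2$beta12, 4 * b1$beta12)
  expect_equal(b2$beta21, 4 * b1$beta21)
  # hand arithmetic: kt12 = 1.67e-5, N = 7200, L = 6 => beta12 = 1.67e-5*1200^2
  expect_equal(effectiveRates(pr$rates, 7200 / 6)$beta12, 1.67e-5 * 1200^2)
})

test_that("preset blocks expand to the published values", {
  pr <- fig3()
  expect_equal(pr$rates$k21, 3.6)
  expect_equal(pr$rates$kt12, 1.67e-5)
  expect_equal(pr$rates$k31, 0.0416)
  expect_equal(pr$diffusion$D1, 0.3)
  expect_equal(pr$diffusion$D3, 0.3)
  expect_equal(pr$diffusion$D2, 0.012)
  expect_equal(pr$geometry$L, 6)
  expect_equal(pr$geometry$n_box, 60)
  expect_equal(pr$N, 7200)
  pr4 <- fig4()
  expect_equal(pr4$diffusion$D1, 1.8)
  expect_equal(pr4$rates$kt21, 1.67e-5)
  expect_equal(pr4$rates$k32, 0.0139)
})

test_that("geometry enforces exact box arithmetic", {
  g <- rdGeometry(6, 60)
  expect_equal(g$dx * g$n_box, g$L)
  expect_equal(length(g$x), 60)
  expect_error(rdGeometry(6, 2))
})
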