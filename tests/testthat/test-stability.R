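test_that("dispersion relation has the conservation zero mode and a Turing band", {
  pr <- fig3()
  disp <- dispersionRelation(pr$rates, pr$diffusion, pr$c_tot)
  # q = 0: one eigenvalue exactly zero along the conserved direction
  expect_lt(abs(turingcost:::.rhoOfQ(disp$J, disp$D, 0)), 1e-10)
  # fig3 preset (d = 25): the finite-system three-stripe mode q = pi lies
  # inside the unstable band
  expect_gt(turingcost:::.rhoOfQ(disp$J, disp$D, pi), 0)
  expect_gt(disp$q0, 0)
  expect_lt(disp$curvature, 0)
})

test_that("dispersion growth rates match direct PDE mode growth", {
  pr <- fig3()
  net <- fig3_network()
  disp <- dispersionRelation(pr$rates, pr$diffusion, pr$c_tot)
  fp <- disp$fixed_point
  g <- pr$geometry
  for (n_mode in c(2, 3, 4)) {
    q <- 2 * pi * n_mode / g$L
    rho_lin <- turingcost:::.rhoOfQ(disp$J, disp$D, q)
    # seed the single cosine mode at 0.1% and measure its exponential rate
    u0 <- matrix(c(fp$u1s, fp$u2s, fp$u3s), 3, g$n_box)
    amp0 <- 1e-3 * fp$u2s
    seed <- cos(q * g$x)
    u0[2, ] <- u0[2, ] + amp0 * seed
    u0[1, ] <- u0[1, ] - amp0 * seed
    # skip the first second (eigenvector mixing transient), then measure
    kym <- integratePDE(net, g, u0, t_end = 3, sample_dt = 1)
    proj <- function(u) 2 * mean((u[2, ] - mean(u[2, ])) * seed)
    a2 <- proj(fieldAt(kym, 3)); a3 <- proj(fieldAt(kym, 4))
    rho_pde <- log(a3 / a2)
    expect_equal(rho_pde, rho_lin, tolerance = 0.02)
  }
})

test_that("infinite-system onset kt0 brackets growth and is grid stable", {
  pr <- fig3()
  kt0 <- as.numeric(onsetKt0(pr$rates, pr$diffusion, pr$c_tot))
  below <- turingcost:::.rhoMaxAt(pr$rates, pr$diffusion, pr$c_tot,
                                  0.98 * kt0)$rho
  above <- turingcost:::.rhoMaxAt(pr$rates, pr$diffusion, pr$c_tot,
                                  1.02 * kt0)$rho
  expect_gt(below, 0)
  expect_lt(above, 0)
  # preset kt21 (W = 3.21) is inside the pattern regime
  expect_lt(pr$rates$kt21, kt0)
})

test_that("finite-system onset is stricter than the infinite one", {
  cs <- fig3_onset()
  expect_lte(cs$ktc, cs$kt0)
  expect_lte(cs$Gammac, cs$Gamma0)
  expect_gte(cs$Wc, cs$W0)
  expect_true(cs$zeta <= 1)
  # dq = 0 recovers ktc = kt0 exactly
  pr <- fig3()
  g_match <- rdGeometry(L = 3 * 2 * pi / cs$q0, n_box = 60)
  cs0 <- onsetKtcFinite(pr$rates, pr$diffusion, pr$c_tot, g_match, 3)
  expect_equal(cs0$ktc, cs0$kt0, tolerance = 1e-6)

  # W_c > W_0 for every k12 in the (restricted) sweep, both increasing as
  # k12 decreases
  scans <- lapply(c(0.4, 0.45, 0.5), function(k12) {
    p <- presetConfig("fig3", k12 = k12)
    onsetKtcFinite(p$rates, p$diffusion, p$c_tot, p$geometry, 3)
  })
  W0 <- vapply(scans, `[[`, numeric(1), "W0")
  Wc <- vapply(scans, `[[`, numeric(1), "Wc")
  expect_true(all(Wc > W0))
  expect_true(all(diff(W0) < 0))   # k12 increasing => onset energy decreasing
  expect_true(all(diff(Wc) < 0))
})

test_that("d_min marks the Turing boundary at infinite driving", {
  pr <- presetConfig("fig3", k12 = 0.4)
  dm <- findDmin(pr$rates, D2 = pr$diffusion$D2, c_tot = pr$c_tot)
  # definition check: just below d_min no unstable band for kt21 = 0
  r0 <- pr$rates; r0$kt21 <- 0
  disp_lo <- dispersionRelation(r0, diffusionConstants((dm - 0.05) * 0.012,
                                                       0.012), pr$c_tot)
  disp_hi <- dispersionRelation(r0, diffusionConstants((dm + 0.05) * 0.012,
                                                       0.012), pr$c_tot)
  expect_lt(disp_lo$rho_max, 1e-10)
  expect_gt(disp_hi$rho_max, 0)

  # invariance under a common time rescaling of all rates and diffusivities
  r2 <- rateConstants(k12 = 10 * r0$k12, k21 = 10 * r0$k21,
                      k23 = 10 * r0$k23, k32 = 10 * r0$k32,
                      k31 = 10 * r0$k31, k13 = 10 * r0$k13,
                      kt12 = 10 * r0$kt12, kt21 = 0, irreversible = TRUE)
  dm2 <- findDmin(r2, D2 = 10 * pr$diffusion$D2, c_tot = pr$c_tot)
  expect_equal(dm2, dm, tolerance = 5e-3)
})

test_that("closed-form beta0/Gamma0 reproduces the onset structure in N", {
  pr <- fig4()
  b <- beta0Gamma0(pr$rates, pr$c_tot)
  expect_gt(b$R1, 1)
  expect_gt(b$R2, 1)

  curve <- gammaCofN(pr$rates, pr$diffusion, pr$geometry,
                     N = exp(seq(log(1200), log(2e5), length.out = 60)))
  gc <- curve$GammaC
  ipk <- which.max(gc)
  expect_gt(ipk, 1)
  expect_lt(ipk, nrow(curve))
  # sharp rise then gradual decay: rise slope above peak-left exceeds the
  # decay slope magnitude right of the peak (log-log)
  lr <- diff(log(pmax(gc, 1e-300))) / diff(log(curve$N))
  expect_gt(max(lr[seq_len(ipk - 1)], na.rm = TRUE),
            abs(min(lr[ipk:(length(lr))])))
  # large-N asymptote: log-log slope -> -2 within 2%
  slope_tail <- (log(gc[60]) - log(gc[55])) / (log(curve$N[60]) - log(curve$N[55]))
  expect_equal(slope_tail, -2, tolerance = 0.02)
})

test_that("the stable-N window widens with driving and keeps N* fixed", {
  pr <- fig4()
  nr <- nRange(pr$rates, pr$diffusion, pr$geometry, Gamma = 0.011)
  expect_true(nr$N_min < nr$N_star && nr$N_star < nr$N_max)
  # Gamma_c equals the operating Gamma at both flanks
  zeta <- nr$zeta
  for (N in c(nr$N_min, nr$N_max)) {
    gc <- zeta * beta0Gamma0(pr$rates, N / 6)$Gamma0
    expect_equal(gc, 0.011, tolerance = 1e-4)
  }
  # more driving (smaller Gamma): N_max grows, N_min shrinks (weakly)
  nr2 <- nRange(pr$rates, pr$diffusion, pr$geometry, Gamma = 0.011 / 3)
  expect_gt(nr2$N_max, nr$N_max)
  expect_lte(nr2$N_min, nr$N_min)
  expect_lt((nr$N_min - nr2$N_min) / nr$N_min,
            (nr2$N_max - nr$N_max) / nr$N_max)
  # N* from the Gamma_c peak does not move with the operating Gamma
  expect_equal(nr2$N_star, nr$N_star, tolerance = 1e-6)

  # ln N_max vs W slope approaches 1/2 in the strong-driving asymptote
  Ws <- c(9, 10, 11)
  lnN <- vapply(Ws, function(W)
    log(nRange(pr$rates, pr$diffusion, pr$geometry, Gamma = exp(-W))$N_max),
    numeric(1))
  slopes <- diff(lnN) / diff(Ws)
  expect_equal(mean(slopes), 0.5, tolerance = 0.02)

  # operating Gamma above the peak: no window
  expect_error(nRange(pr$rates, pr$diffusion, pr$geometry, Gamma = 0.5),
               "no stable-N window")
})
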