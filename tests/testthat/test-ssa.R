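test_that("propensities implement exact CME combinatorics and no-flux ends", {
  pr <- fig3()
  net <- fig3_network()
  g <- small_geometry()
  # a single molecule: interior box hops at 2 D/dx^2, end box at D/dx^2
  counts <- matrix(0L, 3, 6)
  counts[1, 3] <- 1L
  pp <- propensities(counts, net, g)
  hops <- pp[pp$kind == "hop" & pp$channel == "u1" & pp$propensity > 0, ]
  expect_equal(sum(hops$propensity), 2 * 0.3 / g$dx^2)
  counts2 <- matrix(0L, 3, 6); counts2[1, 1] <- 1L
  pp2 <- propensities(counts2, net, g)
  hops2 <- pp2[pp2$kind == "hop" & pp2$channel == "u1" & pp2$propensity > 0, ]
  expect_equal(nrow(hops2), 1)           # inward only
  expect_equal(hops2$propensity, 0.3 / g$dx^2)

  # n2 = 2: backward autocatalysis needs three distinct X2 => propensity 0;
  # forward autocatalysis from one X1 and two X2 is (kt12/dx^2) n1 n2 (n2-1)
  counts3 <- matrix(0L, 3, 6); counts3[1, 2] <- 1L; counts3[2, 2] <- 2L
  pp3 <- propensities(counts3, net, g)
  auto_b <- pp3[pp3$channel == "auto-" & pp3$box == 2, "propensity"]
  auto_f <- pp3[pp3$channel == "auto+" & pp3$box == 2, "propensity"]
  expect_equal(auto_b, 0)
  expect_equal(auto_f, pr$rates$kt12 / g$dx^2 * 1 * 2 * 1)

  # summed forward autocatalytic propensity matches mass action in the
  # large-count limit: L kt12 <u1 u2^2> from a smooth field
  g60 <- pr$geometry
  u <- fig3_steady()
  big <- latticeStateFromField(u, g60, net)
  ppb <- propensities(big, net, g60)
  tot_f <- sum(ppb[ppb$channel == "auto+", "propensity"])
  mass_action <- sum(pr$rates$kt12 * u[1, ] * u[2, ]^2) * g60$dx
  # falling factorials n2(n2-1) sit ~1/n2 below n2^2 at n2 ~ 100/box
  expect_equal(tot_f, mass_action, tolerance = 0.03)
})

test_that("pure diffusion spreads by 2Dt and relaxes to uniform", {
  # one diffusing species, no reactions
  net <- reactionNetwork("u", D = 0.25, reactions = list())
  g <- rdGeometry(10, 50)
  init <- matrix(0L, 1, 50); init[1, 25] <- 2000L
  kym <- runSSA(net, g, init, t_end = 60, sample_dt = 0.5, seed = 101)
  x <- g$x
  # variance of position grows like 2 D t before boundary contact
  v0 <- 0 # delta start at a box centre
  for (ti in c(5, 9)) {   # t = 2, 4 s
    p <- kym$fields[1, , ti] / sum(kym$fields[1, , ti])
    v <- sum(p * x^2) - sum(p * x)^2
    expect_equal(v, 2 * 0.25 * kym$times[ti], tolerance = 0.1)
  }
  # long-time occupancy approaches uniform
  pT <- rowMeans(matrix(kym$fields[1, , 81:121], 50))
  expect_lt(max(abs(pT - mean(pT))) / mean(pT), 0.25)
  expect_true(all(totalMass(kym) == 2000))
})

test_that("one-box SSA means relax to the well-mixed fixed point", {
  pr <- fig3()
  net <- fig3_network()
  g1 <- rdGeometry(3, 3)   # small lattice, still well mixed at D >> k
  N <- 1200
  fp <- homogeneousFixedPoint(pr$rates, N / g1$L)
  target <- c(fp$u1s, fp$u2s, fp$u3s) * g1$L      # expected totals
  reps <- 50
  means <- matrix(0, reps, 3)
  init <- latticeState(net, g1, N)
  for (i in seq_len(reps)) {
    kym <- runSSA(net, g1, init, t_end = 60, sample_dt = 2, seed = 300 + i)
    keep <- 16:31
    means[i, ] <- rowMeans(apply(kym$fields[, , keep], c(1, 3), sum))
  }
  est <- colMeans(means)
  sem <- apply(means, 2, stats::sd) / sqrt(reps)
  for (s in 1:3)
    expect_lt(abs(est[s] - target[s]), 3 * sem[s] + 0.01 * target[s])
})

test_that("trajectories conserve N exactly and reproduce bit-for-bit", {
  pr <- fig3()
  net <- fig3_network()
  g <- small_geometry()
  init <- latticeState(net, g, 600)
  expect_equal(sum(init), 600)
  k1 <- runSSA(net, g, init, t_end = 20, sample_dt = 1, seed = 77)
  expect_true(all(totalMass(k1) == 600))
  k2 <- runSSA(net, g, init, t_end = 20, sample_dt = 1, seed = 77)
  expect_identical(k1$fields, k2$fields)
  k3 <- runSSA(net, g, init, t_end = 20, sample_dt = 1, seed = 78)
  expect_false(identical(k1$fields, k3$fields))

  ens <- runEnsemble(net, g, init, t_end = 5, sample_dt = 1,
                     n_replicates = 3, seed_base = 500)
  ref <- runSSA(net, g, init, t_end = 5, sample_dt = 1, seed = 502)
  expect_identical(ens[[2]]$fields, ref$fields)
})

test_that("ensemble mean field tracks the deterministic solution as N grows", {
  pr <- fig3()
  net <- fig3_network()
  g <- pr$geometry
  u <- fig3_steady()
  # the fluctuating stochastic pattern averages to the deterministic
  # profile; error shrinks with N (tested against a generous 3 SEM band
  # plus the phase-wander floor at N = 7200)
  init <- latticeStateFromField(u, g, net)
  ens <- runEnsemble(net, g, init, t_end = 40, sample_dt = 2,
                     n_replicates = 4, seed_base = 900)
  fields <- vapply(ens, function(k) timeAveragedField(k, 0.25),
                   matrix(0, 3, g$n_box))
  mf <- apply(fields, c(1, 2), mean)
  # per-box agreement within 3 SEM bands (replicate scatter includes the
  # soft-mode phase wander, the dominant fluctuation at this N)
  se2 <- apply(fields[2, , ], 1, stats::sd) / sqrt(length(ens))
  inside <- abs(mf[2, ] - u[2, ]) <= 3 * se2 + 0.02 * mean(u[2, ])
  expect_gt(mean(inside), 0.9)
})
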