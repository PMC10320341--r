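#' Default parameters of the five-species Muk model
#'
#' The published description fixes the network topology, the ATP/ADP scaling
#' rule and the diffusion grouping (DNA-free species fast, DNA-bound slow)
#' but not the individual rate values; this default set is the package's
#' documented choice, constructed to (a) satisfy cycle thermodynamic
#' consistency exactly, (b) support a three-stripe pattern at the reference
#' ATP/ADP ratio in an L = 6 um domain, and (c) reproduce the qualitative
#' accuracy/robustness trends. All entries can be overridden.
#'
#' `kf` are forward rate constants (capture `k1` in s^-1 um^2,
#' re-dimerisation `k6` in s^-1 um, the rest s^-1). `u_eq` is a reference
#' equilibrium composition (um^-1) that *defines* the backward rates
#' through detailed balance at ATP/ADP = 1, guaranteeing that every
#' reaction cycle is reversible and equilibrated there. `hydrolysis` counts
#' ATP hydrolysis events per forward firing; the forward/backward ratio of
#' each driven reaction scales with the ATP/ADP ratio once per event, and
#' the dependence is carried entirely by the backward rate
#' (`kf` fixed, `kb ~ r^-h`): hydrolysis is treated as ATP-saturated
#' (catalysis-limited) while the reverse, ADP-consuming direction scales
#' with the ADP concentration -- the same structure as the three-species
#' study, where only the reverse autocatalytic rate carries the driving.
#'
#' @return list of defaults consumed by [mukNetwork()].
#' @export
mukParams <- function() {
  list(
    kf = c(k1 = 1.67e-5,   # cooperative DNA capture X1 + 2 X2 -> M1 + 2 X2
           k2 = 10,        # re-closing M1 -> X2
           k3 = 3.6,       # hydrolysis/DNA release X2 -> M2
           k4 = 10,        # ATP re-binding M2 -> X1
           k5 = 0.0139,    # double-hydrolysis de-dimerisation X2 -> 2 X3
           k6 = 1e-4,      # re-dimerisation 2 X3 -> X1
           k7 = 0.5),      # basal (non-cooperative) DNA capture X1 -> M1
    hydrolysis = c(k1 = 1L, k2 = 0L, k3 = 1L, k4 = 0L, k5 = 2L, k6 = 0L,
                   k7 = 1L),
    u_eq = c(X1 = 100, M1 = 100, X2 = 100, M2 = 100, X3 = 100),
    D_fast = 0.3, D_slow = 0.012,
    atp_ref = 100,    # reference ATP/ADP ratio (physiological order)
    N_ref = 26000)    # dimer-equivalent copy number at the reference point
}

#' Build the five-species Muk reaction network
#'
#' Species: X1 (closed dimer-of-dimers, DNA-free), M1 (post-hydrolysis
#' intermediate, DNA-bound), X2 (closed DD, DNA-bound), M2 (post-hydrolysis
#' intermediate, DNA-free), X3 (open dimer). The DD loop
#' X1 -> M1 -> X2 -> M2 -> X1 carries one hydrolysis per half-turn
#' (capture and release); DNA capture is cooperative -- a basal channel
#' plus a channel enhanced by nearby DNA-bound DDs (cubic, the same form as
#' the three-species autocatalysis), both hydrolysis-driven; and
#' simultaneous double hydrolysis de-dimerises a bound DD into two open
#' dimers which re-dimerise to X1. DNA-free species diffuse fast, DNA-bound
#' species slowly. The conservation weighting counts dimers: DD species
#' weigh 2, the open dimer 1.
#'
#' Counting distinct species-pair edges (6 edges, 5 species, 1 conserved
#' total) the network has exactly two independent cycles, mirroring the
#' Gamma/Gamma' structure of the three-species model; the parallel
#' basal/cooperative capture channels add a channel-level loop whose
#' affinity is identically zero (both channels are driven by the same
#' single hydrolysis). At `atp_adp = 1` every cycle is equilibrated by
#' construction and total dissipation vanishes.
#'
#' @param atp_adp ATP/ADP concentration ratio (> 0); the driving knob.
#' @param params parameter list as produced by [mukParams()]; `kb` may be
#'   supplied explicitly instead of `u_eq`, in which case cycle consistency
#'   at `atp_adp = 1` is verified and violations are reported per cycle.
#' @return an [reactionNetwork()] with attribute `atp_adp`.
#' @export
mukNetwork <- function(atp_adp, params = mukParams()) {
  stopifnot(atp_adp > 0)
  kf <- params$kf
  h <- params$hydrolysis
  if (is.null(params$kb)) {
    ue <- params$u_eq
    kb <- c(k1 = unname(kf["k1"] * ue["X1"] / ue["M1"]),
            k2 = unname(kf["k2"] * ue["M1"] / ue["X2"]),
            k3 = unname(kf["k3"] * ue["X2"] / ue["M2"]),
            k4 = unname(kf["k4"] * ue["M2"] / ue["X1"]),
            k5 = unname(kf["k5"] * ue["X2"] / ue["X3"]^2),
            k6 = unname(kf["k6"] * ue["X3"]^2 / ue["X1"]),
            k7 = unname(kf["k7"] * ue["X1"] / ue["M1"]))
  } else kb <- params$kb
  kfs <- kf                      # forward: ATP-saturated, ratio-independent
  kbs <- kb / atp_adp^h          # backward: carries the full ADP dependence
  net <- reactionNetwork(
    species = c("X1", "M1", "X2", "M2", "X3"),
    D = c(params$D_fast, params$D_slow, params$D_slow, params$D_fast,
          params$D_fast),
    weights = c(2, 2, 2, 2, 1),
    reactions = list(
      list(name = "capture", reactants = c(X1 = 1L, X2 = 2L),
           products = c(M1 = 1L, X2 = 2L), kf = kfs[["k1"]],
           kb = kbs[["k1"]], hydrolysis = 1L),
      list(name = "reclose", reactants = c(M1 = 1L), products = c(X2 = 1L),
           kf = kfs[["k2"]], kb = kbs[["k2"]], hydrolysis = 0L),
      list(name = "release", reactants = c(X2 = 1L), products = c(M2 = 1L),
           kf = kfs[["k3"]], kb = kbs[["k3"]], hydrolysis = 1L),
      list(name = "rebind", reactants = c(M2 = 1L), products = c(X1 = 1L),
           kf = kfs[["k4"]], kb = kbs[["k4"]], hydrolysis = 0L),
      list(name = "dedimerise", reactants = c(X2 = 1L),
           products = c(X3 = 2L), kf = kfs[["k5"]], kb = kbs[["k5"]],
           hydrolysis = 2L),
      list(name = "redimerise", reactants = c(X3 = 2L),
           products = c(X1 = 1L), kf = kfs[["k6"]], kb = kbs[["k6"]],
           hydrolysis = 0L),
      list(name = "basal_capture", reactants = c(X1 = 1L),
           products = c(M1 = 1L), kf = kfs[["k7"]], kb = kbs[["k7"]],
           hydrolysis = 1L)))
  attr(net, "atp_adp") <- atp_adp
  # thermodynamic-consistency check: cycle affinities must equal
  # (hydrolysis count) * log(atp_adp)
  aff <- mukCycleAffinities(net)
  expect <- vapply(attr(aff, "cycles"), function(cy)
    sum(h[cy$reactions] * cy$direction), numeric(1)) * log(atp_adp)
  bad <- which(abs(aff - expect) > 1e-8 * (1 + abs(expect)))
  if (length(bad))
    stop("inconsistent cycle affinities in config: cycle(s) ",
         paste(names(aff)[bad], collapse = ", "))
  net
}

#' Cycle affinities of the Muk network
#'
#' The two independent species-level cycles mirror the three-species model:
#' the DD loop (capture, reclose, release, rebind; two hydrolyses per turn)
#' and the dimerisation loop (capture, reclose, dedimerise, redimerise;
#' three hydrolyses). A third, channel-level loop runs between the basal
#' and cooperative capture channels of the same edge; both channels carry
#' one hydrolysis, so its affinity is identically zero at every ATP/ADP
#' ratio. The affinity of a cycle is `sum +- log(kf/kb)` along it (k_B T
#' per turn); at ATP/ADP = 1 all vanish (detailed balance).
#'
#' @param net a [mukNetwork()].
#' @return named numeric vector of affinities with attribute `cycles`.
#' @export
mukCycleAffinities <- function(net) {
  lk <- vapply(net$reactions, function(r) log(r$kf / r$kb), numeric(1))
  names(lk) <- vapply(net$reactions, `[[`, character(1), "name")
  cycles <- list(
    dd_loop = list(reactions = c("capture", "reclose", "release", "rebind"),
                   direction = c(1, 1, 1, 1)),
    dimer_loop = list(reactions = c("capture", "reclose", "dedimerise",
                                    "redimerise"),
                      direction = c(1, 1, 1, 1)),
    capture_pair = list(reactions = c("basal_capture", "capture"),
                        direction = c(1, -1)))
  aff <- vapply(cycles, function(cy)
    sum(lk[cy$reactions] * cy$direction), numeric(1))
  # report cycles with k-table names (the hydrolysis table is keyed that way)
  kmap <- c(capture = "k1", reclose = "k2", release = "k3", rebind = "k4",
            dedimerise = "k5", redimerise = "k6", basal_capture = "k7")
  cycles <- lapply(cycles, function(cy) {
    cy$reactions <- unname(kmap[cy$reactions]); cy
  })
  attr(aff, "cycles") <- cycles
  aff
}

#' Dispersion relation of a generic network
#'
#' Numeric analogue of [dispersionRelation()] for arbitrary networks: the
#' reaction Jacobian at the relaxed well-mixed steady state is formed by
#' finite differences and `rho(q) = max Re eig(J - q^2 diag(D))`.
#'
#' @param network an [reactionNetwork()].
#' @param c_tot total weighted concentration (um^-1).
#' @param q wavevector grid (um^-1).
#' @return list with `q`, `rho`, `q0`, `rho_max`, `u_star`.
#' @export
networkDispersion <- function(network, c_tot, q = seq(0, 40, length.out = 400)) {
  us <- .wellMixedSteady(network, c_tot)
  S <- length(us)
  sm <- .stoichMatrices(network)
  g1 <- structure(list(L = 1, n_box = 1L, dx = 1, x = 0.5,
                       boundary = "no-flux"), class = "rdGeometry")
  f0 <- as.numeric(.pdeRhs(network, g1, matrix(us, S, 1), sm))
  J <- matrix(0, S, S)
  for (j in seq_len(S)) {
    h <- 1e-6 * max(us[j], 1e-6 * max(us))
    up <- us; up[j] <- up[j] + h
    J[, j] <- (as.numeric(.pdeRhs(network, g1, matrix(up, S, 1), sm)) - f0) / h
  }
  rho <- vapply(q, function(qq) .rhoOfQ(J, network$D, qq), numeric(1))
  imax <- which.max(rho)
  list(q = q, rho = rho, q0 = q[imax], rho_max = rho[imax], u_star = us,
       J = J)
}

#' Positional error of the Muk pattern across ATP/ADP ratios
#'
#' Stochastic scan: at each ratio, replicate trajectories are run from the
#' well-mixed composition, the DNA-bound cluster species X2 is tracked, and
#' sigma is summarised. Ratios where the pattern fails or forms with the
#' wrong stripe number are flagged in the table rather than erroring.
#'
#' @param atp_grid ATP/ADP ratios to scan.
#' @param N total dimer-equivalent molecule number.
#' @param geometry an [rdGeometry()].
#' @param t_end,sample_dt horizon and snapshot interval (s).
#' @param n_replicates replicates per ratio.
#' @param seed_base base seed.
#' @param params Muk parameter list.
#' @param target_stripes target pattern.
#' @return data.frame with per-ratio mean `sigma`, `sem`, `n_ok`, `status`.
#' @export
mukSigmaScan <- function(atp_grid, N, geometry, t_end, sample_dt,
                         n_replicates = 3, seed_base = 1,
                         params = mukParams(), target_stripes = 3) {
  rows <- lapply(seq_along(atp_grid), function(i) {
    net <- mukNetwork(atp_grid[i], params)
    ss <- tryCatch(patternedSteadyState(net, geometry, N / geometry$L,
                                        target_stripes, t_relax = 300,
                                        activator = 3, donor = 1,
                                        max_stages = 3),
                   error = function(e) NULL)
    if (is.null(ss))
      return(data.frame(atp_adp = atp_grid[i], sigma = NA_real_,
                        sem = NA_real_, n_ok = 0L,
                        status = "no deterministic target pattern"))
    init <- latticeStateFromField(ss, geometry, net, N = N)
    status <- character(0)
    sigs <- numeric(0)
    for (r in seq_len(n_replicates)) {
      kym <- runSSA(net, geometry, init, t_end, sample_dt,
                    seed = seed_base + 1000 * i + r)
      res <- tryCatch({
        tr <- trackPeak(kym, species = "X2", target_stripes = target_stripes)
        if (tr$frac_invalid > 0.2)
          list(s = NA_real_, st = "wrong stripe count")
        else list(s = tr$sigma, st = "ok")
      }, error = function(e) list(s = NA_real_, st = "pattern lost"))
      sigs <- c(sigs, res$s); status <- c(status, res$st)
    }
    okv <- sigs[status == "ok"]
    data.frame(atp_adp = atp_grid[i],
               sigma = if (length(okv)) mean(okv) else NA_real_,
               sem = if (length(okv) > 1) stats::sd(okv) / sqrt(length(okv))
               else NA_real_,
               n_ok = length(okv),
               status = if (length(okv) >= max(1, n_replicates %/% 2)) "ok"
               else paste(unique(status[status != "ok"]), collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Maximum molecule number sustaining the Muk pattern vs ATP/ADP
#'
#' For each ratio, the largest N in `N_grid` at which the target pattern is
#' sustained (majority of replicates track it with at most 20% invalid
#' samples).
#'
#' @inheritParams mukSigmaScan
#' @param N_grid molecule-number grid (ascending).
#' @return data.frame with columns `atp_adp`, `N_max` (NA when no N in the
#'   grid sustains the pattern).
#' @export
mukNmaxScan <- function(atp_grid, N_grid, geometry, t_end, sample_dt,
                        n_replicates = 2, seed_base = 1,
                        params = mukParams(), target_stripes = 3) {
  N_grid <- sort(N_grid)
  rows <- lapply(seq_along(atp_grid), function(i) {
    net <- mukNetwork(atp_grid[i], params)
    nmax <- NA_real_
    for (j in seq_along(N_grid)) {
      ss <- tryCatch(patternedSteadyState(net, geometry,
                                          N_grid[j] / geometry$L,
                                          target_stripes, t_relax = 300,
                                          activator = 3, donor = 1,
                                          max_stages = 3),
                     error = function(e) NULL)
      if (is.null(ss)) next
      init <- latticeStateFromField(ss, geometry, net, N = N_grid[j])
      ok <- 0
      for (r in seq_len(n_replicates)) {
        kym <- runSSA(net, geometry, init, t_end, sample_dt,
                      seed = seed_base + 1e5 * i + 100 * j + r)
        good <- tryCatch({
          tr <- trackPeak(kym, species = "X2",
                          target_stripes = target_stripes)
          tr$frac_invalid <= 0.2
        }, error = function(e) FALSE)
        ok <- ok + good
      }
      if (ok >= max(1, n_replicates %/% 2 + n_replicates %% 2))
        nmax <- N_grid[j]
    }
    data.frame(atp_adp = atp_grid[i], N_max = nmax)
  })
  do.call(rbind, rows)
}
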