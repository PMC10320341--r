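#' Integrate the deterministic reaction-diffusion equations
#'
#' Method-of-lines integration of the mass-action PDEs on the no-flux box
#' lattice (second-order central Laplacian with ghost-cell reflection,
#' classical RK4 with a stability-limited fixed step). The RK stages are
#' linear in the conserved total, so mass is conserved to round-off.
#'
#' @param network an [reactionNetwork()].
#' @param geometry an [rdGeometry()].
#' @param init S x n_box matrix of initial concentrations (um^-1).
#' @param t_end integration horizon (s).
#' @param sample_dt sampling interval (s).
#' @param dt RK4 step (s); default 0.8 x the linear stability limit
#'   estimated from the diffusion CFL and the reaction Jacobian.
#' @param t0 initial time.
#' @return an `rdKymograph` of concentration snapshots.
#' @export
integratePDE <- function(network, geometry, init, t_end,
                         sample_dt = t_end / 100, dt = NULL, t0 = 0) {
  stopifnot(t_end > t0, all(init >= 0),
            nrow(init) == length(network$species),
            ncol(init) == geometry$n_box)
  sm <- .stoichMatrices(network)
  if (is.null(dt)) dt <- .stableStep(network, geometry, init, sm)
  out <- .rd_integrate_cpp(init, sm$reac, sm$net, sm$k, network$D,
                           geometry$dx, t0, t_end, dt, sample_dt)
  newKymograph(out$times, out$fields, geometry, network$species,
               stochastic = FALSE,
               meta = list(network = network, dt = dt))
}

# explicit-RK stability-limited step: diffusion CFL + reaction Jacobian bound
.stableStep <- function(network, geometry, init, sm = .stoichMatrices(network)) {
  lam_diff <- 4 * max(network$D) / geometry$dx^2
  # bound attainable local concentrations: patterns concentrate mass, so the
  # initial per-species maxima are not a safe stiffness bound for the cubic
  # rates; use twice the largest per-box total as the working ceiling
  ucap <- 2 * max(colSums(init))
  umax <- pmax(pmin(apply(init, 1, max) * 4, ucap), ucap / 4, 1e-12)
  # bound on reaction Jacobian: sum over channels of k * d(monomial)/du
  lam_reac <- 0
  for (cch in seq_along(sm$k)) {
    if (sm$k[cch] == 0) next
    mono <- prod(umax^sm$reac[, cch])
    lam_reac <- lam_reac + sm$k[cch] * sum(sm$reac[, cch] * mono /
                                             pmax(umax, 1e-300))
  }
  0.8 * 2.5 / (lam_diff + lam_reac)
}

# deterministic RHS (reaction + diffusion) of a field, um^-1 s^-1
.pdeRhs <- function(network, geometry, u, sm = .stoichMatrices(network)) {
  .rd_rhs_cpp(u, sm$reac, sm$net, sm$k, network$D, geometry$dx)
}

#' Patterned steady state with a given stripe count
#'
#' Starts from the homogeneous fixed point seeded with a 1% cosine
#' perturbation of the target mode (wavevector `q_n = 2*pi*n/L`, i.e. `n`
#' interior stripes with a trough at each wall), relaxes the PDE and then
#' polishes the state by Newton iteration on the steady-state system with
#' the mass constraint substituted for one redundant equation.
#'
#' @param network an [reactionNetwork()] (three-species or compatible).
#' @param geometry an [rdGeometry()].
#' @param c_tot total concentration N/L (um^-1).
#' @param n_stripes target stripe count n.
#' @param fixed_point optional precomputed homogeneous fixed point vector
#'   (length S); defaults to [homogeneousFixedPoint()] applied to the
#'   three-species rates in `network$meta`, or the relaxed well-mixed state.
#' @param t_relax PDE relaxation horizon (s).
#' @param tol residual tolerance relative to `c_tot` (per second).
#' @param activator,donor species indices used for the seed perturbation
#'   (slow patterned species and the fast species that donates the mass).
#' @return S x n_box matrix of steady concentrations with attributes
#'   `residual` (max |du/dt|) and `n_stripes`.
#' @export
patternedSteadyState <- function(network, geometry, c_tot, n_stripes,
                                 fixed_point = NULL, t_relax = 2000,
                                 tol = 1e-8, activator = 2, donor = 1,
                                 max_stages = 8) {
  S <- length(network$species)
  if (is.null(fixed_point)) fixed_point <- .wellMixedSteady(network, c_tot)
  q <- 2 * pi * n_stripes / geometry$L
  seed <- -cos(q * geometry$x)          # interior peaks, troughs at walls
  u0 <- matrix(rep(fixed_point, geometry$n_box), S, geometry$n_box)
  # move 1% of the activator amplitude between the two dominant species,
  # keeping the conserved total exactly
  amp <- 0.01 * fixed_point[activator]
  u0[activator, ] <- u0[activator, ] + amp * seed
  u0[donor, ] <- u0[donor, ] -
    amp * seed * network$weights[activator] / network$weights[donor]
  # slow transients (soft phase mode, slow X3 exchange) can outlast any
  # single horizon: alternate PDE relaxation with Newton polish until the
  # residual tolerance is met
  u <- u0
  res <- Inf
  for (stage in seq_len(max_stages)) {
    kym <- integratePDE(network, geometry, u, t_end = t_relax,
                        sample_dt = t_relax / 4)
    u <- fieldAt(kym)
    sc <- stripeCount(u[activator, ])
    if (sc != n_stripes)     # wrong mode: no point polishing further
      stop(sprintf("mode not sustained: relaxed to a %g-stripe state", sc))
    up <- .newtonSteady(network, geometry, u, c_tot)
    res_relax <- max(abs(.pdeRhs(network, geometry, u)))
    res_pol <- max(abs(.pdeRhs(network, geometry, up)))
    if (res_pol <= res_relax) { u <- up; res <- res_pol } else res <- res_relax
    if (res <= tol * c_tot) break
  }
  if (res > tol * c_tot)
    stop(sprintf("mode not sustained: steady-state residual %g > %g",
                 res, tol * c_tot))
  if (stripeCount(u[activator, ]) != n_stripes)
    stop(sprintf("mode not sustained: relaxed to a %g-stripe state",
                 stripeCount(u[activator, ])))
  amp <- (max(u[activator, ]) - min(u[activator, ])) / 2
  if (amp < 0.01 * mean(u[activator, ]))
    stop("mode not sustained: amplitude ~ 0 (homogeneous state, below onset)")
  attr(u, "residual") <- res
  attr(u, "n_stripes") <- n_stripes
  u
}

# well-mixed steady state of a generic network by relaxation (one box)
.wellMixedSteady <- function(network, c_tot, t_relax = 5000) {
  S <- length(network$species)
  w <- network$weights
  u0 <- matrix(c_tot * (w / sum(w)) / w, S, 1)   # equal weighted partition
  g1 <- structure(list(L = 1, n_box = 1L, dx = 1, x = 0.5,
                       boundary = "no-flux"), class = "rdGeometry")
  kym <- integratePDE(network, g1, u0, t_end = t_relax,
                      sample_dt = t_relax / 2)
  as.numeric(fieldAt(kym))
}

# Analytic Jacobian of the lattice RHS (reaction blocks per box + diffusion
# tridiagonal with reflecting ends), n x n with n = S*n_box.
.pdeJacobian <- function(network, geometry, u, sm = .stoichMatrices(network)) {
  S <- nrow(u); B <- ncol(u); n <- S * B
  J <- matrix(0, n, n)
  idx <- function(s, b) s + (b - 1L) * S
  for (b in seq_len(B)) {
    Jb <- matrix(0, S, S)
    for (cc in seq_along(sm$k)) {
      k <- sm$k[cc]
      if (k == 0) next
      nu <- sm$reac[, cc]
      for (s2 in which(nu > 0)) {
        # d(k prod u^nu)/du_s2 = k nu_s2 u_s2^(nu-1) prod_others
        dflux <- k * nu[s2] * u[s2, b]^(nu[s2] - 1)
        oth <- which(nu > 0 & seq_len(S) != s2)
        for (s3 in oth) dflux <- dflux * u[s3, b]^nu[s3]
        Jb[, s2] <- Jb[, s2] + sm$net[, cc] * dflux
      }
    }
    J[idx(seq_len(S), b), idx(seq_len(S), b)] <- Jb
  }
  idx2 <- 1 / geometry$dx^2
  for (b in seq_len(B)) {
    for (s in seq_len(S)) {
      i <- idx(s, b)
      nn <- if (B == 1) 0 else if (b == 1 || b == B) 1 else 2
      J[i, i] <- J[i, i] - nn * network$D[s] * idx2
      if (b > 1) J[i, idx(s, b - 1)] <- J[i, idx(s, b - 1)] +
          network$D[s] * idx2
      if (b < B) J[i, idx(s, b + 1)] <- J[i, idx(s, b + 1)] +
          network$D[s] * idx2
    }
  }
  J
}

# Newton polish of a lattice steady state under the conservation constraint:
# the RHS Jacobian is singular along the conserved direction, so one
# component equation is replaced by the weighted-mass constraint.
.newtonSteady <- function(network, geometry, u, c_tot, iters = 12) {
  S <- length(network$species)
  B <- geometry$n_box
  n <- S * B
  sm <- .stoichMatrices(network)
  w <- rep(network$weights, B)
  mass0 <- c_tot * geometry$L / geometry$dx   # sum of weighted u equals this
  # full residual (all n dynamic equations) plus the mass constraint as an
  # extra stacked equation: dropping a component instead would let the
  # line search reduce its objective while the dropped equation diverges
  fvec <- function(x) {
    c(as.numeric(.pdeRhs(network, geometry, matrix(x, S, B), sm)),
      sum(w * x) - mass0)
  }
  x <- as.numeric(u)
  f <- fvec(x)
  for (it in seq_len(iters)) {
    if (max(abs(f)) < 1e-12 * c_tot) break
    J <- rbind(.pdeJacobian(network, geometry, matrix(x, S, B), sm), w)
    # the pattern's translational phase mode makes the dynamic block nearly
    # singular: least-squares Newton on the stacked system (QR; damped
    # fallbacks), accepting only residual-decreasing steps
    scl <- max(abs(J))
    improved <- FALSE
    for (lam in c(0, 1e-10, 1e-6, 1e-3) * scl) {
      A <- if (lam > 0) rbind(J, lam * diag(n)) else J
      bvec <- if (lam > 0) -c(f, numeric(n)) else -f
      dx <- tryCatch(qr.solve(A, bvec), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) next
      step <- 1
      for (bt in 1:10) {
        xn <- x + step * dx
        if (all(is.finite(xn)) && all(xn > -1e-8 * c_tot)) {
          fn <- fvec(pmax(xn, 0))
          if (max(abs(fn)) < max(abs(f))) {
            x <- pmax(xn, 0); f <- fn; improved <- TRUE
            break
          }
        }
        step <- step / 2
      }
      if (improved) break
    }
    if (!improved) break
  }
  matrix(x, S, B)
}

#' Count the stripes of a 1-D concentration profile
#'
#' The stripe number is read off the dominant cosine mode on the no-flux
#' domain: the profile is projected on `cos(k*pi*x/L)` (the discrete Neumann
#' eigenmodes) and the maximising `k` is halved, so a three-stripe pattern
#' (wavelength L/3) reports 3 whether its peaks sit at the walls or in the
#' interior. Robust to noise, unlike local-extremum counting.
#'
#' @param profile numeric vector of box values.
#' @param k_max largest mode index examined.
#' @return stripe count (multiple of 0.5).
#' @export
stripeCount <- function(profile, k_max = min(length(profile) - 1L, 20L)) {
  B <- length(profile)
  xi <- (seq_len(B) - 0.5) / B
  amp <- vapply(seq_len(k_max), function(k)
    abs(2 * mean(profile * cos(k * pi * xi))), numeric(1))
  if (max(amp) < 1e-12 * (abs(mean(profile)) + max(amp))) return(0)
  which.max(amp) / 2
}
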