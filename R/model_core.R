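#' Rate constants of the reversible three-species network
#'
#' The network couples three conformations X1, X2, X3 of one protein through
#' three reversible linear conversions (X1<->X2, X2<->X3, X3<->X1) and one
#' reversible autocatalytic reaction X1 + 2 X2 <-> 3 X2. The autocatalytic
#' rates `kt12`, `kt21` carry units s^-1 um^2 (1-D concentration convention).
#'
#' Zero backward rates are only admitted with `irreversible = TRUE`
#' (the original irreversible-limit model, `kt21 = 0`); thermodynamic
#' quantities are undefined there and [computeThermo()] refuses such sets.
#'
#' @param k12,k21,k23,k32,k31,k13 first-order conversion rates (s^-1).
#' @param kt12,kt21 autocatalytic forward/backward rates (s^-1 um^2).
#' @param irreversible declare the irreversible limit (allows `kt21 = 0`).
#' @return object of class `rateConstants`.
#' @export
rateConstants <- function(k12, k21, k23, k32, k31, k13, kt12, kt21,
                          irreversible = FALSE) {
  r <- c(k12 = k12, k21 = k21, k23 = k23, k32 = k32, k31 = k31, k13 = k13,
         kt12 = kt12, kt21 = kt21)
  stopifnot(all(r >= 0), kt12 > 0)
  if (!irreversible && any(r[c("k21", "k32", "k31", "kt21")] == 0))
    stop("zero backward rate: irreversible limit, dissipation undefined ",
         "(pass irreversible = TRUE to allow)")
  structure(as.list(r), irreversible = irreversible, class = "rateConstants")
}

#' Diffusion constants of the three species
#'
#' By default D3 = D1 (same protein in different conformations). The ratio
#' `d = D1/D2 > 1` is the classic Turing requirement (fast inhibitor /
#' substrate, slow activator).
#'
#' @param D1,D2,D3 diffusion constants (um^2/s).
#' @return object of class `diffusionConstants` with derived ratio `d`.
#' @export
diffusionConstants <- function(D1, D2, D3 = D1) {
  stopifnot(D1 > 0, D2 > 0, D3 > 0)
  structure(list(D1 = D1, D2 = D2, D3 = D3, d = D1 / D2),
            class = "diffusionConstants")
}

#' Cycle irreversibility parameters and chemical driving
#'
#' The network has two independent reaction cycles: the autocatalytic/linear
#' X1->X2->X1 cycle with irreversibility `Gamma = kt21*k12/(kt12*k21)` and
#' the linear loop X1->X2->X3->X1 with
#' `GammaPrime = k13*k32*k21/(k12*k23*k31)`. The system is at equilibrium iff
#' both equal 1. The chemical driving per cycle is `W = -log(Gamma)` (k_B T).
#'
#' @param rates a [rateConstants()] object.
#' @return object of class `thermoState` with `Gamma`, `GammaPrime`, `W`,
#'   `Wprime`.
#' @export
computeThermo <- function(rates) {
  r <- rates
  if (any(unlist(r[c("k21", "k32", "k31", "kt21")]) == 0))
    stop("irreversible limit, dissipation undefined")
  Gamma <- r$kt21 * r$k12 / (r$kt12 * r$k21)
  GammaPrime <- r$k13 * r$k32 * r$k21 / (r$k12 * r$k23 * r$k31)
  structure(list(Gamma = Gamma, GammaPrime = GammaPrime,
                 W = -log(Gamma), Wprime = -log(GammaPrime)),
            class = "thermoState")
}

#' @export
print.thermoState <- function(x, ...) {
  cat(sprintf("Gamma = %.4g (W = %.3f kT), Gamma' = %.4g (W' = %.3f kT)\n",
              x$Gamma, x$W, x$GammaPrime, x$Wprime))
  invisible(x)
}

#' Effective autocatalytic rates at a given total concentration
#'
#' In relative-concentration variables v = u/c_tot the autocatalytic rates
#' become `beta = kt * c_tot^2 = kt * N^2 / L^2`; these grow quadratically
#' with molecule number and control the N-dependence of the Turing onset.
#'
#' @param rates a [rateConstants()] object.
#' @param c_tot total concentration N/L (um^-1).
#' @return list with `beta12`, `beta21` (s^-1).
#' @export
effectiveRates <- function(rates, c_tot) {
  stopifnot(c_tot >= 0)
  list(beta12 = rates$kt12 * c_tot^2, beta21 = rates$kt21 * c_tot^2)
}

#' Build the three-species reaction network
#'
#' @param rates a [rateConstants()] object.
#' @param diffusion a [diffusionConstants()] object.
#' @return an [reactionNetwork()] object with species `u1`, `u2`, `u3`.
#' @export
threeSpeciesNetwork <- function(rates, diffusion) {
  reactionNetwork(
    species = c("u1", "u2", "u3"),
    D = c(diffusion$D1, diffusion$D2, diffusion$D3),
    reactions = list(
      list(name = "lin12", reactants = c(u1 = 1L), products = c(u2 = 1L),
           kf = rates$k12, kb = rates$k21),
      list(name = "lin23", reactants = c(u2 = 1L), products = c(u3 = 1L),
           kf = rates$k23, kb = rates$k32),
      list(name = "lin31", reactants = c(u3 = 1L), products = c(u1 = 1L),
           kf = rates$k31, kb = rates$k13),
      list(name = "auto", reactants = c(u1 = 1L, u2 = 2L),
           products = c(u2 = 3L), kf = rates$kt12, kb = rates$kt21)))
}

# well-mixed RHS for the three-species model (analytic; used for fixed points)
.wmRhs3 <- function(u, r) {
  auto <- r$kt12 * u[1] * u[2]^2 - r$kt21 * u[2]^3
  f1 <- -(r$k12 + r$k13) * u[1] + r$k21 * u[2] + r$k31 * u[3] - auto
  f2 <- r$k12 * u[1] - (r$k21 + r$k23) * u[2] + r$k32 * u[3] + auto
  f3 <- r$k13 * u[1] + r$k23 * u[2] - (r$k31 + r$k32) * u[3]
  c(f1, f2, f3)
}

# analytic Jacobian of the well-mixed three-species reaction terms
.wmJac3 <- function(u, r) {
  da1 <- r$kt12 * u[2]^2                       # d auto / d u1
  da2 <- 2 * r$kt12 * u[1] * u[2] - 3 * r$kt21 * u[2]^2
  matrix(c(-(r$k12 + r$k13) - da1, r$k21 - da2, r$k31,
           r$k12 + da1, -(r$k21 + r$k23) + da2, r$k32,
           r$k13, r$k23, -(r$k31 + r$k32)),
         3, 3, byrow = TRUE)
}

#' All nonnegative homogeneous steady states
#'
#' Eliminating u3 (species-3 balance) and u1 (mass conservation) reduces the
#' well-mixed steady-state system to a cubic in u2, solved exactly.
#'
#' @param rates a [rateConstants()] object.
#' @param c_tot total concentration (um^-1).
#' @return matrix with one row per nonnegative root, columns u1, u2, u3.
#' @export
fixedPointRoots <- function(rates, c_tot) {
  r <- rates
  A <- r$k31 + r$k32
  b1 <- (r$k23 - r$k13) / (A + r$k13)
  b0 <- r$k13 * c_tot / (A + r$k13)
  a0 <- c_tot - b0
  a1 <- -(1 + b1)
  # f1(u2) = 0 with u1 = a0 + a1 u2, u3 = b0 + b1 u2
  cf <- c(-(r$k12 + r$k13) * a0 + r$k31 * b0,
          -(r$k12 + r$k13) * a1 + r$k21 + r$k31 * b1,
          -r$kt12 * a0,
          -r$kt12 * a1 + r$kt21)
  z <- polyroot(cf)
  u2 <- Re(z[abs(Im(z)) < 1e-8 * (1 + abs(Re(z)))])
  u2 <- u2[u2 >= -1e-12 * c_tot]
  out <- t(vapply(u2, function(v) {
    c(u1 = a0 + a1 * v, u2 = max(v, 0), u3 = b0 + b1 * v)
  }, numeric(3)))
  out <- out[out[, 1] >= -1e-9 * c_tot & out[, 3] >= -1e-9 * c_tot, ,
             drop = FALSE]
  pmax(out, 0)
}

#' Homogeneous fixed point of the well-mixed dynamics
#'
#' Returns the steady state reached by relaxation from the uniform
#' equal-partition state (the physically selected root when the cubic has
#' several nonnegative solutions; see [fixedPointRoots()] for all of them),
#' polished by Newton iteration on the reduced system.
#'
#' @param rates a [rateConstants()] object.
#' @param c_tot total concentration N/L (um^-1), > 0.
#' @return object of class `homogeneousFixedPoint` with fields `u1s`, `u2s`,
#'   `u3s` (um^-1), `v2s = u2s/c_tot` and `c_tot`.
#' @export
homogeneousFixedPoint <- function(rates, c_tot) {
  stopifnot(c_tot > 0)
  roots <- fixedPointRoots(rates, c_tot)
  if (nrow(roots) == 0)
    stop("invalid parameter regime: no nonnegative homogeneous steady state")
  if (nrow(roots) == 1) {
    u <- as.numeric(roots[1, ])
  } else {
    # several admissible roots: select by relaxation from equal partition
    u <- rep(c_tot / 3, 3)
    for (iter in 1:20000) {
      f <- .wmRhs3(u, rates)
      if (max(abs(f)) < 1e-10 * c_tot) break
      h <- 0.5 / max(rowSums(abs(.wmJac3(u, rates))))
      u <- pmax(u + h * f, 0)
      s <- sum(u); u <- u * (c_tot / s)
    }
    u <- as.numeric(roots[which.min(colSums((t(roots) - u)^2)), ])
  }
  # Newton polish on (u2, u3) with u1 = c_tot - u2 - u3
  for (iter in 1:50) {
    f <- .wmRhs3(u, rates)[2:3]
    if (max(abs(f)) < 1e-13 * c_tot) break
    J <- .wmJac3(u, rates)
    Jr <- J[2:3, 2:3] - J[2:3, 1]   # eliminate u1
    du <- tryCatch(solve(Jr, -f), error = function(e) c(0, 0))
    u[2:3] <- u[2:3] + du
    u[1] <- c_tot - u[2] - u[3]
  }
  if (any(u < -1e-9 * c_tot) || max(abs(.wmRhs3(u, rates))) > 1e-6 * c_tot)
    stop("invalid parameter regime: no nonnegative homogeneous steady state found")
  u <- pmax(u, 0)
  structure(list(u1s = u[1], u2s = u[2], u3s = u[3],
                 v2s = u[2] / c_tot, c_tot = c_tot),
            class = "homogeneousFixedPoint")
}

#' @export
print.homogeneousFixedPoint <- function(x, ...) {
  cat(sprintf(
    "homogeneous fixed point (c_tot = %g /um): u1* = %.6g, u2* = %.6g, u3* = %.6g (v2* = %.4f)\n",
    x$c_tot, x$u1s, x$u2s, x$u3s, x$v2s))
  invisible(x)
}
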