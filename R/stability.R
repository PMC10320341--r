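#' Dispersion relation of the homogeneous state
#'
#' Linearising the reaction-diffusion equations about the homogeneous fixed
#' point gives, for each wavevector q, the growth-rate matrix
#' `J - q^2 diag(D)` where J is the reaction Jacobian at the fixed point.
#' `rho(q)` is the largest real part of its eigenvalues. At q = 0 one
#' eigenvalue is exactly zero (the conserved-total direction).
#'
#' @param rates a [rateConstants()] object.
#' @param diffusion a [diffusionConstants()] object.
#' @param c_tot total concentration (um^-1).
#' @param q wavevector grid (um^-1); default covers the unstable band.
#' @return object of class `dispersionResult` with fields `q`, `rho` (s^-1),
#'   `q0` (maximising wavevector, refined off-grid), `rho_max`, `xi2`
#'   (curvature length^2, um^2, see Details) and `tau` left NA until an
#'   onset calculation fixes the timescale.
#' @details Near onset the growth rate is modelled as
#'   `rho(q) ~ (eps0 - xi^2 (q - q0)^2)/tau`; `xi^2` is obtained from the
#'   finite-difference curvature of rho at q0 together with the timescale
#'   `tau = 1/(kt0 |d rho_max/d kt21|)` evaluated at onset (the published
#'   normalisation of xi is ambiguous; this pairing is the one that makes
#'   the finite-size onset shift dimensionless and is used consistently).
#' @export
dispersionRelation <- function(rates, diffusion, c_tot, q = NULL) {
  fp <- homogeneousFixedPoint(rates, c_tot)
  J <- .wmJac3(c(fp$u1s, fp$u2s, fp$u3s), rates)
  D <- c(diffusion$D1, diffusion$D2, diffusion$D3)
  if (is.null(q)) {
    qmax <- 3 * sqrt(max(rates$k21, rates$k12, rates$kt12 * c_tot^2) /
                       min(D))
    q <- seq(0, qmax, length.out = 400)
  }
  rho <- vapply(q, function(qq) .rhoOfQ(J, D, qq), numeric(1))
  # the conserved total gives rho(0) = 0 exactly; the Turing-relevant
  # quantity is the interior band maximum at q > 0, not the zero mode
  nq <- length(q)
  loc <- which(rho[2:(nq - 1)] >= rho[1:(nq - 2)] &
                 rho[2:(nq - 1)] >= rho[3:nq]) + 1L
  loc <- loc[q[loc] > 0]
  imax <- if (length(loc)) loc[which.max(rho[loc])]
          else which.max(rho[-(1:2)]) + 2L
  q0 <- q[imax]; rho_max <- rho[imax]
  if (imax > 1 && imax < length(q)) {
    opt <- stats::optimize(function(qq) -.rhoOfQ(J, D, qq),
                           interval = c(q[imax - 1], q[imax + 1]),
                           tol = 1e-10)
    q0 <- opt$minimum; rho_max <- -opt$objective
  }
  # curvature d2 rho/dq2 at q0 by central differences (relative step 1e-3)
  h <- max(1e-3 * q0, 1e-6)
  curv <- (.rhoOfQ(J, D, q0 + h) - 2 * .rhoOfQ(J, D, q0) +
             .rhoOfQ(J, D, q0 - h)) / h^2
  structure(list(q = q, rho = rho, q0 = q0, rho_max = rho_max,
                 curvature = curv, xi2 = NA_real_, tau = NA_real_,
                 J = J, D = D, fixed_point = fp),
            class = "dispersionResult")
}

.rhoOfQ <- function(J, D, q) {
  max(Re(eigen(J - q^2 * diag(D), only.values = TRUE)$values))
}

#' @export
print.dispersionResult <- function(x, ...) {
  cat(sprintf("dispersion: q0 = %.4g /um, rho(q0) = %.4g /s, curvature = %.4g\n",
              x$q0, x$rho_max, x$curvature))
  invisible(x)
}

# max over q > 0 of rho(q) for given kt21 (all other rates fixed)
.rhoMaxAt <- function(rates, diffusion, c_tot, kt21) {
  r <- rates; r$kt21 <- kt21
  disp <- dispersionRelation(r, diffusion, c_tot)
  list(rho = disp$rho_max, disp = disp)
}

#' Infinite-system Turing onset of the reverse autocatalytic rate
#'
#' Increasing `kt21` (weakening the driving) stabilises the homogeneous
#' state; `kt0` is the value at which the maximal growth rate over all
#' wavevectors crosses zero. Found by bisection to relative precision 1e-6.
#'
#' @param rates a [rateConstants()] object; its `kt21` seeds the bracket.
#' @param diffusion a [diffusionConstants()] object.
#' @param c_tot total concentration (um^-1).
#' @param bracket optional kt21 search interval.
#' @return `kt0` (s^-1 um^2), with the onset dispersion in attribute
#'   `dispersion`.
#' @export
onsetKt0 <- function(rates, diffusion, c_tot, bracket = NULL) {
  f <- function(kt) .rhoMaxAt(rates, diffusion, c_tot, kt)$rho
  if (is.null(bracket)) {
    lo <- 0
    if (f(lo) <= 0) stop("no onset in range: homogeneous state stable even at infinite driving")
    hi <- max(rates$kt21, rates$kt12 * 1e-3, 1e-9)
    for (i in 1:60) {
      if (f(hi) < 0) break
      hi <- hi * 2
      if (i == 60) stop("no onset in range: no stabilising kt21 found")
    }
    bracket <- c(lo, hi)
  } else if (f(bracket[1]) <= 0 || f(bracket[2]) >= 0) {
    stop("no onset in range: growth rate does not change sign in bracket")
  }
  kt0 <- stats::uniroot(f, bracket, tol = 1e-6 * bracket[2])$root
  attr(kt0, "dispersion") <- .rhoMaxAt(rates, diffusion, c_tot, kt0)$disp
  kt0
}

#' Finite-system onset for a given stripe mode
#'
#' In a domain of length L the admissible pattern wavevectors are
#' `q_n = 2*pi*n/L` (wavelength L/n). Because `q_n` generally differs from
#' the fastest-growing `q0`, phase stability of the n-stripe pattern is lost
#' before the infinite-system onset:
#' `ktc = kt0 * (1 - 3 xi^2 dq^2)` with `dq = q_n - q0`. The corresponding
#' critical irreversibilities `Gamma0 = kt0 k12/(kt12 k21)` and
#' `Gammac = ktc k12/(kt12 k21)` give the onset drivings `W0 < Wc`.
#'
#' @inheritParams onsetKt0
#' @param geometry an [rdGeometry()].
#' @param n stripe-mode index (n >= 1).
#' @param q_convention `"2pi"` for `q_n = 2*pi*n/L` (default) or `"neumann"`
#'   for `q_n = n*pi/L`.
#' @return object of class `criticalScan` with fields `kt0`, `ktc`, `zeta`,
#'   `Gamma0`, `Gammac`, `W0`, `Wc`, `q0`, `qn`, `dq`, `xi2`, `tau`.
#' @export
onsetKtcFinite <- function(rates, diffusion, c_tot, geometry, n,
                           q_convention = c("2pi", "neumann")) {
  q_convention <- match.arg(q_convention)
  kt0 <- onsetKt0(rates, diffusion, c_tot)
  disp <- attr(kt0, "dispersion")
  kt0 <- as.numeric(kt0)
  # timescale from the kt21-sensitivity of the maximal growth rate at onset
  h <- 1e-3 * kt0
  slope <- (.rhoMaxAt(rates, diffusion, c_tot, kt0 + h)$rho -
              .rhoMaxAt(rates, diffusion, c_tot, kt0 - h)$rho) / (2 * h)
  tau <- 1 / (abs(slope) * kt0)
  xi2 <- -0.5 * tau * disp$curvature
  qn <- if (q_convention == "2pi") 2 * pi * n / geometry$L else n * pi / geometry$L
  dq <- qn - disp$q0
  zeta <- 1 - 3 * xi2 * dq^2
  if (zeta <= 0)
    stop("mode outside phase-stable band: zeta = 1 - 3 xi^2 dq^2 <= 0")
  ktc <- kt0 * zeta
  Gamma0 <- kt0 * rates$k12 / (rates$kt12 * rates$k21)
  Gammac <- ktc * rates$k12 / (rates$kt12 * rates$k21)
  structure(list(kt0 = kt0, ktc = ktc, zeta = zeta,
                 Gamma0 = Gamma0, Gammac = Gammac,
                 W0 = -log(Gamma0), Wc = -log(Gammac),
                 q0 = disp$q0, qn = qn, dq = dq, xi2 = xi2, tau = tau),
            class = "criticalScan")
}

#' @export
print.criticalScan <- function(x, ...) {
  cat(sprintf("finite-system onset: kt0 = %.4g, ktc = %.4g (zeta = %.4f)\n",
              x$kt0, x$ktc, x$zeta))
  cat(sprintf("  Gamma0 = %.4g (W0 = %.3f), Gammac = %.4g (Wc = %.3f)\n",
              x$Gamma0, x$W0, x$Gammac, x$Wc))
  cat(sprintf("  q0 = %.4g, qn = %.4g, xi2 = %.4g um^2, tau = %.4g s\n",
              x$q0, x$qn, x$xi2, x$tau))
  invisible(x)
}

#' Minimum diffusion-constant ratio for a Turing instability
#'
#' At infinite chemical driving (`kt21 = 0`) the instability still requires
#' the inhibitor/activator diffusion ratio `d = D1/D2` to exceed a minimum
#' `d_min`; below it no pattern forms at any driving. `D2` is held fixed and
#' `D1 = D3` is varied; the smallest d with a positive growth rate at
#' nonzero wavevector is bisected to absolute precision `tol`.
#'
#' @param rates a [rateConstants()] object (its kt21 is ignored and set to 0).
#' @param D2 activator diffusion constant held fixed (um^2/s).
#' @param c_tot total concentration (um^-1).
#' @param bracket search interval for d.
#' @param tol bisection tolerance on d.
#' @return `d_min` (dimensionless).
#' @export
findDmin <- function(rates, D2, c_tot, bracket = c(1, 100), tol = 1e-3) {
  r <- rates
  r$kt21 <- 0
  unstable <- function(d) {
    disp <- dispersionRelation(r, diffusionConstants(D1 = d * D2, D2 = D2),
                               c_tot)
    # require growth at a genuinely finite wavevector (exclude the q ~ 0
    # conserved mode)
    disp$rho_max > 1e-12 && disp$q0 > disp$q[2]
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (unstable(lo)) return(lo)
  if (!unstable(hi)) stop("no instability found up to d = ", hi)
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (unstable(mid)) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

#' Closed-form critical effective rate and onset irreversibility
#'
#' In the large-d limit the critical effective reverse rate `beta0` (the
#' onset value of `beta21 = kt21 c_tot^2`) has the closed form
#' `beta0 = -2 k12 R1 / v2*^3 + (2 k12 R1 R2 + k21) / v2*^2` with
#' `R1 = (k31+k32+k13)/(k31+k32)`, `R2 = (k31+k32+k23)/(k31+k32)`, and `v2*`
#' the relative activator concentration of the homogeneous fixed point.
#' The infinite-system onset irreversibility is
#' `Gamma0 = beta0 k12 / (beta12 k21)`.
#'
#' @param rates a [rateConstants()] object.
#' @param c_tot total concentration (um^-1).
#' @return list with `beta0`, `Gamma0`, `R1`, `R2`, `v2s`, `beta12`.
#' @export
beta0Gamma0 <- function(rates, c_tot) {
  fp <- homogeneousFixedPoint(rates, c_tot)
  v2 <- fp$v2s
  if (v2 <= 0) stop("v2* = 0: fixed point has no activator")
  A <- rates$k31 + rates$k32
  R1 <- (A + rates$k13) / A
  R2 <- (A + rates$k23) / A
  beta0 <- -2 * rates$k12 * R1 / v2^3 + (2 * rates$k12 * R2 * R1 + rates$k21) / v2^2
  beta12 <- rates$kt12 * c_tot^2
  list(beta0 = beta0, Gamma0 = beta0 * rates$k12 / (beta12 * rates$k21),
       R1 = R1, R2 = R2, v2s = v2, beta12 = beta12)
}

#' Critical irreversibility curve over molecule number
#'
#' `Gamma_c(N) = zeta * Gamma_0(N)` where `Gamma_0(N)` comes from the
#' closed-form onset ([beta0Gamma0()]) evaluated at `c_tot = N/L` and the
#' finite-size factor `zeta = 1 - 3 xi^2 dq^2` is evaluated once at a
#' reference molecule number and treated as constant across the scan.
#'
#' @param rates a [rateConstants()] object (operating parameter set).
#' @param diffusion a [diffusionConstants()] object.
#' @param geometry an [rdGeometry()].
#' @param N molecule-number grid.
#' @param n_stripes target mode for the finite-size factor.
#' @param N_ref reference N at which `zeta` is evaluated (default: the grid
#'   point maximising `Gamma_0`).
#' @param zeta optionally supply a precomputed finite-size factor.
#' @return data.frame with columns `N`, `Gamma0`, `GammaC`, `v2s`, `beta0`;
#'   attribute `zeta`.
#' @export
gammaCofN <- function(rates, diffusion, geometry, N, n_stripes = 3,
                      N_ref = NULL, zeta = NULL) {
  g0 <- lapply(N, function(nn) beta0Gamma0(rates, nn / geometry$L))
  Gamma0 <- vapply(g0, `[[`, numeric(1), "Gamma0")
  if (is.null(zeta)) {
    if (is.null(N_ref)) N_ref <- N[which.max(Gamma0)]
    cs <- onsetKtcFinite(rates, diffusion, N_ref / geometry$L, geometry,
                         n_stripes)
    zeta <- cs$zeta
  }
  out <- data.frame(N = N, Gamma0 = Gamma0, GammaC = zeta * Gamma0,
                    v2s = vapply(g0, `[[`, numeric(1), "v2s"),
                    beta0 = vapply(g0, `[[`, numeric(1), "beta0"))
  attr(out, "zeta") <- zeta
  out
}

#' Stable molecule-number window of a target pattern
#'
#' `Gamma_c(N)` rises sharply to a peak at `N*` and then decays like N^-2;
#' a pattern operated at irreversibility `Gamma` is phase-stable where
#' `Gamma_c(N) > Gamma`, so the window boundaries `N_min`, `N_max` are the
#' two roots of `Gamma_c(N) = Gamma`.
#'
#' @inheritParams gammaCofN
#' @param Gamma operating irreversibility (below the peak of `Gamma_c`).
#' @param N_range search interval for the window.
#' @return object of class `nRangeResult` with `N_min`, `N_max`, `N_star`,
#'   `zeta` and the scanned curve in `$curve`.
#' @export
nRange <- function(rates, diffusion, geometry, Gamma, n_stripes = 3,
                   N_range = c(200, 2e6)) {
  # locate the peak of Gamma0(N) on a log grid, then refine
  lg <- seq(log(N_range[1]), log(N_range[2]), length.out = 80)
  curve <- gammaCofN(rates, diffusion, geometry, exp(lg), n_stripes)
  zeta <- attr(curve, "zeta")
  ipk <- which.max(curve$Gamma0)
  if (ipk == 1 || ipk == length(lg))
    stop("Gamma_c peak not interior to N_range")
  opt <- stats::optimize(function(l)
    -beta0Gamma0(rates, exp(l) / geometry$L)$Gamma0,
    interval = lg[c(ipk - 1, ipk + 1)], tol = 1e-8)
  N_star <- exp(opt$minimum)
  Gc_peak <- -opt$objective * zeta
  if (Gamma >= Gc_peak)
    stop(sprintf("no stable-N window: Gamma = %g above the Gamma_c peak %g",
                 Gamma, Gc_peak))
  gcm <- function(l) zeta * beta0Gamma0(rates, exp(l) / geometry$L)$Gamma0 - Gamma
  # lower flank: Gamma_c rises through Gamma between N_range[1] and N*
  lo <- lg[1]
  if (gcm(lo) >= 0) stop("N_range[1] already inside the window")
  N_min <- exp(stats::uniroot(gcm, c(lo, log(N_star)), tol = 1e-7)$root)
  if (gcm(lg[length(lg)]) >= 0) stop("N_range[2] still inside the window")
  N_max <- exp(stats::uniroot(gcm, c(log(N_star), lg[length(lg)]),
                              tol = 1e-7)$root)
  structure(list(N_min = N_min, N_max = N_max, N_star = N_star,
                 zeta = zeta, Gamma = Gamma, curve = curve),
            class = "nRangeResult")
}

#' @export
print.nRangeResult <- function(x, ...) {
  cat(sprintf(
    "stable-N window at Gamma = %g: N_min = %.0f < N* = %.0f < N_max = %.0f (zeta = %.4f)\n",
    x$Gamma, x$N_min, x$N_star, x$N_max, x$zeta))
  invisible(x)
}
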