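#' Forward and backward flux densities of every reaction
#'
#' Mass-action flux densities `j+ = kf prod(u^nu_r)`, `j- = kb prod(u^nu_p)`
#' per box (um^-1 s^-1).
#'
#' @param field S x n_box matrix of concentrations (um^-1).
#' @param network an [reactionNetwork()].
#' @return list with matrices `jplus`, `jminus` (reactions x boxes).
#' @export
channelFluxes <- function(field, network) {
  sm <- .stoichMatrices(network)
  R <- length(network$reactions)
  B <- ncol(field)
  jp <- jm <- matrix(0, R, B)
  for (j in seq_len(R)) {
    f <- 2L * j - 1L; b <- 2L * j
    jp[j, ] <- sm$k[f] * apply(field^sm$reac[, f], 2, prod)
    jm[j, ] <- sm$k[b] * apply(field^sm$reac[, b], 2, prod)
  }
  list(jplus = jp, jminus = jm)
}

#' Chemical dissipation rate density
#'
#' Per box, the sum over reactions of `(j+ - j-) log(j+/j-)` (k_B T s^-1
#' um^-1); each term is nonnegative by the log-mean inequality, so the
#' density is a pointwise second-law bound.
#'
#' @inheritParams channelFluxes
#' @return numeric vector over boxes (k_B T s^-1 um^-1).
#' @export
chemDissipation <- function(field, network) {
  fl <- channelFluxes(field, network)
  bad <- fl$jminus == 0 & fl$jplus > 0
  if (any(bad))
    stop("irreversible limit: zero backward flux with nonzero forward flux")
  term <- (fl$jplus - fl$jminus) * log(fl$jplus / fl$jminus)
  term[fl$jplus == 0 & fl$jminus == 0] <- 0
  colSums(term)
}

#' Diffusive dissipation rate density
#'
#' Continuum mode evaluates `sum_k D_k (du_k/dx)^2 / u_k` with centred
#' differences (ghost-cell reflection at the walls). Discrete mode treats
#' each inter-box hop pair as a reaction channel, `(J+ - J-) log(J+/J-)`
#' with `J+- = (D/dx) u` on either side of the interface, and assigns half
#' of each interface term to each adjacent box; it converges to the
#' continuum form as dx -> 0 and is the exact lattice counterpart used by
#' the steady-state dissipation identity.
#'
#' @inheritParams channelFluxes
#' @param geometry an [rdGeometry()].
#' @param mode `"discrete"` or `"continuum"`.
#' @return numeric vector over boxes (k_B T s^-1 um^-1).
#' @export
diffDissipation <- function(field, network, geometry,
                            mode = c("discrete", "continuum")) {
  mode <- match.arg(mode)
  S <- nrow(field); B <- ncol(field); dx <- geometry$dx
  out <- numeric(B)
  if (mode == "continuum") {
    for (s in seq_len(S)) {
      u <- field[s, ]
      ughost <- c(u[1], u, u[B])           # reflecting walls
      grad <- (ughost[3:(B + 2)] - ughost[1:B]) / (2 * dx)
      nz <- grad != 0
      if (any(nz & u <= 0))
        stop("zero concentration with nonzero gradient")
      out[nz] <- out[nz] + network$D[s] * grad[nz]^2 / u[nz]
    }
  } else {
    for (s in seq_len(S)) {
      u <- field[s, ]
      ul <- u[-B]; ur <- u[-1]
      jp <- network$D[s] / dx * ul         # molecules/s across interface
      jm <- network$D[s] / dx * ur
      w <- numeric(B - 1)
      act <- jp != jm
      if (any(act & (ul == 0 | ur == 0)))
        stop("zero concentration at an active interface")
      w[act] <- (jp[act] - jm[act]) * log(jp[act] / jm[act])
      out[-B] <- out[-B] + 0.5 * w / dx
      out[-1] <- out[-1] + 0.5 * w / dx
    }
  }
  out
}

#' Total dissipation rate from the cycle-flux formula
#'
#' At steady state the spatially integrated dissipation collapses to a
#' two-cycle expression in the species totals N_i alone -- diffusion drops
#' out entirely:
#' `Wdot = J1c log(1/Gamma) + J2c log(1/Gamma')`, with
#' `J2c = k23 N2 - k32 N3` the flux around the linear three-species loop
#' and `J1c = (k21 N2 - k12 N1) + J2c` the flux around the autocatalytic
#' cycle. Note the orientation: the cycle flux J1c is the net
#' autocatalytic conversion rate, which at steady state equals the reverse
#' linear-edge flux `k21 N2 - k12 N1` plus the loop flux J2c; with this
#' orientation the identity with the integrated chemical + diffusive
#' dissipation densities is exact at steady state (the linear-edge flux
#' alone, with either sign, is only the leading approximation when
#' `J1c >> J2c`). Away from steady state the formula is invalid; a warning
#' is attached if the supplied field has a large dynamic residual.
#'
#' @param field S x n_box matrix of concentrations (um^-1) of the
#'   three-species model.
#' @param rates a [rateConstants()] object.
#' @param geometry an [rdGeometry()].
#' @param network optional [threeSpeciesNetwork()] for the residual check.
#' @return `Wdot_total` (k_B T/s) with attributes `J1c`, `J2c`.
#' @export
totalDissipationCycle <- function(field, rates, geometry, network = NULL) {
  th <- computeThermo(rates)
  Ntot <- rowSums(field) * geometry$dx
  J2c <- rates$k23 * Ntot[2] - rates$k32 * Ntot[3]
  J1c <- (rates$k21 * Ntot[2] - rates$k12 * Ntot[1]) + J2c
  W <- J1c * log(1 / th$Gamma) + J2c * log(1 / th$GammaPrime)
  if (!is.null(network)) {
    res <- max(abs(.pdeRhs(network, geometry, field)))
    if (res > 1e-4 * sum(Ntot) / geometry$L)
      warning("field far from steady state; cycle-flux formula invalid transiently")
  }
  attr(W, "J1c") <- J1c
  attr(W, "J2c") <- J2c
  W
}

#' Generalised cycle-form dissipation for any network
#'
#' `Wdot = sum_r log(kf_r/kb_r) * integral(j+_r - j-_r) dx`, the steady-state
#' identity in its network-agnostic form (equals the spatially integrated
#' chemical + diffusive dissipation at steady state).
#'
#' @inheritParams channelFluxes
#' @param geometry an [rdGeometry()].
#' @return `Wdot_total` (k_B T/s).
#' @export
cycleFormDissipation <- function(field, network, geometry) {
  fl <- channelFluxes(field, network)
  kf <- vapply(network$reactions, `[[`, numeric(1), "kf")
  kb <- vapply(network$reactions, `[[`, numeric(1), "kb")
  if (any(kb == 0)) stop("irreversible limit, dissipation undefined")
  sum(log(kf / kb) * rowSums(fl$jplus - fl$jminus) * geometry$dx)
}

#' Full dissipation accounting of a concentration field
#'
#' @inheritParams diffDissipation
#' @param rates the [rateConstants()] when `network` is the three-species
#'   model (enables the cycle-flux total and r_diff bookkeeping); omit for
#'   generic networks.
#' @return object of class `dissipationBreakdown` with densities `w_chem`,
#'   `w_diff` (k_B T s^-1 um^-1), totals `Wdot_chem`, `Wdot_diff`,
#'   `Wdot_total`, cycle fluxes `J1c`, `J2c`, cycle-form total
#'   `Wdot_cycle`, and the diffusion fraction `r_diff`.
#' @export
dissipationBreakdown <- function(field, network, geometry, rates = NULL,
                                 mode = c("discrete", "continuum")) {
  mode <- match.arg(mode)
  wc <- chemDissipation(field, network)
  wd <- diffDissipation(field, network, geometry, mode)
  Wc <- sum(wc) * geometry$dx
  Wd <- sum(wd) * geometry$dx
  J1c <- J2c <- NA_real_
  Wcycle <- cycleFormDissipation(field, network, geometry)
  if (!is.null(rates)) {
    tot <- totalDissipationCycle(field, rates, geometry)
    J1c <- attr(tot, "J1c"); J2c <- attr(tot, "J2c")
  }
  structure(list(w_chem = wc, w_diff = wd,
                 Wdot_chem = Wc, Wdot_diff = Wd, Wdot_total = Wc + Wd,
                 Wdot_cycle = Wcycle, J1c = J1c, J2c = J2c,
                 r_diff = if (Wc + Wd > 0) Wd / (Wc + Wd) else 0,
                 mode = mode),
            class = "dissipationBreakdown")
}

#' @export
print.dissipationBreakdown <- function(x, ...) {
  cat(sprintf("dissipation (%s): chem = %.6g, diff = %.6g, total = %.6g kT/s\n",
              x$mode, x$Wdot_chem, x$Wdot_diff, x$Wdot_total))
  cat(sprintf("  cycle-form total = %.6g kT/s, r_diff = %.4g", x$Wdot_cycle,
              x$r_diff))
  if (is.finite(x$J1c)) cat(sprintf(", J1c = %.4g, J2c = %.4g /s", x$J1c, x$J2c))
  cat("\n")
  invisible(x)
}

#' Closed-form estimate of the diffusive/chemical dissipation ratio
#'
#' Deep in the Turing regime (d, W >> 1) the ratio of diffusive to chemical
#' dissipation is approximately `(2 pi^2 / W) (Delta_u2 / <u2>)^2`, with
#' `Delta_u2 = (u2max - u2min)/2` the pattern amplitude.
#'
#' @param field S x n_box concentration matrix (activator in row 2) or a
#'   numeric activator profile.
#' @param W chemical driving (k_B T per cycle).
#' @return estimated ratio `Wdot_diff / Wdot_chem` (dimensionless).
#' @export
diffusiveFractionEstimate <- function(field, W) {
  u2 <- if (is.matrix(field)) field[2, ] else field
  amp <- (max(u2) - min(u2)) / 2
  2 * pi^2 / W * (amp / mean(u2))^2
}
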