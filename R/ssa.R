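#' Initial lattice state of integer molecule counts
#'
#' Distributes N (weighted) molecules over species and boxes. Species
#' proportions default to the homogeneous fixed point; within each species
#' molecules are spread uniformly across boxes with remainders assigned
#' round-robin so the weighted total is exactly N.
#'
#' @param network an [reactionNetwork()].
#' @param geometry an [rdGeometry()].
#' @param N total weighted molecule number.
#' @param proportions numeric vector of target per-species fractions of the
#'   weighted total; default from the well-mixed steady state.
#' @return integer matrix S x n_box of counts.
#' @export
latticeState <- function(network, geometry, N, proportions = NULL) {
  S <- length(network$species)
  B <- geometry$n_box
  w <- network$weights
  if (is.null(proportions)) {
    us <- .wellMixedSteady(network, N / geometry$L)
    proportions <- us * w / sum(us * w)
  }
  proportions <- proportions / sum(proportions)
  # weighted molecule budget per species, then per box
  counts <- matrix(0L, S, B)
  budget <- N
  for (s in seq_len(S)) {
    ns <- if (s < S) round(N * proportions[s] / w[s]) else budget %/% w[s]
    ns <- max(ns, 0)
    if (ns * w[s] > budget) ns <- budget %/% w[s]
    budget <- budget - ns * w[s]
    base <- ns %/% B
    extra <- ns %% B
    counts[s, ] <- base
    if (extra > 0) {
      idx <- round(seq(1, B, length.out = extra))  # spread the remainder
      counts[s, idx] <- counts[s, idx] + 1L
    }
  }
  if (budget > 0) counts[which(w == min(w))[1], 1] <-
      counts[which(w == min(w))[1], 1] + as.integer(budget %/% min(w))
  storage.mode(counts) <- "integer"
  counts
}

#' Integer lattice state nearest a concentration field
#'
#' Discretises a deterministic concentration field into integer counts
#' (`n = u*dx`), distributing rounding remainders within each species to the
#' boxes with the largest fractional parts so the weighted total is exactly
#' `N`. Used to start stochastic runs from a patterned steady state.
#'
#' @param field S x n_box concentration matrix (um^-1).
#' @param geometry an [rdGeometry()].
#' @param network an [reactionNetwork()] (for the conservation weights).
#' @param N target weighted total; default: the rounded weighted mass of
#'   `field`.
#' @return integer S x n_box count matrix.
#' @export
latticeStateFromField <- function(field, geometry, network, N = NULL) {
  w <- network$weights
  raw <- field * geometry$dx
  counts <- floor(raw)
  if (is.null(N)) N <- round(sum(w * rowSums(raw)))
  # per species, hand out remainders to the largest fractional parts
  for (s in seq_len(nrow(field))) {
    ns <- round(sum(raw[s, ]))
    extra <- ns - sum(counts[s, ])
    if (extra > 0) {
      ord <- order(raw[s, ] - counts[s, ], decreasing = TRUE)
      counts[s, ord[seq_len(extra)]] <- counts[s, ord[seq_len(extra)]] + 1
    }
  }
  # absorb any residual weighted mismatch in the lightest species
  resid <- N - sum(w * rowSums(counts))
  if (resid != 0) {
    s <- which(w == min(w))[1]
    step <- resid %/% w[s]
    counts[s, which.max(counts[s, ])] <-
      counts[s, which.max(counts[s, ])] + step
  }
  storage.mode(counts) <- "integer"
  stopifnot(all(counts >= 0))
  counts
}

#' Event channels and exact propensities of a lattice state
#'
#' Enumerates every reaction channel (per box) and hop channel (per species,
#' box and direction) with its exact chemical-master-equation propensity:
#' mass-action with falling-factorial combinatorics,
#' `a = k dx^(1-m) prod_s n_s (n_s-1) ... (n_s - nu_s + 1)`, and hop rate
#' `D/dx^2` per molecule with end boxes hopping inward only.
#'
#' Reference implementation used for testing; simulation itself runs in
#' compiled code.
#'
#' @param counts integer S x n_box matrix.
#' @param network an [reactionNetwork()].
#' @param geometry an [rdGeometry()].
#' @return data.frame with columns `kind` ("reaction"/"hop"), `box`,
#'   `channel` (reaction name + direction, or species for hops),
#'   `direction`, `propensity` (s^-1).
#' @export
propensities <- function(counts, network, geometry) {
  sm <- .stoichMatrices(network)
  ks <- .kScaled(sm, geometry$dx)
  S <- length(network$species); B <- geometry$n_box
  C <- length(ks)
  rn <- vapply(network$reactions, function(r)
    if (is.null(r$name)) "rxn" else r$name, character(1))
  rows <- list()
  for (b in seq_len(B)) {
    for (cc in seq_len(C)) {
      a <- ks[cc]
      for (s in seq_len(S)) {
        m <- sm$reac[s, cc]
        if (m > 0) a <- a * prod(pmax(counts[s, b] - 0:(m - 1), 0))
      }
      rows[[length(rows) + 1]] <- data.frame(
        kind = "reaction", box = b,
        channel = paste0(rn[ceiling(cc / 2)],
                         if (cc %% 2 == 1) "+" else "-"),
        direction = NA_integer_, propensity = a)
    }
    for (s in seq_len(S)) {
      for (dir in c(-1L, 1L)) {
        if ((b == 1 && dir == -1L) || (b == B && dir == 1L)) next
        rows[[length(rows) + 1]] <- data.frame(
          kind = "hop", box = b, channel = network$species[s],
          direction = dir,
          propensity = network$D[s] / geometry$dx^2 * counts[s, b])
      }
    }
  }
  do.call(rbind, rows)
}

#' Exact stochastic simulation of the lattice reaction-diffusion system
#'
#' Statistically exact Gillespie (direct-method) trajectory of the
#' reaction-diffusion master equation: reactions fire per box with
#' falling-factorial propensities, molecules hop to nearest neighbours at
#' rate D/dx^2, end boxes reflect. The weighted total N is conserved exactly
#' at every event. Randomness comes from R's RNG, so `seed` makes runs
#' bit-reproducible.
#'
#' @param network an [reactionNetwork()].
#' @param geometry an [rdGeometry()].
#' @param init integer S x n_box matrix of initial counts
#'   (see [latticeState()]).
#' @param t_end simulation horizon (s).
#' @param sample_dt snapshot interval (s).
#' @param seed integer seed; required for reproducibility.
#' @param tally_entropy also accumulate the per-event entropy tally
#'   `sum log(a_fwd/a_bwd)` (k_B), the trajectory-level dissipation
#'   estimator; `NA` when any fired channel lacks a reverse.
#' @param max_events abort guard.
#' @return an `rdKymograph` (stochastic; counts stored). Metadata records
#'   the seed, event count and, if requested, entropy tally.
#' @export
runSSA <- function(network, geometry, init, t_end, sample_dt,
                   seed = NULL, tally_entropy = FALSE, max_events = 5e9) {
  stopifnot(t_end > 0, all(init >= 0), is.matrix(init))
  storage.mode(init) <- "integer"
  sm <- .stoichMatrices(network)
  ks <- .kScaled(sm, geometry$dx)
  if (!is.null(seed)) set.seed(seed)
  out <- .ssa_run_cpp(init, network$D / geometry$dx^2,
                      sm$reac, sm$net, ks, sm$partner,
                      0, t_end, sample_dt, max_events, tally_entropy)
  dim(out$counts) <- c(length(network$species), geometry$n_box,
                       length(out$times))
  newKymograph(out$times, out$counts, geometry, network$species,
               stochastic = TRUE,
               meta = list(seed = seed, n_events = out$n_events,
                           entropy = out$entropy, t_final = out$t_final,
                           network = network))
}

#' Ensemble of independent stochastic replicates
#'
#' Replicate i runs with seed `seed_base + i`, so ensembles are
#' deterministic given `seed_base` and order-independent.
#'
#' @inheritParams runSSA
#' @param n_replicates number of independent trajectories.
#' @param seed_base base seed.
#' @return list of `rdKymograph` objects.
#' @export
runEnsemble <- function(network, geometry, init, t_end, sample_dt,
                        n_replicates, seed_base, tally_entropy = FALSE) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(i)
    runSSA(network, geometry, init, t_end, sample_dt,
           seed = seed_base + i, tally_entropy = tally_entropy))
}
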