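#' Reversible reaction network on a 1-D diffusive lattice
#'
#' A generic container for a set of reversible mass-action reactions between
#' named species that also diffuse, used by both the deterministic integrator
#' and the exact stochastic simulator. Every reaction carries a forward and a
#' backward rate constant; thermodynamic bookkeeping (cycle affinities,
#' dissipation) requires strictly positive backward rates.
#'
#' Rate-constant units follow the 1-D concentration convention `u = n/dx`
#' (molecules per micron): a reaction of total reactant order m has rate
#' constant units of s^-1 * um^(m-1), so that the deterministic flux density
#' `k * prod(u^nu)` is in um^-1 s^-1.
#'
#' @param species character vector of species names.
#' @param D numeric vector of diffusion constants (um^2/s), one per species.
#' @param reactions list of reactions, each a list with elements
#'   `name`, `reactants` (named integer vector of stoichiometries),
#'   `products`, `kf`, `kb`, and optionally `hydrolysis` (number of ATP
#'   hydrolysis events per forward firing; used for ATP/ADP scaling).
#' @param weights conservation weights per species (e.g. monomer content);
#'   `sum(weights * n)` must be invariant under every reaction.
#' @return an object of class `rdNetwork`.
#' @export
reactionNetwork <- function(species, D, reactions, weights = rep(1, length(species))) {
  stopifnot(is.character(species), length(species) >= 1,
            length(D) == length(species), all(D > 0),
            length(weights) == length(species))
  S <- length(species)
  for (r in reactions) {
    stopifnot(!is.null(r$reactants), !is.null(r$products),
              is.numeric(r$kf), is.numeric(r$kb), r$kf >= 0, r$kb >= 0)
    if (!all(names(r$reactants) %in% species) ||
        !all(names(r$products) %in% species))
      stop("reaction references unknown species")
  }
  net <- structure(list(species = species, D = D, reactions = reactions,
                        weights = weights), class = "rdNetwork")
  # conservation check: every reaction must preserve the weighted total
  sm <- .stoichMatrices(net)
  bad <- which(abs(as.numeric(weights %*% sm$net)) > 1e-12)
  if (length(bad))
    stop("reactions violate the conservation weighting: ",
         paste(unique(ceiling(bad / 2)), collapse = ", "))
  net
}

#' @export
print.rdNetwork <- function(x, ...) {
  cat("Reaction-diffusion network:", length(x$species), "species,",
      length(x$reactions), "reversible reactions\n")
  cat("  species:", paste(sprintf("%s (D=%g)", x$species, x$D), collapse = ", "),
      "\n")
  for (r in x$reactions) {
    side <- function(v) paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
                              sep = "", collapse = " + ")
    cat(sprintf("  %s: %s <-> %s   kf=%g kb=%g\n",
                if (is.null(r$name)) "rxn" else r$name,
                side(r$reactants), side(r$products), r$kf, r$kb))
  }
  invisible(x)
}

# Expand reversible reactions into directed channels.
# Channel 2j-1 = forward of reaction j, channel 2j = backward.
# Returns reactant-stoich and net-change matrices (S x C), per-channel rate
# constants, channel order, and 0-based partner indices for the C++ engine.
.stoichMatrices <- function(net) {
  S <- length(net$species)
  R <- length(net$reactions)
  C <- 2L * R
  sr <- matrix(0L, S, C)
  sn <- matrix(0L, S, C)
  k <- numeric(C)
  for (j in seq_len(R)) {
    r <- net$reactions[[j]]
    ir <- match(names(r$reactants), net$species)
    ip <- match(names(r$products), net$species)
    f <- 2L * j - 1L; b <- 2L * j
    sr[ir, f] <- as.integer(r$reactants)
    sr[ip, b] <- as.integer(r$products)
    sn[, f] <- -sr[, f]; sn[ip, f] <- sn[ip, f] + as.integer(r$products)
    sn[, b] <- -sn[, f]
    k[f] <- r$kf; k[b] <- r$kb
  }
  order <- colSums(sr)
  # partner of forward channel 2j-1 is 2j and vice versa (0-based for C++)
  partner <- integer(C)
  if (C > 0) {
    partner[seq(1, C, 2)] <- seq(2, C, 2) - 1L
    partner[seq(2, C, 2)] <- seq(1, C, 2) - 1L
  }
  list(reac = sr, net = sn, k = k, order = order, partner = partner)
}

# per-channel propensity rate constants on a lattice of box width dx
.kScaled <- function(sm, dx) sm$k * dx^(1 - sm$order)

#' Simulation geometry: closed 1-D domain of boxes
#'
#' @param L domain length (um).
#' @param n_box number of boxes (>= 3); box width is `dx = L/n_box`.
#' @return object of class `rdGeometry` with fields `L`, `n_box`, `dx`, `x`
#'   (box-centre coordinates) and no-flux boundaries.
#' @export
rdGeometry <- function(L, n_box) {
  stopifnot(L > 0, n_box >= 3, n_box == as.integer(n_box))
  n_box <- as.integer(n_box)
  dx <- L / n_box
  structure(list(L = L, n_box = n_box, dx = dx,
                 x = (seq_len(n_box) - 0.5) * dx, boundary = "no-flux"),
            class = "rdGeometry")
}

#' @export
print.rdGeometry <- function(x, ...) {
  cat(sprintf("1-D no-flux domain: L = %g um, %d boxes (dx = %g um)\n",
              x$L, x$n_box, x$dx))
  invisible(x)
}
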