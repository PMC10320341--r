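#' Kymograph: a time-stamped sequence of concentration fields
#'
#' Internal constructor shared by the deterministic integrator and the
#' stochastic simulator. Stochastic kymographs store integer counts
#' losslessly; concentrations are derived as `u = n/dx` on access.
#'
#' @param times sampling times (s), strictly increasing.
#' @param fields numeric array S x n_box x n_times of concentrations
#'   (um^-1), or integer counts if `stochastic`.
#' @param geometry the [rdGeometry()] of the run.
#' @param species species names.
#' @param stochastic whether `fields` holds integer counts.
#' @param meta list of provenance metadata (parameters, seed, ...).
#' @return object of class `rdKymograph`.
#' @keywords internal
newKymograph <- function(times, fields, geometry, species,
                         stochastic = FALSE, meta = list()) {
  stopifnot(all(diff(times) > 0), dim(fields)[1] == length(species),
            dim(fields)[2] == geometry$n_box, dim(fields)[3] == length(times))
  structure(list(times = times, fields = fields, geometry = geometry,
                 species = species, stochastic = stochastic, meta = meta),
            class = "rdKymograph")
}

#' Concentration field of one species over time
#'
#' @param kym an `rdKymograph`.
#' @param species species index or name.
#' @return matrix n_box x n_times of concentrations (um^-1).
#' @export
speciesField <- function(kym, species = 2) {
  if (is.character(species)) species <- match(species, kym$species)
  f <- kym$fields[species, , , drop = TRUE]
  f <- matrix(f, kym$geometry$n_box, length(kym$times))
  if (kym$stochastic) f <- f / kym$geometry$dx
  f
}

#' Snapshot of all species at one sampled time
#'
#' @param kym an `rdKymograph`.
#' @param i time index (default: last sample).
#' @return matrix S x n_box of concentrations (um^-1).
#' @export
fieldAt <- function(kym, i = length(kym$times)) {
  f <- kym$fields[, , i, drop = TRUE]
  f <- matrix(f, length(kym$species), kym$geometry$n_box)
  if (kym$stochastic) f <- f / kym$geometry$dx
  rownames(f) <- kym$species
  f
}

#' Total mass (weighted molecule number) at each sampled time
#'
#' @param kym an `rdKymograph`.
#' @param weights per-species conservation weights.
#' @return numeric vector over time; for the closed system this is constant.
#' @export
totalMass <- function(kym, weights = rep(1, length(kym$species))) {
  S <- length(kym$species)
  m <- apply(kym$fields, 3, function(f) sum(weights * rowSums(matrix(f, S))))
  if (!kym$stochastic) m <- m * kym$geometry$dx
  m
}

#' Time-averaged concentration field
#'
#' @param kym an `rdKymograph`.
#' @param burnin_frac fraction of initial samples to discard.
#' @return matrix S x n_box of mean concentrations (um^-1).
#' @export
timeAveragedField <- function(kym, burnin_frac = 0.2) {
  nt <- length(kym$times)
  keep <- seq.int(max(1L, floor(burnin_frac * nt) + 1L), nt)
  f <- apply(kym$fields[, , keep, drop = FALSE], c(1, 2), mean)
  if (kym$stochastic) f <- f / kym$geometry$dx
  rownames(f) <- kym$species
  f
}

#' @export
print.rdKymograph <- function(x, ...) {
  cat(sprintf("%s kymograph: %d species x %d boxes x %d samples, t in [%g, %g] s\n",
              if (x$stochastic) "stochastic" else "deterministic",
              length(x$species), x$geometry$n_box, length(x$times),
              x$times[1], x$times[length(x$times)]))
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' Export a kymograph as a tidy table
#'
#' One row per time x box with columns `t` (s), `x` (um) and one
#' concentration column per species (um^-1).
#'
#' @param x an `rdKymograph`.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.rdKymograph <- function(x, ...) {
  nt <- length(x$times)
  B <- x$geometry$n_box
  out <- data.frame(t = rep(x$times, each = B),
                    x = rep(x$geometry$x, nt))
  for (s in seq_along(x$species)) {
    f <- x$fields[s, , ]
    if (x$stochastic) f <- f / x$geometry$dx
    out[[x$species[s]]] <- as.numeric(f)
  }
  out
}
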