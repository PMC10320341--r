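#' Read and validate an experiment configuration
#'
#' Configurations are JSON with explicit units. Either `preset` ("fig3" or
#' "fig4", expanded to the bundled published values, with optional
#' overrides) or explicit `rates`/`diffusion`/`geometry` blocks. Unknown
#' keys are schema errors naming the field.
#'
#' @param path JSON file path.
#' @return an `experimentConfig` list: `rates`, `diffusion`, `geometry`,
#'   `N`, `c_tot`, plus any of `driver`, `sweep`, `n_replicates`,
#'   `seed_base`, `scale`, `t_end`, `sample_dt`.
#' @export
loadConfig <- function(path) {
  stopifnot(file.exists(path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preset", "rates", "diffusion", "geometry", "N", "driver",
             "sweep", "n_replicates", "seed_base", "scale", "t_end",
             "sample_dt", "k12", "W", "units", "atp_adp", "target_stripes")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$units)) {
    expect <- c(rates = "s^-1 (autocatalytic: s^-1 um^2)",
                diffusion = "um^2/s", length = "um")
    mism <- names(cfg$units)[unlist(cfg$units) != expect[names(cfg$units)]]
    if (length(mism)) stop("unit mismatch in field(s): ",
                           paste(mism, collapse = ", "))
  }
  if (!is.null(cfg$preset)) {
    base <- presetConfig(cfg$preset,
                         k12 = if (is.null(cfg$k12)) 0.5 else cfg$k12,
                         W = if (is.null(cfg$W)) 3.21 else cfg$W)
    out <- base
  } else {
    r <- cfg$rates
    need <- c("k12", "k21", "k23", "k32", "k31", "k13", "kt12", "kt21")
    miss <- setdiff(need, names(r))
    if (length(miss)) stop("rates block missing field(s): ",
                           paste(miss, collapse = ", "))
    out <- list(name = "custom",
                rates = do.call(rateConstants, as.list(r[need])),
                diffusion = diffusionConstants(cfg$diffusion$D1,
                                               cfg$diffusion$D2,
                                               if (is.null(cfg$diffusion$D3))
                                                 cfg$diffusion$D1
                                               else cfg$diffusion$D3),
                geometry = rdGeometry(cfg$geometry$L, cfg$geometry$n_box),
                N = cfg$N)
    out$c_tot <- out$N / out$geometry$L
  }
  if (!is.null(cfg$N)) { out$N <- cfg$N; out$c_tot <- cfg$N / out$geometry$L }
  for (f in c("driver", "sweep", "n_replicates", "seed_base", "scale",
              "t_end", "sample_dt", "atp_adp", "target_stripes"))
    out[[f]] <- cfg[[f]]
  class(out) <- "experimentConfig"
  out
}

#' Serialise an experiment configuration to JSON
#'
#' Round-trips with [loadConfig()]: explicit parameter blocks with a units
#' stanza are written, never the preset shorthand, so what was run is what
#' is recorded.
#'
#' @param config an `experimentConfig` (or the list returned by
#'   [presetConfig()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  r <- config$rates
  out <- list(
    rates = r[c("k12", "k21", "k23", "k32", "k31", "k13", "kt12", "kt21")],
    diffusion = list(D1 = config$diffusion$D1, D2 = config$diffusion$D2,
                     D3 = config$diffusion$D3),
    geometry = list(L = config$geometry$L, n_box = config$geometry$n_box),
    N = config$N,
    units = list(rates = "s^-1 (autocatalytic: s^-1 um^2)",
                 diffusion = "um^2/s", length = "um"))
  for (f in c("driver", "sweep", "n_replicates", "seed_base", "scale",
              "t_end", "sample_dt", "atp_adp", "target_stripes"))
    if (!is.null(config[[f]])) out[[f]] <- config[[f]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a kymograph as a delimited text table
#'
#' Tab-separated, one row per time x box, with a `#`-prefixed header block
#' stating the units of every column; readable back by
#' [readKymographTable()].
#'
#' @param kym an `rdKymograph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKymographTable <- function(kym, path) {
  df <- as.data.frame(kym)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# kymograph export",
               sprintf("# L_um=%g n_box=%d dx_um=%g stochastic=%s",
                       kym$geometry$L, kym$geometry$n_box, kym$geometry$dx,
                       kym$stochastic),
               if (!is.null(kym$meta$seed)) sprintf("# seed=%d", kym$meta$seed),
               "# columns: t [s], x [um], concentrations [um^-1]"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kymograph table written by [writeKymographTable()]
#'
#' @param path file path.
#' @return an `rdKymograph` (concentrations; count information is not
#'   reconstructed).
#' @export
readKymographTable <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  gl <- regmatches(hdr[2], regexec(
    "L_um=([0-9.eE+-]+) n_box=([0-9]+)", hdr[2]))[[1]]
  geometry <- rdGeometry(as.numeric(gl[2]), as.integer(gl[3]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  times <- sort(unique(df$t))
  species <- setdiff(names(df), c("t", "x"))
  f <- array(0, c(length(species), geometry$n_box, length(times)))
  df <- df[order(df$t, df$x), ]
  for (s in seq_along(species))
    f[s, , ] <- matrix(df[[species[s]]], geometry$n_box, length(times))
  newKymograph(times, f, geometry, species, stochastic = FALSE,
               meta = list(source = path))
}

#' Run a configured experiment driver
#'
#' Dispatches on `config$driver`:
#' * `"dissipation"`: deterministic patterned steady state of the configured
#'   set, full dissipation breakdown.
#' * `"error_energy"`: stochastic sweep over `sweep$k12` x `sweep$kt21`
#'   (the latter as fractions of the finite-system critical rate `ktc` of
#'   each `k12`), emitting per-point `(dW, sigma)` rows consumable by
#'   [fitErrorEnergy()].
#' * `"n_scan"`: [scanSigmaVsN()] over `sweep$N`.
#' * `"muk_sigma"` / `"muk_nmax"`: the Muk scans over `sweep$atp_adp`.
#'
#' Every run is fully determined by the config plus `seed_base`; outputs
#' carry the config as an attribute (and are written alongside a config
#' copy when `out_dir` is given). A `scale` factor < 1 shortens horizons
#' and replicate counts uniformly and is recorded in the metadata.
#'
#' @param config an `experimentConfig` from [loadConfig()].
#' @param out_dir optional output directory for tables + provenance.
#' @return driver-specific result with attributes `config` and `scale`.
#' @export
runExperiment <- function(config, out_dir = NULL) {
  driver <- if (is.null(config$driver)) "dissipation" else config$driver
  scale <- if (is.null(config$scale)) 1 else config$scale
  seed_base <- if (is.null(config$seed_base)) 1 else config$seed_base
  n_rep <- max(1L, as.integer(ceiling(
    (if (is.null(config$n_replicates)) 3 else config$n_replicates) * scale)))
  t_end <- (if (is.null(config$t_end)) 400 else config$t_end) * scale
  sample_dt <- if (is.null(config$sample_dt)) 1 else config$sample_dt
  res <- switch(
    driver,
    dissipation = {
      net <- threeSpeciesNetwork(config$rates, config$diffusion)
      u <- patternedSteadyState(net, config$geometry, config$c_tot,
                                n_stripes = if (is.null(config$target_stripes))
                                  3 else config$target_stripes,
                                t_relax = 300)
      dissipationBreakdown(u, net, config$geometry, rates = config$rates)
    },
    error_energy = {
      rows <- list()
      for (k12 in config$sweep$k12) {
        pr <- presetConfig("fig3", k12 = k12)
        cs <- onsetKtcFinite(pr$rates, pr$diffusion, pr$c_tot, pr$geometry,
                             n = 3)
        for (kt21 in config$sweep$kt21 * cs$ktc) {
          r <- pr$rates; r$kt21 <- kt21
          W <- -log(computeThermo(r)$Gamma)
          net <- threeSpeciesNetwork(r, pr$diffusion)
          init <- latticeState(net, pr$geometry, pr$N)
          sig <- vapply(seq_len(n_rep), function(i) {
            kym <- runSSA(net, pr$geometry, init, t_end, sample_dt,
                          seed = seed_base + i +
                            round(1e4 * k12 + 1e7 * kt21 / cs$ktc))
            tryCatch(trackPeak(kym, target_stripes = 3)$sigma,
                     error = function(e) NA_real_)
          }, numeric(1))
          rows[[length(rows) + 1]] <- data.frame(
            k12 = k12, kt21 = kt21, W = W, Wc = cs$Wc, dW = W - cs$Wc,
            sigma = mean(sig, na.rm = TRUE), n_ok = sum(is.finite(sig)))
        }
      }
      do.call(rbind, rows)
    },
    n_scan = scanSigmaVsN(config$rates, config$diffusion, config$geometry,
                          N_grid = config$sweep$N, t_end = t_end,
                          sample_dt = sample_dt, n_replicates = n_rep,
                          seed_base = seed_base),
    muk_sigma = mukSigmaScan(config$sweep$atp_adp, config$N,
                             config$geometry, t_end, sample_dt,
                             n_replicates = n_rep, seed_base = seed_base),
    muk_nmax = mukNmaxScan(config$sweep$atp_adp, config$sweep$N,
                           config$geometry, t_end, sample_dt,
                           n_replicates = n_rep, seed_base = seed_base),
    stop("unknown driver: ", driver))
  attr(res, "config") <- config
  attr(res, "scale") <- scale
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeConfig(config, file.path(out_dir, "config.json"))
    if (is.data.frame(res))
      utils::write.table(res, file.path(out_dir, paste0(driver, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}
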