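# Shared fixtures, built in code and cached lazily for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fig3 <- function() fixture("fig3", function() presetConfig("fig3"))
fig4 <- function() fixture("fig4", function() presetConfig("fig4"))

fig3_network <- function() fixture("fig3_net", function() {
  pr <- fig3()
  threeSpeciesNetwork(pr$rates, pr$diffusion)
})

fig4_network <- function() fixture("fig4_net", function() {
  pr <- fig4()
  threeSpeciesNetwork(pr$rates, pr$diffusion)
})

# an exactly equilibrated rate set (Gamma = Gamma' = 1, nontrivial rates)
equilibrium_rates <- function() fixture("eq_rates", function() {
  k12 <- 0.8; k21 <- 1.6; k23 <- 0.4; k31 <- 0.9
  kt12 <- 2e-4
  # Gamma = 1: kt21 = kt12 k21 / k12 ; Gamma' = 1: k32 = k12 k23 k31 / (k13 k21)
  k13 <- 0.5
  rateConstants(k12 = k12, k21 = k21, k23 = k23,
                k32 = k12 * k23 * k31 / (k13 * k21),
                k31 = k31, k13 = k13,
                kt12 = kt12, kt21 = kt12 * k21 / k12)
})

# deterministic three-stripe steady states (expensive; built once)
fig4_steady <- function() fixture("fig4_steady", function() {
  pr <- fig4()
  patternedSteadyState(fig4_network(), pr$geometry, pr$c_tot, 3,
                       t_relax = 300)
})

fig3_steady <- function() fixture("fig3_steady", function() {
  pr <- fig3()
  patternedSteadyState(fig3_network(), pr$geometry, pr$c_tot, 3,
                       t_relax = 300)
})

fig3_onset <- function() fixture("fig3_onset", function() {
  pr <- fig3()
  onsetKtcFinite(pr$rates, pr$diffusion, pr$c_tot, pr$geometry, 3)
})

small_geometry <- function() rdGeometry(6, 6)
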