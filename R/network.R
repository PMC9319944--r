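#' Species tracked by the Fenton-like reaction network
#'
#' Identifiers used throughout the package for the copper/peroxide reaction
#' system: `Cu2` (Cu2+), `Cu1` (Cu+), `Cu3` (Cu3+), `H2O2`, `OH` (hydroxyl
#' radical), `O2m` (superoxide O2.-), `HO2` (hydroperoxyl radical), `O2`
#' (molecular oxygen), `OHm` (hydroxide), `Hp` (H+), `TH` (terephthalate
#' dianion, the hydroxyl-radical trap) and `HTA` (hydroxyterephthalate, the
#' fluorescent trap product).
#'
#' @return Character vector of the twelve species identifiers, in canonical
#'   order.
#' @export
fenton_species <- function() {
  c("Cu2", "Cu1", "Cu3", "H2O2", "OH", "O2m", "HO2", "O2", "OHm", "Hp",
    "TH", "HTA")
}

#' Rate constants of the Fenton-like network
#'
#' Second-order rate constants (M^-1 s^-1) for the eight elementary steps of
#' the copper-catalysed peroxide decomposition model:
#'
#' * `k1`: Cu2+ + H2O2 -> Cu3+ + OH. + OH-
#' * `k2`: Cu2+ + H2O2 -> Cu+ + O2.- + 2 H+
#' * `k3`: Cu2+ + O2.- -> Cu+ + O2
#' * `k4`: OH. + H2O2 -> HO2. + H2O
#' * `k5`: HO2. + HO2. -> H2O2 + O2
#' * `k6`: OH. + OH. -> H2O2
#' * `k7`: Cu+ + H2O2 -> Cu2+ + OH. + OH-  (re-oxidation closing the
#'   catalytic cycle)
#' * `k_trap`: OH. + TH2- -> HTA  (terephthalate dosimeter trap)
#'
#' The packaged defaults are *effective* constants: no literature values exist
#' for this specific system at these conditions, so they were tuned once (see
#' `data-raw/tune-rate-constants.R`) such that the default scenario
#' (1 mM Cu2+, 10 mM H2O2, 100 mM terephthalate, 20 min) reproduces the
#' headline observables of the experiment: a 0.2 mM decrease in Cu2+,
#' 0.9 uM of trapped hydroxyl radical, and 14 mg/L of liberated dissolved
#' oxygen. They are deliberately scaled so the system is integrable with an
#' explicit stepper; they are not radiolysis literature constants.
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k_trap Non-negative rate constants
#'   (M^-1 s^-1).
#' @return A named numeric vector of class `rate_constants`.
#' @export
#' @examples
#' rate_constants()
#' rate_constants(k_trap = 0) # disable the dosimeter trap
rate_constants <- function(k1 = 1.4340756279e-2,
                           k2 = 2.0702481680e-2,
                           k3 = 1e6,
                           k4 = 1e4,
                           k5 = 1e6,
                           k6 = 1e9,
                           k7 = 0.6,
                           k_trap = 1.8598151780) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
         k_trap = k_trap)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0))
    abort("all rate constants must be finite and >= 0.")
  structure(k, class = "rate_constants")
}

# Oxidation-state-weighted copper content used by the conservation checks.
copper_weights <- function() {
  w <- setNames(numeric(length(fenton_species())), fenton_species())
  w[c("Cu2", "Cu1", "Cu3")] <- 1
  w
}

#' Mass-action reaction network for the Cu(II)/H2O2 system
#'
#' Assembles the stoichiometry and reactant-order matrices of the eight-step
#' network described under [rate_constants()]. Every reaction conserves total
#' copper (Cu2+ + Cu+ + Cu3+); the constructor verifies this.
#'
#' @param rates A [rate_constants()] vector.
#' @return A tibble with one row per reaction (`reaction`, `label`, `k`) and
#'   attributes `stoich` and `orders`, both species x reaction matrices in
#'   [fenton_species()] order, of class `reaction_network`.
#' @export
reaction_network <- function(rates = rate_constants()) {
  if (!inherits(rates, "rate_constants")) rates <- do.call(rate_constants, as.list(rates))
  sp <- fenton_species()
  rx <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "Rtrap")
  labels <- c(
    R1 = "Cu2+ + H2O2 -> Cu3+ + OH. + OH-",
    R2 = "Cu2+ + H2O2 -> Cu+ + O2.- + 2H+",
    R3 = "Cu2+ + O2.- -> Cu+ + O2",
    R4 = "OH. + H2O2 -> HO2. + H2O",
    R5 = "HO2. + HO2. -> H2O2 + O2",
    R6 = "OH. + OH. -> H2O2",
    R7 = "Cu+ + H2O2 -> Cu2+ + OH. + OH-",
    Rtrap = "OH. + TH2- -> HTA"
  )
  S <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  O <- matrix(0L, length(sp), length(rx), dimnames = list(sp, rx))

  S[c("Cu2", "H2O2"), "R1"] <- -1; S[c("Cu3", "OH", "OHm"), "R1"] <- 1
  O[c("Cu2", "H2O2"), "R1"] <- 1L
  S[c("Cu2", "H2O2"), "R2"] <- -1; S[c("Cu1", "O2m"), "R2"] <- 1
  S["Hp", "R2"] <- 2
  O[c("Cu2", "H2O2"), "R2"] <- 1L
  S[c("Cu2", "O2m"), "R3"] <- -1; S[c("Cu1", "O2"), "R3"] <- 1
  O[c("Cu2", "O2m"), "R3"] <- 1L
  S[c("OH", "H2O2"), "R4"] <- -1; S["HO2", "R4"] <- 1
  O[c("OH", "H2O2"), "R4"] <- 1L
  S["HO2", "R5"] <- -2; S[c("H2O2", "O2"), "R5"] <- 1
  O["HO2", "R5"] <- 2L
  S["OH", "R6"] <- -2; S["H2O2", "R6"] <- 1
  O["OH", "R6"] <- 2L
  S[c("Cu1", "H2O2"), "R7"] <- -1; S[c("Cu2", "OH", "OHm"), "R7"] <- 1
  O[c("Cu1", "H2O2"), "R7"] <- 1L
  S[c("OH", "TH"), "Rtrap"] <- -1; S["HTA", "Rtrap"] <- 1
  O[c("OH", "TH"), "Rtrap"] <- 1L

  cu_balance <- drop(copper_weights() %*% S)
  if (any(abs(cu_balance) > 0))
    abort("internal error: a reaction does not balance copper atoms.")
  if (any(S != round(S)))
    abort("internal error: non-integer stoichiometric coefficient.")

  out <- tibble::tibble(reaction = rx, label = unname(labels[rx]),
                        k = as.numeric(rates))
  structure(out, stoich = S, orders = O, rates = rates,
            class = c("reaction_network", class(out)))
}
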