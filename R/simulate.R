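#' Initial concentrations for the default reaction scenario
#'
#' The default matches the benchtop experiment: 1 mM CuSO4, 10 mM H2O2 and
#' 100 mM disodium terephthalate in water at the moment the peroxide is added.
#'
#' @param cu2,h2o2,th Initial molar concentrations of Cu2+, H2O2 and
#'   terephthalate.
#' @param ... Further named species concentrations (see [fenton_species()]).
#' @return Named numeric vector over all twelve species (unspecified species
#'   start at zero).
#' @export
initial_state <- function(cu2 = 1e-3, h2o2 = 1e-2, th = 0.1, ...) {
  extra <- c(...)
  y0 <- setNames(numeric(length(fenton_species())), fenton_species())
  y0["Cu2"] <- cu2; y0["H2O2"] <- h2o2; y0["TH"] <- th
  if (length(extra)) {
    bad <- setdiff(names(extra), fenton_species())
    if (length(bad)) abort(paste0("unknown species: ", toString(bad)))
    y0[names(extra)] <- extra
  }
  if (any(y0 < 0)) abort("initial concentrations must be >= 0.")
  y0
}

#' Simulate the Cu(II)/H2O2 reaction kinetics
#'
#' Integrates the mass-action ODE system of the Fenton-like network on a
#' user-supplied time grid. The default method is an adaptive embedded
#' Runge-Kutta 4(5) (Cash-Karp) stepper with mixed absolute/relative error
#' control; `method = "fixed"` uses a classic fixed-step RK4 and serves as an
#' independent cross-check of the adaptive path.
#'
#' @param initial Named numeric vector of initial molar concentrations
#'   (see [initial_state()]); species not named start at zero.
#' @param rates A [rate_constants()] vector.
#' @param t_grid Strictly increasing time grid in seconds; the first element
#'   is the initial time.
#' @param method `"adaptive"` (default) or `"fixed"`.
#' @param rtol,atol Relative / absolute error tolerances of the adaptive
#'   stepper.
#' @param dt Step size in seconds for `method = "fixed"`.
#' @param max_steps Safety cap on adaptive steps; exceeding it is an explicit
#'   error, never a silent NaN.
#' @return A `kinetic_trajectory`: a tibble with `time_s` plus one column per
#'   species (molar), carrying the rates and method as attributes.
#' @export
#' @examples
#' traj <- simulate_kinetics(t_grid = seq(0, 1200, by = 60))
#' traj[nrow(traj), c("time_s", "Cu2", "O2", "HTA")]
simulate_kinetics <- function(initial = initial_state(),
                              rates = rate_constants(),
                              t_grid = seq(0, 1200, by = 5),
                              method = c("adaptive", "fixed"),
                              rtol = 1e-8, atol = 1e-16,
                              dt = 1e-3, max_steps = 5e7) {
  method <- match.arg(method)
  net <- reaction_network(rates)
  sp <- fenton_species()

  if (is.null(names(initial))) {
    if (length(initial) != length(sp))
      abort("`initial` must be named or have one entry per species.")
    names(initial) <- sp
  }
  y0 <- initial_state(cu2 = 0, h2o2 = 0, th = 0)
  bad <- setdiff(names(initial), sp)
  if (length(bad)) abort(paste0("unknown species in `initial`: ", toString(bad)))
  y0[names(initial)] <- initial
  if (any(!is.finite(y0)) || any(y0 < 0))
    abort("initial concentrations must be finite and >= 0.")
  check_increasing(t_grid, "t_grid")

  S <- attr(net, "stoich"); O <- attr(net, "orders")
  conc <- if (method == "adaptive") {
    .cpp_integrate_adaptive(y0, S, O, net$k, as.numeric(t_grid), rtol, atol,
                            max_steps)
  } else {
    check_number(dt, "dt", positive = TRUE)
    .cpp_integrate_rk4(y0, S, O, net$k, as.numeric(t_grid), dt)
  }
  colnames(conc) <- sp
  out <- tibble::as_tibble(as.data.frame(conc))
  out <- tibble::add_column(out, time_s = as.numeric(t_grid), .before = 1)
  structure(out, rates = attr(net, "rates"), method = method,
            class = c("kinetic_trajectory", class(out)))
}

#' Total copper across oxidation states
#'
#' @param traj A `kinetic_trajectory`.
#' @return Numeric vector, one value per time point (molar).
#' @export
total_copper <- function(traj) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  traj$Cu2 + traj$Cu1 + traj$Cu3
}

#' @export
tidy.kinetic_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time_s",
                      names_to = "species", values_to = "concentration_M")
}

#' Interpolate a species concentration at arbitrary times
#'
#' Linear interpolation on the stored grid; times outside the grid are an
#' error.
#' @param traj A `kinetic_trajectory`.
#' @param species One species identifier.
#' @param time_s Times (seconds) at which to evaluate.
#' @return Numeric vector of molar concentrations.
#' @export
concentration_at <- function(traj, species, time_s) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  if (!species %in% fenton_species()) abort(paste0("unknown species: ", species))
  rng <- range(traj$time_s)
  if (any(time_s < rng[1] - 1e-9) || any(time_s > rng[2] + 1e-9))
    abort("requested times fall outside the trajectory grid.")
  approx(traj$time_s, traj[[species]], xout = pmin(pmax(time_s, rng[1]), rng[2]))$y
}
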