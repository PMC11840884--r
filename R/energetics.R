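#' Energy budget of a dispersal event
#'
#' The budget splits the fat reserve `E0` into the energy available for
#' transit, `E_alpha = (1 - lambda) * E0`, and the residual fraction
#' `lambda` that must remain on arrival for the animal to survive and
#' settle. The default `lambda = 0.1` reserves 10% of storage.
#'
#' @inheritParams allometry
#' @param lambda residual energy fraction in `[0, 1]`.
#' @return list of class `energy_budget` with elements `E0`, `lambda`,
#'   `E_available` (all energies in J).
#' @examples
#' energy_budget(animal_profile(2, "fish"))
#' @export
energy_budget <- function(animal, lambda = 0.1, params = dispersal_params()) {
  .check_lambda(lambda)
  E0 <- energy_storage(animal, params)
  structure(list(E0 = E0, lambda = lambda,
                 E_available = (1 - lambda) * E0),
            class = "energy_budget")
}

.check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single number in [0, 1]")
  invisible(lambda)
}

.check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta > 1)
    stop("'beta' must be a single number in [0, 1]")
  invisible(beta)
}

#' Energetic cost of dispersing a given distance
#'
#' Dispersal is modelled as straight-line travel at the sustained speed
#' `v`: travel time `t1 = D / v`, cost `Ec = FMRdis * t1`, remaining
#' storage `Er = E0 - Ec`. Cost is exactly linear in distance. Distances
#' beyond the physiological maximum are not an error: the outcome then
#' reports `Er < 0` (and `E_available - Ec < 0`) with `feasible = FALSE`,
#' because the network layer clamps those links to zero itself.
#'
#' @inheritParams energy_budget
#' @param distance dispersal distance in m; non-negative, vectorized.
#' @return a `data.frame` (class `dispersal_outcome`) with one row per
#'   distance (recycled against body mass): `distance` (m), `travel_time`
#'   (s), `energy_cost` (J), `energy_remaining` (J), `feasible` (is
#'   `distance <= ` the maximum given `lambda`).
#' @examples
#' fox <- animal_profile(4.5, "mammal")
#' energy_cost(fox, 1e5)     # 100 km costs ~5.9e6 J
#' @export
energy_cost <- function(animal, distance, lambda = 0.1,
                        params = dispersal_params()) {
  .check_lambda(lambda)
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0))
    stop("'distance' must be finite and >= 0 m")
  v <- travel_speed(animal, params)
  fmr <- field_metabolic_rate(animal, params)
  E0 <- energy_storage(animal, params)
  t1 <- distance / v
  Ec <- fmr * t1
  dmax <- v * (1 - lambda) * E0 / fmr
  out <- data.frame(distance = distance, travel_time = t1, energy_cost = Ec,
                    energy_remaining = E0 - Ec, feasible = distance <= dmax)
  class(out) <- c("dispersal_outcome", "data.frame")
  out
}

#' Energetic cost per metre travelled
#'
#' The distance-independent marginal cost `FMRdis / v` in J/m: the slope of
#' the linear energy depletion. Larger animals pay more joules per metre in
#' absolute terms, but fewer relative to their (disproportionately larger)
#' reserves.
#'
#' @inheritParams allometry
#' @return cost in J/m, one element per body mass.
#' @examples
#' cost_per_metre(animal_profile(4.5, "mammal"))    # ~58.9 J/m
#' cost_per_metre(animal_profile(4000, "mammal"))   # ~5395 J/m
#' @export
cost_per_metre <- function(animal, params = dispersal_params()) {
  field_metabolic_rate(animal, params) / travel_speed(animal, params)
}

#' Relative energy depletion over a distance
#'
#' The cost of a journey expressed as a fraction of the *available* energy
#' `E_alpha = (1 - lambda) * E0`: it rises linearly with distance and
#' reaches exactly 1 at the physiological maximum dispersal distance.
#'
#' @inheritParams energy_cost
#' @return fraction `Ec / E_alpha` (can exceed 1 beyond the maximum).
#' @examples
#' # a 4000 kg running mammal spends ~7% of its available energy on 100 km
#' relative_depletion(animal_profile(4000, "mammal"), 1e5)
#' @export
relative_depletion <- function(animal, distance, lambda = 0.1,
                               params = dispersal_params()) {
  .check_lambda(lambda)
  if (lambda == 1)
    stop("lambda = 1 leaves no available energy; relative depletion ",
         "is undefined")
  Ea <- (1 - lambda) * energy_storage(animal, params)
  energy_cost(animal, distance, lambda, params)$energy_cost / Ea
}

#' Physiological maximum dispersal distance
#'
#' The distance at which the available energy is exhausted: travelling at
#' speed `v`, the animal can sustain its dispersal field metabolic rate for
#' `t2 = E_alpha / FMRdis` seconds, giving `Dmax = v * t2`.
#' `max_dispersal_distance_resting()` extends this with a resting fraction
#' `beta` of the time budget: resting burns BMR but covers no distance, so
#' `t3 = E_alpha / ((1-beta)*FMRdis + beta*BMR)` and
#' `Dmax_beta = (1-beta) * v * t3`. `beta = 0` reproduces the non-resting
#' result exactly; `beta = 1` gives zero distance.
#'
#' @inheritParams energy_budget
#' @param beta fraction of the time budget spent resting, in `[0, 1]`.
#' @return list of class `max_dispersal`: `d_max` (m), `depletion_time`
#'   (s; `t2`, or `t3` when resting), `speed` (m/s), `resting_fraction`,
#'   `lambda`, `available_energy` (J). Elements are vectors when
#'   `animal$body_mass` is.
#' @examples
#' max_dispersal_distance(animal_profile(8.44, "bird"))$d_max / 1000  # km
#' max_dispersal_distance_resting(animal_profile(2, "fish"), beta = 0.5)
#' @export
max_dispersal_distance <- function(animal, lambda = 0.1,
                                   params = dispersal_params()) {
  max_dispersal_distance_resting(animal, lambda, beta = 0, params)
}

#' @rdname max_dispersal_distance
#' @export
max_dispersal_distance_resting <- function(animal, lambda = 0.1, beta,
                                           params = dispersal_params()) {
  .check_lambda(lambda); .check_beta(beta)
  v <- travel_speed(animal, params)
  fmr <- field_metabolic_rate(animal, params)
  bmr <- basal_metabolic_rate(animal, params)
  Ea <- (1 - lambda) * energy_storage(animal, params)
  t3 <- Ea / ((1 - beta) * fmr + beta * bmr)
  structure(list(d_max = (1 - beta) * v * t3, depletion_time = t3,
                 speed = v, resting_fraction = beta, lambda = lambda,
                 available_energy = Ea),
            class = "max_dispersal")
}

#' @export
print.max_dispersal <- function(x, ...) {
  cat(sprintf(
    "Maximum dispersal distance (lambda = %g, resting fraction = %g)\n",
    x$lambda, x$resting_fraction))
  show <- data.frame(d_max_km = x$d_max / 1000, speed_m_s = x$speed,
                     depletion_time_d = x$depletion_time / 86400)
  print(utils::head(show, 10), row.names = FALSE)
  if (nrow(show) > 10) cat("  ...", nrow(show), "masses\n")
  invisible(x)
}

#' Sensitivity of the maximum distance to the residual threshold
#'
#' Because the maximum distance is linear in the available energy,
#' `Dmax(lambda) = (1 - lambda) * Dmax(0)` exactly; the sweep makes that
#' dependence explicit for a grid of residual fractions.
#'
#' @inheritParams energy_budget
#' @param lambda_grid numeric vector of residual fractions in `[0, 1]`.
#' @return `data.frame` with columns `lambda`, `d_max_m`, `d_max_km`.
#' @examples
#' lambda_sweep(animal_profile(0.5, "bird"), c(0, 0.1, 0.5, 1))
#' @export
lambda_sweep <- function(animal, lambda_grid = seq(0, 0.9, by = 0.1),
                         params = dispersal_params()) {
  if (length(lambda_grid) == 0)
    stop("'lambda_grid' must contain at least one value")
  if (any(!is.finite(lambda_grid)) || any(lambda_grid < 0 | lambda_grid > 1))
    stop("'lambda_grid' values must lie in [0, 1]")
  if (length(animal$body_mass) != 1L)
    stop("lambda_sweep() expects a single body mass")
  d <- vapply(lambda_grid, function(l)
    max_dispersal_distance(animal, l, params)$d_max, numeric(1))
  data.frame(lambda = lambda_grid, d_max_m = d, d_max_km = d / 1000)
}
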