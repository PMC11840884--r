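#' Allometric building blocks of the dispersal energy budget
#'
#' Four trait-driven quantities feed the energy budget, each a function of
#' body mass `M` (kg) with group- or mode-specific parameters:
#'
#' * `energy_storage()` -- total mobilisable fat reserve `E0 = a * M^b` in J.
#' * `basal_metabolic_rate()` -- maintenance power `BMR = a * M^b` in J/s.
#' * `travel_speed()` -- sustained travel speed `v` in m/s (see Details).
#' * `locomotion_cost()` -- power needed to move at speed `v` (`LCOT`, J/s).
#' * `field_metabolic_rate()` -- total power draw while dispersing,
#'   `FMRdis = postural * BMR + LCOT(v)`, in J/s.
#'
#' @details
#' Travel speed comes from a general locomotion model balancing the
#' animal's energy-utilisation capacity against its heat-dissipation
#' capacity. The shipped `"harmonic"` form adds the two time costs per
#' metre:
#' \deqn{1/v = 1/(v_0 M^c) + k M^d}
#' i.e. `v = v0*M^c / (1 + k*v0*M^(c+d))`. Speed therefore rises roughly as
#' `M^c` in small animals and falls as `M^-d` in very large ones, where
#' shedding metabolic heat limits sustained speed. Alternative algebraic
#' forms (`"saturating_d"`: `v0*M^c/(1+k*M^d)`, `"saturating_cd"`:
#' `v0*M^c/(1+k*M^(c+d))`, `"power"`: `v0*M^c`) remain available through
#' `dispersal_params(speed_parse = ...)`; [resolve_parse()] documents why
#' the harmonic form is the default.
#'
#' Locomotion cost is mode specific: U-shaped in speed for flight (an
#' induced-power term falling as `1/v` plus profile/parasite-power terms
#' rising as `v^2.5`), linear in speed for running, and exponential in
#' speed for swimming with a mass-proportional baseline.
#'
#' @param animal an [animal_profile()].
#' @param params a [dispersal_params()] set.
#' @param v speed in m/s (strictly positive) for `locomotion_cost()`;
#'   `field_metabolic_rate()` evaluates it at `travel_speed(animal)`.
#' @return numeric vector, one element per body mass in `animal`; units as
#'   listed above.
#' @examples
#' mouse <- animal_profile(0.02, "mammal")
#' energy_storage(mouse)          # J of fat reserve
#' basal_metabolic_rate(mouse)    # J/s at rest
#' travel_speed(mouse)            # m/s sustained
#' field_metabolic_rate(mouse)    # J/s while dispersing
#' @name allometry
NULL

.group_coef <- function(params, group, which) {
  idx <- switch(group, bird = 1L, mammal = 2L, fish = 3L,
                stop("unsupported taxonomic group: ", group))
  if (which == "storage")
    c(a = params[[paste0("a", idx)]], b = params[[paste0("b", idx)]])
  else
    c(a = params[[paste0("a", idx + 3L)]], b = params[[paste0("b", idx + 3L)]])
}

#' @rdname allometry
#' @export
energy_storage <- function(animal, params = dispersal_params()) {
  .check_animal(animal); validate_params(params)
  ab <- .group_coef(params, animal$group, "storage")
  unname(ab["a"] * animal$body_mass^ab["b"])
}

#' @rdname allometry
#' @export
basal_metabolic_rate <- function(animal, params = dispersal_params()) {
  .check_animal(animal); validate_params(params)
  ab <- .group_coef(params, animal$group, "bmr")
  unname(ab["a"] * animal$body_mass^ab["b"])
}

#' @rdname allometry
#' @export
travel_speed <- function(animal, params = dispersal_params()) {
  .check_animal(animal); validate_params(params)
  M <- animal$body_mass
  v0 <- switch(animal$mode, flying = params$v0_fly, running = params$v0_run,
               swimming = params$v0_swim)
  vmax <- v0 * M^params$c
  switch(params$speed_parse,
    harmonic      = 1 / (1 / vmax + params$k * M^params$d),
    saturating_d  = vmax / (1 + params$k * M^params$d),
    saturating_cd = vmax / (1 + params$k * M^(params$c + params$d)),
    power         = vmax,
    stop("configuration error: unresolved travel-speed parse '",
         params$speed_parse, "'"))
}

#' @rdname allometry
#' @export
locomotion_cost <- function(animal, v, params = dispersal_params()) {
  .check_animal(animal); validate_params(params)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
    stop("speed 'v' must be finite and > 0 m/s")
  M <- animal$body_mass
  switch(animal$mode,
    flying = params$a7 * M^params$b7 * v^params$b8 +
             params$a8 * M^params$b7 * v^params$b9 +
             params$a9 * M^params$b10 * v^params$b9,
    running = params$a10 * M^params$b11 * v,
    swimming = params$a11 * M^params$b13 *
               exp(params$a12 * M^params$b12 * v),
    stop("unsupported locomotion mode: ", animal$mode))
}

.postural <- function(mode, params) {
  switch(mode, flying = params$a13, running = params$a14, swimming = 1)
}

#' @rdname allometry
#' @export
field_metabolic_rate <- function(animal, params = dispersal_params()) {
  v <- travel_speed(animal, params)
  .postural(animal$mode, params) * basal_metabolic_rate(animal, params) +
    locomotion_cost(animal, v, params)
}
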