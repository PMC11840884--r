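#' Define the animal whose dispersal is modelled
#'
#' An animal profile is the key into every allometry of the model: body mass
#' plus the taxonomic group / locomotion mode pairing. Only the three
#' parameterized pairings are supported: flying birds, running mammals and
#' swimming fishes. When `mode` is omitted it is inferred from the group.
#'
#' `body_mass` may be a vector, in which case every downstream quantity
#' (storage, BMR, speed, cost, maximum distance) is computed element-wise:
#' convenient for mass sweeps and record tables.
#'
#' @param body_mass body mass in kg; strictly positive. Masses outside
#'   `[1e-6, 1e6]` kg trigger a warning (the allometries are extrapolations
#'   well before that).
#' @param group `"bird"`, `"mammal"` or `"fish"`.
#' @param mode optional; `"flying"`, `"running"` or `"swimming"`. Must match
#'   the group's parameterized locomotion mode.
#' @return An object of class `animal_profile` with elements `body_mass`,
#'   `group`, `mode`.
#' @examples
#' animal_profile(4.5, "mammal")           # a 4.5 kg running mammal
#' animal_profile(0.02, "bird", "flying")
#' @export
animal_profile <- function(body_mass,
                           group = c("bird", "mammal", "fish"),
                           mode = NULL) {
  group <- match.arg(group)
  expected <- .mode_for_group(group)
  if (is.null(mode)) {
    mode <- expected
  } else {
    mode <- match.arg(mode, c("flying", "running", "swimming"))
    if (mode != expected)
      stop("unsupported taxon-locomotion pairing: ", group, " + ", mode,
           " (parameterized pairings: bird+flying, mammal+running, ",
           "fish+swimming)")
  }
  if (!is.numeric(body_mass) || length(body_mass) < 1L ||
      any(!is.finite(body_mass)))
    stop("'body_mass' must be finite and numeric (kg)")
  if (any(body_mass <= 0))
    stop("'body_mass' must be > 0 kg")
  if (any(body_mass < 1e-6 | body_mass > 1e6))
    warning("body mass outside [1e-6, 1e6] kg: the allometries are ",
            "extrapolated far beyond their empirical support")
  structure(list(body_mass = body_mass, group = group, mode = mode),
            class = "animal_profile")
}

.mode_for_group <- function(group) {
  switch(group, bird = "flying", mammal = "running", fish = "swimming")
}

.check_animal <- function(animal) {
  if (!inherits(animal, "animal_profile"))
    stop("'animal' must be an animal_profile object")
  animal
}

#' @export
print.animal_profile <- function(x, ...) {
  m <- x$body_mass
  cat(sprintf("%s %s, body mass %s kg\n", x$mode, x$group,
              if (length(m) == 1L) format(m) else
                sprintf("[%s .. %s] (n = %d)", format(min(m)),
                        format(max(m)), length(m))))
  invisible(x)
}
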