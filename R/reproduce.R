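# The nine published worked examples used to verify the parameterization
# and to resolve the ambiguous equation typography (see resolve_parse).
.golden <- function() {
  data.frame(
    id = c("cpm_mammal_4.5kg", "cpm_mammal_4000kg", "reldep_pct_4000kg_100km",
           "dmax_bird_0.0031kg", "dmax_bird_8.44kg", "dmax_mammal_0.0076kg",
           "dmax_mammal_3940kg", "dmax_fish_0.22kg", "dmax_fish_550kg"),
    quantity = c("cost per metre", "cost per metre", "% available energy",
                 rep("max dispersal distance", 6)),
    units = c("J/m", "J/m", "%", rep("km", 6)),
    group = c("mammal", "mammal", "mammal", "bird", "bird", "mammal",
              "mammal", "fish", "fish"),
    mass_kg = c(4.5, 4000, 4000, 0.0031, 8.44, 0.0076, 3940, 0.22, 550),
    published = c(58.82, 5390.62, 7, 193.82, 5435.39, 8.47, 1332.97,
                  1860.75, 21472.13),
    stringsAsFactors = FALSE
  )
}

.golden_value <- function(row, params, lambda = 0.1) {
  a <- animal_profile(row$mass_kg, row$group)
  switch(row$quantity,
    "cost per metre" = cost_per_metre(a, params),
    "% available energy" =
      round(100 * relative_depletion(a, 1e5, lambda, params)),
    "max dispersal distance" =
      max_dispersal_distance(a, lambda, params)$d_max / 1000)
}

#' Recompute the published worked examples
#'
#' Evaluates the nine published worked numbers (two costs per metre, one
#' rounded energy-use percentage, six maximum-distance range endpoints at
#' `lambda = 0.1`) with the current parameter set and reports them next to
#' the published values with a pass/fail flag at a relative tolerance.
#'
#' With the shipped defaults, seven of the nine agree within 1%; the two
#' small-bodied range endpoints (0.0076 kg mammal, 0.22 kg fish) land
#' within 2%, the agreement attainable from the published
#' two-decimal-place coefficients (see the package vignette).
#'
#' @inheritParams allometry
#' @param lambda residual energy fraction used for the distance rows.
#' @param tol relative tolerance for the `pass` column.
#' @return `data.frame` with columns `id`, `quantity`, `units`, `group`,
#'   `mass_kg`, `published`, `computed`, `rel_error`, `pass`, and
#'   attribute `overall` (all rows passing).
#' @examples
#' run_reproduction_suite()
#' @export
run_reproduction_suite <- function(params = dispersal_params(),
                                   lambda = 0.1, tol = 0.01) {
  g <- .golden()
  g$computed <- vapply(seq_len(nrow(g)), function(i)
    .golden_value(g[i, ], params, lambda), numeric(1))
  g$rel_error <- (g$computed - g$published) / g$published
  g$pass <- abs(g$rel_error) <= tol
  attr(g, "overall") <- all(g$pass)
  g
}

#' Resolve the algebraic form of the ambiguous published equations
#'
#' The published typography of the travel-speed equation and of the
#' swimming locomotion-cost equation admits several algebraic readings.
#' This harness evaluates every candidate configuration -- the four
#' travel-speed parses crossed with the swimming baseline mass exponent
#' `b13` in `{0, 1}` -- against the nine published worked numbers and ranks
#' them by their worst relative discrepancy. The winning configuration
#' (`harmonic` speed, `b13 = 1`) reproduces all nine values to within 2%
#' (seven within 1%) and ships as the package default; the runner-up
#' configurations are off by 4--130% on at least one number, so the
#' published results over-determine the intended algebra.
#'
#' @inheritParams allometry
#' @param speed_parses character vector of speed parses to evaluate.
#' @param swim_mass_exps numeric vector of `b13` candidates.
#' @return `data.frame` of candidate configurations sorted by
#'   `max_abs_rel_error`, with attribute `best` holding the resolved
#'   `dispersal_params` object.
#' @examples
#' resolve_parse()[1:3, ]
#' @export
resolve_parse <- function(params = dispersal_params(),
                          speed_parses = c("harmonic", "saturating_d",
                                           "saturating_cd", "power"),
                          swim_mass_exps = c(0, 1)) {
  grid <- expand.grid(speed_parse = speed_parses, b13 = swim_mass_exps,
                      stringsAsFactors = FALSE)
  grid$max_abs_rel_error <- vapply(seq_len(nrow(grid)), function(i) {
    p <- modify_params(params, speed_parse = grid$speed_parse[i],
                       b13 = grid$b13[i])
    max(abs(run_reproduction_suite(p)$rel_error))
  }, numeric(1))
  grid <- grid[order(grid$max_abs_rel_error), ]
  rownames(grid) <- NULL
  attr(grid, "best") <- modify_params(params,
                                      speed_parse = grid$speed_parse[1],
                                      b13 = grid$b13[1])
  grid
}
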