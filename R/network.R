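#' Dispersal-cost-weighted spatial networks
#'
#' For a species and a patch landscape, every patch pair is linked by the
#' relative energy the animal would retain after travelling the straight
#' Euclidean distance between them:
#' \deqn{w_{ij} = \max(0,\; 1 - E_c(d_{ij}) / E_\alpha)}
#' Costs exceeding the available energy are clamped to zero, so a link is
#' present exactly when the pair lies strictly within the species'
#' physiological maximum dispersal distance (a separation of exactly
#' `Dmax` depletes `E_alpha` fully and carries weight 0). The network is
#' undirected and self-links are excluded.
#'
#' @inheritParams energy_budget
#' @param land a [landscape()] with at least two patches.
#' @return object of class `dispersal_network`: list with `weights`
#'   (symmetric matrix in `[0, 1]`), `distances` (m), `d_max` (m),
#'   `animal`, `lambda` and `land`.
#' @examples
#' L <- generate_random_landscape(20, extent = 2e5, seed = 42)
#' net <- build_network(animal_profile(4.5, "mammal"), L)
#' connectance(net); weighted_connectance(net)
#' @export
build_network <- function(animal, land, lambda = 0.1,
                          params = dispersal_params()) {
  stopifnot(inherits(land, "landscape"))
  if (length(animal$body_mass) != 1L)
    stop("build_network() expects a single body mass")
  D <- pairwise_distances(land)
  Ea <- (1 - lambda) * energy_storage(animal, params)
  if (Ea <= 0) stop("lambda = 1 leaves no available energy for dispersal")
  jpm <- cost_per_metre(animal, params)  # Ec is linear in distance
  W <- 1 - (jpm * D) / Ea
  W[W < 0] <- 0
  diag(W) <- 0
  structure(list(weights = W, distances = D, d_max = Ea / jpm,
                 animal = animal, lambda = lambda, land = land),
            class = "dispersal_network")
}

.n_pairs <- function(net) {
  n <- nrow(net$weights)
  if (n < 2) stop("network needs at least 2 patches")
  n * (n - 1) / 2
}

#' Connectance of a dispersal network
#'
#' `connectance()` is the proportion of patch pairs carrying a feasible
#' dispersal link (weight > 0); `weighted_connectance()` weights each pair
#' by the relative energy remaining, so it is never larger than the
#' unweighted connectance.
#'
#' @param net a [build_network()] result.
#' @return a fraction in `[0, 1]`.
#' @export
connectance <- function(net) {
  stopifnot(inherits(net, "dispersal_network"))
  sum(net$weights[upper.tri(net$weights)] > 0) / .n_pairs(net)
}

#' @rdname connectance
#' @export
weighted_connectance <- function(net) {
  stopifnot(inherits(net, "dispersal_network"))
  sum(net$weights[upper.tri(net$weights)]) / .n_pairs(net)
}

#' Edge list of a dispersal network
#'
#' @inheritParams connectance
#' @param drop_absent drop pairs with zero weight (infeasible links)?
#' @return `data.frame` with columns `source`, `target`, `distance_m`,
#'   `weight`, one row per unordered patch pair.
#' @export
network_edges <- function(net, drop_absent = FALSE) {
  stopifnot(inherits(net, "dispersal_network"))
  ids <- rownames(net$weights)
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  out <- data.frame(source = ids[ut[, 1]], target = ids[ut[, 2]],
                    distance_m = net$distances[ut],
                    weight = net$weights[ut])
  if (drop_absent) out <- out[out$weight > 0, , drop = FALSE]
  out
}

#' Serialize a dispersal network
#'
#' `write_network_csv()` writes the edge list (`source,target,distance_m,
#' weight`) followed by a `#`-prefixed metrics line holding the connectance
#' and weighted connectance. `write_network_graphml()` emits a minimal
#' GraphML document for graph viewers.
#'
#' @inheritParams connectance
#' @param file output path.
#' @export
write_network_csv <- function(net, file) {
  edges <- network_edges(net)
  utils::write.csv(edges, file, row.names = FALSE, quote = FALSE)
  cat(sprintf("# connectance=%.6f,weighted_connectance=%.6f\n",
              connectance(net), weighted_connectance(net)),
      file = file, append = TRUE)
  invisible(file)
}

#' @rdname write_network_csv
#' @export
write_network_graphml <- function(net, file) {
  stopifnot(inherits(net, "dispersal_network"))
  p <- net$land$patches
  edges <- network_edges(net, drop_absent = TRUE)
  con <- file(file, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="x" for="node" attr.name="x" attr.type="double"/>')
  w('  <key id="y" for="node" attr.name="y" attr.type="double"/>')
  w('  <key id="w" for="edge" attr.name="weight" attr.type="double"/>')
  w('  <key id="d" for="edge" attr.name="distance_m" attr.type="double"/>')
  w('  <graph edgedefault="undirected">')
  for (i in seq_len(nrow(p)))
    w('    <node id="%s"><data key="x">%g</data><data key="y">%g</data></node>',
      p$patch_id[i], p$x[i], p$y[i])
  for (i in seq_len(nrow(edges)))
    w(paste0('    <edge source="%s" target="%s">',
             '<data key="w">%g</data><data key="d">%g</data></edge>'),
      edges$source[i], edges$target[i], edges$weight[i], edges$distance_m[i])
  w('  </graph>')
  w('</graphml>')
  invisible(file)
}

#' @export
print.dispersal_network <- function(x, ...) {
  cat(sprintf("dispersal-cost-weighted network: %d patches, %s %s (%g kg)\n",
              nrow(x$weights), x$animal$mode, x$animal$group,
              x$animal$body_mass))
  cat(sprintf("  Dmax = %.2f km (lambda = %g)\n", x$d_max / 1000, x$lambda))
  cat(sprintf("  connectance = %.3f, weighted connectance = %.3f\n",
              connectance(x), weighted_connectance(x)))
  invisible(x)
}
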