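#' Patch landscapes
#'
#' A landscape is a set of habitat patches on a Cartesian plane with metres
#' as units. Landscapes can be read from CSV (`patch_id,x,y`), supplied as
#' a data frame, or generated synthetically: `generate_random_landscape()`
#' scatters patches independently and uniformly over the extent, while
#' `generate_clustered_landscape()` places cluster centres uniformly and
#' scatters patches isotropically (Gaussian, sd `spread`) around a
#' randomly chosen centre, reflecting any overshoot back into the extent.
#'
#' @param patches data.frame with columns `patch_id`, `x`, `y` (m).
#' @param extent landscape size in m: a single number (square side) or a
#'   length-2 vector `c(width, height)`; the origin is (0, 0).
#' @param n number of patches (>= 2; a single patch has no network).
#' @param n_clusters number of cluster centres, `1 <= n_clusters <= n`.
#' @param spread within-cluster Gaussian standard deviation in m (> 0).
#' @param seed optional integer; when given, generation is deterministic
#'   and the caller's RNG state is left untouched.
#' @return object of class `landscape`: list with `patches` (data.frame)
#'   and `extent` (length-2 numeric).
#' @examples
#' L <- generate_random_landscape(25, extent = 1e5, seed = 1)
#' C <- generate_clustered_landscape(30, n_clusters = 3, spread = 2e3,
#'                                   extent = 1e5, seed = 1)
#' @name landscapes
NULL

#' @rdname landscapes
#' @export
landscape <- function(patches, extent = NULL) {
  patches <- as.data.frame(patches)
  need <- c("patch_id", "x", "y")
  if (!all(need %in% names(patches)))
    stop("'patches' needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(patches$patch_id))
    stop("patch_id values must be unique")
  if (any(!is.finite(patches$x)) || any(!is.finite(patches$y)))
    stop("patch coordinates must be finite")
  if (is.null(extent))
    extent <- c(max(patches$x, 0), max(patches$y, 0))
  extent <- .check_extent(extent)
  structure(list(patches = patches[need], extent = extent),
            class = "landscape")
}

.check_extent <- function(extent) {
  if (!is.numeric(extent) || !length(extent) %in% c(1L, 2L) ||
      any(!is.finite(extent)) || any(extent <= 0))
    stop("'extent' must be one or two positive numbers (m)")
  if (length(extent) == 1L) extent <- c(extent, extent)
  extent
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @rdname landscapes
#' @export
generate_random_landscape <- function(n, extent = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be >= 2 patches")
  extent <- .check_extent(extent)
  .with_seed(seed, {
    landscape(data.frame(patch_id = seq_len(n),
                         x = stats::runif(n, 0, extent[1]),
                         y = stats::runif(n, 0, extent[2])),
              extent)
  })
}

#' @rdname landscapes
#' @export
generate_clustered_landscape <- function(n, n_clusters, spread, extent = 1,
                                         seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be >= 2 patches")
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L ||
      n_clusters < 1 || n_clusters > n)
    stop("'n_clusters' must satisfy 1 <= n_clusters <= n")
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0)
    stop("'spread' must be > 0 m")
  extent <- .check_extent(extent)
  .with_seed(seed, {
    cx <- stats::runif(n_clusters, 0, extent[1])
    cy <- stats::runif(n_clusters, 0, extent[2])
    assign_to <- sample.int(n_clusters, n, replace = TRUE)
    x <- .reflect(cx[assign_to] + stats::rnorm(n, 0, spread), extent[1])
    y <- .reflect(cy[assign_to] + stats::rnorm(n, 0, spread), extent[2])
    L <- landscape(data.frame(patch_id = seq_len(n), x = x, y = y), extent)
    L$cluster <- assign_to
    L
  })
}

# reflect coordinates into [0, hi] (fold at both boundaries)
.reflect <- function(z, hi) {
  w <- z %% (2 * hi)
  ifelse(w > hi, 2 * hi - w, w)
}

#' Euclidean distance matrix between all patches
#'
#' @param land a [landscape()].
#' @return symmetric n x n matrix of straight-line distances in m, with
#'   zero diagonal and patch ids as dimnames.
#' @export
pairwise_distances <- function(land) {
  stopifnot(inherits(land, "landscape"))
  if (nrow(land$patches) < 2) stop("need at least 2 patches")
  D <- as.matrix(stats::dist(land$patches[c("x", "y")]))
  dimnames(D) <- list(land$patches$patch_id, land$patches$patch_id)
  D
}

#' @rdname landscapes
#' @param file CSV path with header `patch_id,x,y` (m).
#' @export
read_landscape_csv <- function(file) {
  landscape(utils::read.csv(file, comment.char = "#"))
}

#' @rdname landscapes
#' @param land a `landscape` object to serialize.
#' @export
write_landscape_csv <- function(land, file) {
  stopifnot(inherits(land, "landscape"))
  utils::write.csv(land$patches, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d patches in %g x %g m\n",
              nrow(x$patches), x$extent[1], x$extent[2]))
  invisible(x)
}
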