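#' Model parameterization for the bioenergetic dispersal model
#'
#' Returns the full coefficient/exponent set driving the four allometric
#' building blocks of the model: energy storage, basal metabolic rate (BMR),
#' travel speed, and locomotion cost per unit time (LCOT). The defaults are
#' the published SI-unit parameterization for flying birds, running mammals
#' and swimming fishes; every value can be overridden by name, which is how
#' sensitivity analyses and the parse-resolution harness
#' ([resolve_parse()]) are driven.
#'
#' Parameter roles (all masses `M` in kg, speeds `v` in m/s):
#' \describe{
#'   \item{`a1`--`a3`, `b1`--`b3`}{Energy storage `E0 = a * M^b` in J, for
#'     birds, mammals and fishes respectively. Coefficients in `J kg^-b`.}
#'   \item{`a4`--`a6`, `b4`--`b6`}{BMR `= a * M^b` in J/s, same group order.}
#'   \item{`v0_fly`, `v0_run`, `v0_swim`, `c`, `k`, `d`}{Travel-speed model
#'     (see [travel_speed()]): mode-specific speed coefficient `v0`
#'     (m s^-1 kg^-c), shared mass exponent `c`, heat-dissipation time
#'     coefficient `k` (s m^-1 kg^-d) and exponent `d`.}
#'   \item{`a7`--`a9`, `b7`--`b10`}{Flying LCOT
#'     `a7*M^b7*v^b8 + a8*M^b7*v^b9 + a9*M^b10*v^b9` in J/s.}
#'   \item{`a10`, `b11`}{Running LCOT `a10 * M^b11 * v` in J/s.}
#'   \item{`a11`, `a12`, `b12`, `b13`}{Swimming LCOT
#'     `a11 * M^b13 * exp(a12 * M^b12 * v)` in J/s: a mass-proportional
#'     baseline (`b13 = 1`) inflated exponentially with speed, the
#'     speed-sensitivity itself declining with mass (`b12 < 0`).}
#'   \item{`a13`, `a14`}{Postural multipliers on BMR during flight and
#'     running; swimming has none (buoyancy carries the body).}
#'   \item{`speed_parse`}{Algebraic form used by [travel_speed()]; the
#'     shipped default `"harmonic"` is the form selected by
#'     [resolve_parse()]. Alternatives: `"saturating_d"`,
#'     `"saturating_cd"`, `"power"`.}
#' }
#'
#' @param ... named overrides, e.g. `dispersal_params(a10 = 12)`. Unknown
#'   names are an error.
#' @return An object of class `dispersal_params`: a named list of numeric
#'   parameters plus the `speed_parse` choice.
#' @examples
#' p <- dispersal_params()
#' p$a1                      # bird energy-storage coefficient, J/kg
#' dispersal_params(k = 0.05)$k
#' @seealso [modify_params()], [write_params_config()], [resolve_parse()]
#' @export
dispersal_params <- function(...) {
  p <- .default_params()
  modify_params(p, ...)
}

.default_params <- function() {
  structure(list(
    # energy storage E0 = a M^b [J]
    a1 = 2.5e6,  b1 = 0.98,   # birds
    a2 = 2.00e6, b2 = 1.00,   # mammals
    a3 = 4.78e6, b3 = 1.02,   # fishes
    # basal metabolic rate = a M^b [J/s]
    a4 = 3.63, b4 = 0.65,
    a5 = 2.89, b5 = 0.74,
    a6 = 0.29, b6 = 0.95,
    # travel speed
    v0_fly = 30.54, v0_run = 0.28, v0_swim = 0.39,
    c = 0.27, k = 0.03, d = 0.24,
    # locomotion cost per unit time [J/s]
    a7 = 32.00, a8 = 3.3e-3, a9 = 5.8e-3,
    b7 = 0.66, b8 = -1.00, b9 = 2.50, b10 = 0.49,
    a10 = 11.30, b11 = 0.72,
    a11 = 0.12, a12 = 1.88, b12 = -0.36, b13 = 1.00,
    # postural multipliers on BMR
    a13 = 1.10, a14 = 1.20,
    speed_parse = "harmonic"
  ), class = "dispersal_params")
}

.speed_parses <- c("harmonic", "saturating_d", "saturating_cd", "power")

#' Modify an existing parameter set
#'
#' @param params a `dispersal_params` object.
#' @inheritParams dispersal_params
#' @return the modified, re-validated `dispersal_params` object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "dispersal_params"))
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(params))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(ov)] <- ov
  }
  validate_params(params)
}

#' @rdname modify_params
#' @export
validate_params <- function(params) {
  if (!inherits(params, "dispersal_params"))
    stop("not a dispersal_params object")
  num <- setdiff(names(.default_params()), "speed_parse")
  for (nm in num) {
    val <- params[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number")
  }
  coefs <- c("a1", "a2", "a3", "a4", "a5", "a6", "a7", "a8", "a9", "a10",
             "a11", "a12", "a13", "a14", "k", "v0_fly", "v0_run", "v0_swim")
  neg <- coefs[vapply(coefs, function(nm) params[[nm]] <= 0, logical(1))]
  if (length(neg))
    stop("coefficient(s) must be > 0: ", paste(neg, collapse = ", "))
  if (!is.character(params$speed_parse) ||
      !params$speed_parse %in% .speed_parses)
    stop("configuration error: 'speed_parse' must be one of ",
         paste(.speed_parses, collapse = ", "))
  params
}

#' @export
print.dispersal_params <- function(x, ...) {
  cat("Bioenergetic dispersal model parameters\n")
  cat("  travel-speed parse:", x$speed_parse, "\n")
  num <- setdiff(names(x), "speed_parse")
  vals <- unlist(x[num])
  def <- unlist(.default_params()[num])
  changed <- num[vals != def]
  cat(" ", length(num), "numeric parameters;",
      if (length(changed)) paste("overridden:", paste(changed, collapse = ", "))
      else "all at published defaults", "\n")
  invisible(x)
}

#' Read and write parameter configuration files
#'
#' The plain-text configuration format is one parameter per line,
#' `name value`, using the canonical parameter names (`a1` ... `a14`,
#' `b1` ... `b13`, `c`, `d`, `k`, `v0_fly`, `v0_run`, `v0_swim`), plus a
#' final `speed_parse <name>` line. Values are written with full double
#' precision so a write/read round trip is lossless.
#'
#' @param params a `dispersal_params` object.
#' @param file path of the configuration file.
#' @return `write_params_config()` returns `file` invisibly;
#'   `read_params_config()` returns a validated `dispersal_params` object.
#' @export
write_params_config <- function(params, file) {
  params <- validate_params(params)
  num <- setdiff(names(params), "speed_parse")
  lines <- c(
    sprintf("%s %.17g", num, unlist(params[num])),
    paste("speed_parse", params$speed_parse))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]=]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(parts, `[`, character(1), 1L)
  vals <- vapply(parts, `[`, character(1), 2L)
  ov <- list()
  for (i in seq_along(keys)) {
    ov[[keys[i]]] <- if (keys[i] == "speed_parse") vals[i] else
      as.numeric(vals[i])
  }
  do.call(dispersal_params, ov)
}
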