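#' The 21 emulator parameter codes, in registry order
#'
#' Phenology thermal-time targets (T1--T4), grain formation and filling
#' (G1, P1, P2, M2, X1), grain nitrogen (P3, M1), development modifiers
#' (P4, V1), canopy (K, Y1, I1, S1, I2), resource capture (R1, E1, N1).
#'
#' @return Character vector of length 21.
#' @export
parameter_codes <- function() {
  c("P1", "P2", "P3", "M1", "P4", "V1", "G1", "M2", "T1", "T2", "T3",
    "T4", "K", "R1", "Y1", "I1", "S1", "E1", "N1", "I2", "X1")
}

#' Load a parameter-bounds registry
#'
#' Reads a delimited bounds table with columns `code`, `definition`,
#' `unit`, `lower`, `upper`. With `source = NULL` the bundled registry of
#' the 21 wheat-emulator parameters is returned (uniform ranges spanning
#' roughly +/-50% of typical cultivar values, plus a handful of
#' asymmetric physically-bounded ranges such as the extinction
#' coefficient K on [0, 1]).
#'
#' @param source Path to a CSV/TSV bounds file, or `NULL` for the bundled
#'   registry.
#' @param strict When `TRUE` (default), codes outside the canonical set of
#'   [parameter_codes()] are an error; set `FALSE` to load arbitrary
#'   registries (e.g. for toy problems).
#' @return A `data.frame` with one row per parameter, class
#'   `parameter_specs`.
#' @export
load_bounds <- function(source = NULL, strict = TRUE) {
  if (is.null(source)) {
    source <- system.file("extdata", "parameter_bounds.csv",
                          package = "cropsens", mustWork = TRUE)
  }
  sep <- if (grepl("\\.tsv$", source)) "\t" else ","
  df <- utils::read.csv(source, sep = sep, stringsAsFactors = FALSE)
  needed <- c("code", "definition", "unit", "lower", "upper")
  if (!all(needed %in% names(df))) {
    stop("bounds file must have columns: ", paste(needed, collapse = ", "))
  }
  df <- df[, needed]
  if (anyDuplicated(df$code)) {
    stop("duplicate parameter code(s): ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  }
  if (any(!is.finite(df$lower)) || any(!is.finite(df$upper))) {
    stop("non-finite bound")
  }
  bad <- df$lower >= df$upper
  if (any(bad)) {
    stop("lower >= upper for: ", paste(df$code[bad], collapse = ", "))
  }
  if (strict) {
    unknown <- setdiff(df$code, parameter_codes())
    if (length(unknown)) {
      stop("unknown parameter code(s): ", paste(unknown, collapse = ", "))
    }
  }
  class(df) <- c("parameter_specs", "data.frame")
  df
}

#' Write a bounds registry back to delimited text
#'
#' Inverse of [load_bounds()]; the round trip is value-identical.
#'
#' @param specs A `parameter_specs` data frame.
#' @param path Output CSV path.
#' @export
write_bounds <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

assert_specs <- function(specs) {
  if (!inherits(specs, "parameter_specs")) {
    stop("expected a 'parameter_specs' object from load_bounds()")
  }
  invisible(specs)
}

#' Map unit-hypercube coordinates to physical parameter values
#'
#' `to_physical()` applies `lower + u * (upper - lower)` per parameter;
#' `to_unit()` is its exact inverse. A parameter set is a named numeric
#' vector keyed by parameter code.
#'
#' @param u Numeric vector of coordinates in \[0, 1\], one per spec row
#'   (recycled names are taken from `specs$code`), or a matrix with one
#'   column per parameter.
#' @param specs Bounds registry from [load_bounds()].
#' @return Named numeric vector (or matrix) in physical units.
#' @export
to_physical <- function(u, specs) {
  assert_specs(specs)
  if (is.matrix(u)) {
    if (ncol(u) != nrow(specs)) stop("u has wrong number of columns")
    if (any(u < -1e-12 | u > 1 + 1e-12)) stop("coordinate outside [0, 1]")
    x <- sweep(sweep(u, 2, specs$upper - specs$lower, `*`), 2, specs$lower, `+`)
    colnames(x) <- specs$code
    return(x)
  }
  if (length(u) != nrow(specs)) stop("u has wrong length")
  if (any(u < -1e-12 | u > 1 + 1e-12)) stop("coordinate outside [0, 1]")
  stats::setNames(specs$lower + u * (specs$upper - specs$lower), specs$code)
}

#' @rdname to_physical
#' @param x Named numeric vector (or matrix) of physical values.
#' @export
to_unit <- function(x, specs) {
  assert_specs(specs)
  if (is.matrix(x)) {
    x <- x[, specs$code, drop = FALSE]
    u <- sweep(sweep(x, 2, specs$lower, `-`), 2,
               specs$upper - specs$lower, `/`)
    return(u)
  }
  x <- x[specs$code]
  stats::setNames((x - specs$lower) / (specs$upper - specs$lower), specs$code)
}

#' Midpoint (baseline) parameter defaults
#'
#' The midpoint of each bound interval. For symmetric +/-50% ranges this
#' recovers the nominal cultivar value; it is the emulator's baseline and
#' the value at which non-free parameters are pinned during calibration.
#'
#' @inheritParams to_physical
#' @return Named numeric vector of per-code midpoints.
#' @export
midpoint_defaults <- function(specs) {
  assert_specs(specs)
  stats::setNames((specs$lower + specs$upper) / 2, specs$code)
}

#' Validate a physical parameter set against its bounds
#'
#' @param params Named numeric vector in physical units.
#' @param specs Bounds registry.
#' @param complete Require all codes present (default `TRUE`).
#' @return `params`, invisibly, reordered to registry order.
#' @export
validate_params <- function(params, specs, complete = TRUE) {
  assert_specs(specs)
  if (complete) {
    missing <- setdiff(specs$code, names(params))
    if (length(missing)) {
      stop("incomplete parameter set; missing: ",
           paste(missing, collapse = ", "))
    }
  }
  keep <- intersect(specs$code, names(params))
  idx <- match(keep, specs$code)
  v <- params[keep]
  tol <- 1e-9 * (specs$upper[idx] - specs$lower[idx])
  out <- v < specs$lower[idx] - tol | v > specs$upper[idx] + tol
  if (any(out)) {
    stop("parameter(s) outside bounds: ", paste(keep[out], collapse = ", "))
  }
  invisible(params[specs$code[specs$code %in% names(params)]])
}
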