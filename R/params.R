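#' Holzapfel-Ogden material parameters
#'
#' Construct the eight-parameter set of the orthotropic Holzapfel-Ogden
#' strain-energy function for passive myocardium: an isotropic matrix term
#' (`a`, `b`), fibre and sheet reinforcement terms (`a_f`, `b_f`, `a_s`,
#' `b_s`) and a fibre-sheet coupling term (`a_fs`, `b_fs`). Moduli are in
#' kPa, exponents are dimensionless, and all eight must be non-negative.
#'
#' Defaults are read from the packaged configuration file
#' `system.file("extdata", "material_params.cfg", package = "resmyo")`,
#' a literature fit to canine simple-shear data; any subset can be
#' overridden by name.
#'
#' @param ... named overrides of any of `a`, `b`, `a_f`, `b_f`, `a_s`,
#'   `b_s`, `a_fs`, `b_fs` (moduli in kPa).
#' @param file path to a flat `key = value` parameter file to use instead of
#'   the packaged defaults. Unknown or missing keys are an error.
#'
#' @return An object of class `ho_params`: a named list with the eight
#'   parameters.
#' @examples
#' ho_params()
#' ho_params(a_f = 0, a_s = 0, a_fs = 0) # isotropic matrix only
#' @export
ho_params <- function(..., file = NULL) {
  base <- if (is.null(file)) default_params() else read_material_params(file)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), param_names)
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown material parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    base[names(over)] <- over
  }
  validate_params(base)
}

param_names <- c("a", "b", "a_f", "b_f", "a_s", "b_s", "a_fs", "b_fs")

validate_params <- function(p) {
  p <- lapply(p, as.numeric)
  vals <- unlist(p[param_names])
  if (anyNA(vals) || !all(is.finite(vals))) {
    stop("material parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("all eight material parameters must be non-negative", call. = FALSE)
  }
  structure(p[param_names], class = "ho_params")
}

default_params_cache <- new.env(parent = emptyenv())

default_params <- function() {
  if (is.null(default_params_cache$p)) {
    path <- system.file("extdata", "material_params.cfg", package = "resmyo")
    default_params_cache$p <- read_material_params(path)
  }
  default_params_cache$p
}

#' Read material parameters from a key-value file
#'
#' Strict parser for flat `key = value` parameter files: every one of the
#' eight Holzapfel-Ogden keys must be present exactly once and no other keys
#' are allowed. Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return An `ho_params` object.
#' @export
read_material_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("malformed line(s) in parameter file (expect 'key = value')", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  unknown <- setdiff(keys, param_names)
  if (length(unknown)) {
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("duplicated key(s) in parameter file", call. = FALSE)
  missing <- setdiff(param_names, keys)
  if (length(missing)) {
    stop("missing key(s) in parameter file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_params(stats::setNames(as.list(vals), keys))
}

#' @export
print.ho_params <- function(x, ...) {
  cat("Holzapfel-Ogden material parameters (moduli in kPa):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
format.ho_params <- function(x, ...) {
  paste(sprintf("%s=%g", names(x), unlist(x)), collapse = ", ")
}

#' @importFrom generics tidy
#' @export
tidy.ho_params <- function(x, ...) {
  tibble::tibble(
    term = names(x),
    estimate = unlist(x, use.names = FALSE),
    unit = rep(c("kPa", "1"), 4L)
  )
}
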