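#' Nondimensional model parameters
#'
#' Container for the six nondimensional parameters of the viability model:
#' `s1` controls oxygen-saturated proliferation, `s2`--`s4` shape the death
#' term (`s2` the oxygen-independent death rate, `s3` the oxygen-proportional
#' part, `s4` the oxygen saturation of death), and `Q`, `Q1` set the oxygen
#' consumption rate and its saturation. All values must be finite and
#' nonnegative: each enters as a rate or saturation coefficient, and negative
#' values can make the saturating denominators vanish.
#'
#' @param s1,s2,s3,s4 Nondimensional growth/death parameters (>= 0).
#' @param Q,Q1 Nondimensional oxygen-consumption parameters (>= 0).
#' @return An object of class `model_params`: a named list with the six
#'   parameters as doubles.
#' @examples
#' p <- model_params(s1 = 1, s2 = 0.2, s3 = 0.3, s4 = 1, Q = 5.32, Q1 = 4.97)
#' @export
model_params <- function(s1 = 0, s2 = 0, s3 = 0, s4 = 0, Q = 0, Q1 = 0) {
  p <- list(s1 = as.numeric(s1), s2 = as.numeric(s2), s3 = as.numeric(s3),
            s4 = as.numeric(s4), Q = as.numeric(Q), Q1 = as.numeric(Q1))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop_invalid_input(sprintf(
        "parameter '%s' must be a single finite nonnegative number", nm))
    }
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  s1=%g s2=%g s3=%g s4=%g  Q=%g Q1=%g\n",
              x$s1, x$s2, x$s3, x$s4, x$Q, x$Q1))
  invisible(x)
}

param_names <- function() c("s1", "s2", "s3", "s4", "Q", "Q1")

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    missing <- setdiff(param_names(), names(x))
    if (length(missing)) {
      stop_invalid_input(paste0("missing parameter(s): ",
                                paste(missing, collapse = ", ")))
    }
    return(do.call(model_params, x[param_names()]))
  }
  stop_invalid_input("cannot interpret object as model_params")
}

#' Read and write model parameters as JSON
#'
#' The on-disk form is a flat JSON object with keys `"s1"`, `"s2"`, `"s3"`,
#' `"s4"`, `"Q"`, `"Q1"`. Values are serialized at full double precision so a
#' write/read round trip is lossless.
#'
#' @param p A [model_params] object.
#' @param path File path.
#' @return `read_params_json` returns a [model_params]; `write_params_json`
#'   returns `path` invisibly.
#' @export
write_params_json <- function(p, path) {
  p <- as_model_params(p)
  # I(17) significant digits: shortest representation that round-trips doubles
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste0("input not found: ", path))
  as_model_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

# classed conditions: validation errors map to CLI exit code 2
stop_invalid_input <- function(msg) {
  stop(structure(class = c("viabsim_invalid_input", "viabsim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_numerical <- function(msg, data = NULL) {
  stop(structure(class = c("viabsim_numerical_error", "viabsim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), data = data)))
}
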