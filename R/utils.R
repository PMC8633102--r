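# Internal helpers: condition classes and seed scoping.

abort_invalid_parameter <- function(msg) {
  abort(msg, class = "epiensemble_error_invalid_parameter")
}

abort_invalid_input <- function(msg) {
  abort(msg, class = "epiensemble_error_invalid_input")
}

abort_missing_data <- function(msg) {
  abort(msg, class = "epiensemble_error_missing_data")
}

abort_parse <- function(msg) {
  abort(msg, class = "epiensemble_error_parse")
}

abort_io <- function(msg) {
  abort(msg, class = "epiensemble_error_io")
}

check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort_invalid_parameter(
      "`temperature` must be a single positive number (Kelvin).")
  }
  invisible(temperature)
}

check_gas_constant <- function(gas_constant) {
  if (!is.numeric(gas_constant) || length(gas_constant) != 1 ||
      !is.finite(gas_constant) || gas_constant <= 0) {
    abort_invalid_parameter("`gas_constant` must be a single positive number.")
  }
  invisible(gas_constant)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream. `seed = NULL` leaves the global stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort_invalid_parameter("`seed` must be a single integer or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
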