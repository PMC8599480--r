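# Internal validation helpers shared across modules.

stop_input <- function(...) {
  stop(structure(
    class = c("musclemri_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("musclemri_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_config(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_config(name, " must be >= ", lower)
  }
  if (x > upper) {
    stop_config(name, " must be <= ", upper)
  }
  invisible(x)
}

# Restore the caller-visible RNG stream on exit so seeded generators do not
# perturb the session; when seed is NULL the global stream is consumed as is.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
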