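#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Validation stops carry the
## offending argument name so pipeline errors identify their stage.

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation("`%s` must be a single number", name)
  }
  if (x < lower || x > upper) {
    stop_validation("`%s` must be in [%s, %s], got %s", name,
                    format(lower), format(upper), format(x))
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed for a named random substream
#'
#' All randomness in the simulator flows from one master seed; each
#' generation stage (athletes, calendar, tachograms, observation noise)
#' draws from its own substream so stages can be regenerated
#' independently without perturbing one another.
#'
#' @param seed master integer seed.
#' @param name character substream label.
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  check_number(seed, "seed")
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 10007 + h * 97) %% 2147483629L)
}

## Truncated-normal sampler by rejection; sd = 0 collapses to the mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop_validation("sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
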