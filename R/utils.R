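# Internal helpers shared across modules. Timestamps are integer minutes from a
# global epoch; all intervals are half-open [start, end).

HOUR_MIN <- 60
DAY_MIN <- 1440
YEAR_MIN <- 525960  # 365.25 days

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}

stop_data <- function(fmt, ...) {
  stop(sprintf(paste0("data error: ", fmt), ...), call. = FALSE)
}

assert_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop_data("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  }
}

logistic <- function(x) stats::plogis(x)

# hours -> integer minutes
h2min <- function(h) as.integer(round(h * HOUR_MIN))
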