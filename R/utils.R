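#' @importFrom rlang abort warn inform %||% hash
#' @importFrom stats quantile rbinom rnorm runif sd var setNames
#' @importFrom utils head
NULL

# classed conditions so callers can test on failure modes, not message text
stop_subnetap <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("subnetap_", class), "subnetap_error"))
}

warn_subnetap <- function(msg, class = "warning") {
  rlang::warn(msg, class = c(paste0("subnetap_", class), "subnetap_warning"))
}

`%||%` <- rlang::`%||%`

# draw independent substream seeds from one master seed without touching
# the caller's RNG state; keeps every derived seed a valid 32-bit integer
derive_seeds <- function(seed, n, max = .Machine$integer.max) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(max, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
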