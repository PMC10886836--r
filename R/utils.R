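## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a child seed from a master seed by a fixed offset, kept within the
## 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

## All permutations of 1..n as a list (n <= 8 guarded by callers).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

stop_invalid <- function(msg) abort(msg, class = "microstates_invalid_configuration")
stop_dimension <- function(msg) abort(msg, class = "microstates_dimension_error")
stop_undefined <- function(msg) abort(msg, class = "microstates_undefined_result")
stop_input <- function(msg) abort(msg, class = "microstates_invalid_input")
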