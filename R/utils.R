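#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based fan-out: each (replicate, slot) pair maps to its own RNG
#' seed, so adding scenarios or structures never shifts the random stream of
#' the others. All arithmetic stays below 2^31 - 1.
#'
#' @param master master seed (single integer-valued number).
#' @param rep replicate counter (nonnegative integer).
#' @param slot stream slot within the replicate (nonnegative integer);
#'   slots 0..9 are reserved for community construction, 10+ for scenarios.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(master, rep = 0L, slot = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((master %% m) * 48271 + rep * 65537 + slot * 257 + 1) %% m
  # second mixing pass decorrelates consecutive replicates
  s <- (s * 69621) %% m
  as.integer(s + (s == 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("feasnet_config_error", "error")))
}

stop_degenerate <- function(msg, rcond = NA_real_) {
  stop(errorCondition(msg,
    rcond = rcond,
    class = c("feasnet_degenerate_error", "error")
  ))
}

check_square_numeric <- function(A, what = "matrix") {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A)) {
    stop_config(what, " must be a square numeric matrix")
  }
  if (!all(is.finite(A))) stop_config(what, " has non-finite entries")
  invisible(A)
}
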