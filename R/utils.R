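#' @keywords internal
"_PACKAGE"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-subject seed from a master seed
#'
#' Counter-based splitting rule so that cohort simulations are reproducible
#' and subjects are mutually independent. Kept below 2^31 so the result is a
#' valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param index subject counter (1-based).
#' @return integer seed.
#' @export
subject_seed <- function(master_seed, index) {
  s <- (as.numeric(master_seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647
  as.integer(s)
}

gm_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "gaitmark_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# first sample index (1-based, sample i at time (i-1)/fs) whose time is >= t
time_to_index <- function(t, fs) as.integer(ceiling(t * fs + 1 - 1e-9))
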