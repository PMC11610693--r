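#' @keywords internal
#' @importFrom mgcv gam
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded generators behave as pure functions of their arguments and never
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a fixed number of sub-seeds from one master seed
#'
#' One pipeline-level seed deterministically yields per-stage (or per-site)
#' seeds, keeping a single reproducibility knob. All derived seeds are kept
#' below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count", call. = FALSE)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Small deterministic content hash (weighted byte sum over the serialized
# object) used for manifest provenance entries; not cryptographic.
hash_obj <- function(x) {
  bytes <- as.double(serialize(x, NULL, version = 2L))
  w <- (seq_along(bytes) - 1) %% 997 + 1
  sprintf("%08x", as.integer(sum(bytes * w) %% (2^31 - 1)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n[month == 2L & leap] <- 29L
  n
}
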