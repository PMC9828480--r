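# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and labels
#'
#' A single user-facing seed fans out to independent per-unit substreams by
#' hashing the unit labels (e.g. strain, resource, level, replicate) together
#' with the master seed. Regenerating any subset of units therefore yields
#' byte-identical output regardless of generation order.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "|")
  # djb2-style rolling hash kept in double precision below 2^31 - 1
  mod <- 2147483647
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% mod
  as.integer((h + (as.double(seed) %% mod) * 2654435) %% mod)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_rsc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_rsc(fmt, ...)
  invisible(TRUE)
}

RESOURCES <- c("light", "N", "P")

match_resource <- function(resource) {
  match.arg(resource, RESOURCES)
}

# treatment label -> resource whose R* it selects on
TREATMENT_RESOURCE <- c("L-lim" = "light", "N-lim" = "N", "P-lim" = "P")
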