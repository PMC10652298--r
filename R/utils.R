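# Internal helpers shared across modules.

#' Human snRNA-seq cell-type labels
#'
#' The six prefrontal-cortex cell types resolved by the single-nucleus
#' differential-expression table: excitatory neurons (Ex), inhibitory neurons
#' (In), astrocytes (Ast), oligodendrocytes (Oli), oligodendrocyte progenitor
#' cells (OPC) and microglia (Mic). The order is fixed and doubles as the
#' deterministic tie-break order for primary cell-type assignment.
#'
#' @format Character vector of length 6.
#' @export
CELL_TYPES <- c("Ex", "In", "Ast", "Oli", "OPC", "Mic")

CHROMATIN_STATES <- c("promoter", "enhancer", "other")
PHTX_LEVELS <- c("absent", "present")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so generators are pure functions of their seed and
#' never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic per-component seed
#'
#' One user-facing seed fans out to independent per-component substreams
#' (one per generator or bootstrap), keeping components reproducible yet
#' decoupled. The derived seed always stays below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the component.
#' @return Integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  M <- 2147483647   # 2^31 - 1; all arithmetic stays exact in doubles
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% M
  x <- (h * 69621 + (abs(seed) %% M) + 1) %% M
  x <- (x * 48271) %% M          # two Lehmer steps decorrelate nearby labels
  x <- (x * 48271) %% M
  as.integer(max(x, 1))
}

# Truncated-at-zero normal draws (amplitudes must stay positive).
rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) x[bad] <- .Machine$double.eps
  x
}

stop_row <- function(table, row, msg) {
  stop(sprintf("%s, row %d: %s", table, row, msg), call. = FALSE)
}

check_numeric_in <- function(x, lo, hi, what, table) {
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad) > 0L)
    stop_row(table, bad[1L], sprintf("%s = %s outside [%g, %g]",
                                     what, format(x[bad[1L]]), lo, hi))
  invisible(TRUE)
}
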