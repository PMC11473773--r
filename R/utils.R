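#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed through a named
#' substream, so that individual components can be regenerated independently
#' while a single integer reproduces the whole pipeline. The derived seed is
#' always a valid 32-bit integer.
#'
#' @param root integer root seed.
#' @param name character substream name (e.g. "parcel_maps", "permutation").
#' @return An integer seed.
#' @export
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  # pass the combined value through the generator itself: a plain arithmetic
  # combination leaves related (root, name) pairs on an arithmetic
  # progression, which yields correlated streams
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(bitwXor(as.integer(abs(root) %% 2147483647), as.integer(h)))
  sample.int(2147483646L, 1L)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

# rank each row of a matrix (average ties), returning a matrix of same shape
rank_rows <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

# row-standardize so that x %*% t(x) / (n - 1) gives Pearson correlations
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  (m - mu) / s
}

clip_rho <- function(rho, eps = 1e-7) pmin(pmax(rho, -1 + eps), 1 - eps)
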