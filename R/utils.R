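#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(errorCondition(paste0(...), class = c("fibrc_config_error", "error")))
stop_input  <- function(...) stop(errorCondition(paste0(...), class = c("fibrc_input_error", "error")))

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_config("'", name, "' must be a single finite number")
  invisible(x)
}

#' Derive a deterministic sub-seed from a global seed and a stream name
#'
#' All randomness in the package flows from one global seed; independent
#' stages draw from named substreams so that adding a stage never perturbs
#' the draws of another.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- as.numeric(seed) %% 2147483647
  for (k in codes) h <- (h * 69069 + k) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# block-average a matrix down to out_r x out_c (grouping indices by
# ceiling(i * out / n); exact mean pooling when out divides n)
block_average <- function(m, out_r, out_c) {
  n_r <- nrow(m); n_c <- ncol(m)
  out_r <- min(out_r, n_r); out_c <- min(out_c, n_c)
  gi <- ceiling(seq_len(n_r) * out_r / n_r)
  gj <- ceiling(seq_len(n_c) * out_c / n_c)
  rs <- rowsum(m, gi)                      # sum rows within groups
  rs <- t(rowsum(t(rs), gj))               # then columns
  cnt <- outer(tabulate(gi, out_r), tabulate(gj, out_c))
  out <- rs / cnt
  dimnames(out) <- NULL
  out
}
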