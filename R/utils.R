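# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child RNG seed from a base seed and a stream label
#'
#' Hierarchical seeding: the genome, each condition, and each replicate draw
#' from independent streams derived from one user-facing integer seed, so that
#' adding a condition or replicate does not perturb the others. The derived
#' seed stays below 2^31.
#'
#' @param seed integer base seed.
#' @param ... labels (character or integer) identifying the stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Fixed-format number rendering for deterministic text output: integers stay
# integers, doubles use up to 6 significant digits without scientific notation.
format_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         format(x, scientific = FALSE, trim = TRUE),
         formatC(x, digits = 6, format = "fg", flag = "#"))
}

# Deterministic TSV writer (no quoting, no row names, "." for NA).
write_tsv_plain <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format_num(col) else as.character(col)
  })
  df[is.na(df)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
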