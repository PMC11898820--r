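#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, as used in printed
#' genetics reports (base `round()` rounds half to even). A small epsilon
#' guards against binary-float representations of decimal halves
#' (e.g. `0.255` stored fractionally below the true half).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.255, 2)  # 0.26, not 0.25
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Derive a reproducible substream seed
#'
#' Maps a global seed plus a stream label to a 32-bit seed, so that each
#' simulation stream (one per breed x locus, or breed x trait) draws from
#' its own reproducible stream. Adding loci or traits then never perturbs
#' draws of the streams already present.
#'
#' @param seed Integer global seed.
#' @param ... Stream label components (coerced to character).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

# stop() with a class so callers/tests can distinguish error families
abort <- function(message, class) {
  stop(structure(
    class = c(class, "npyassoc_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# deterministic TSV writer: no quoting, no row names, "." for NA
write_tsv <- function(df, path, na = ".") {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = na)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
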