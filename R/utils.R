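# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Half-up decimal rounding (round() is banker's; percentages in reports use
# conventional half-up, e.g. 12.65 -> 12.7).
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stopifnot_scalar_number <- function(x, name, min = -Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("'%s' must be >= %s (got %s)", name, min, x), call. = FALSE)
  }
  if (integer && x != as.integer(x)) {
    stop(sprintf("'%s' must be an integer (got %s)", name, x), call. = FALSE)
  }
  invisible(x)
}

# Write a TSV with a '#'-prefixed header comment block (auditability of every
# reported table: seed, thresholds, package version).
write_tsv_commented <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "),
                              character(1L))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
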