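# internal helpers shared across modules

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported summary statistics use the
#' conventional half-up rule at 2 decimals (full precision is always kept
#' alongside).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# read a UTF-8 TSV; plain or gzip paths both work through base connections
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, quote = "", comment.char = "",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8", ...)
}

#' Write a data frame as a TSV file
#'
#' UTF-8, tab-separated, no quoting, no row names; the writer used for every
#' result table so that write-then-read round-trips exactly.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# FNV-1a over a string; provenance fingerprint for configs (hex string).
# Arithmetic kept in doubles (exact below 2^53); xor only touches the low byte.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  mul32 <- function(a, b) {
    ((a %% 65536) * b %% 4294967296 + (a %/% 65536 * b %% 65536) * 65536) %%
      4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
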