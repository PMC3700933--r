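# Shared interval arithmetic and argument checks.
#
# Coordinate convention used throughout: positions are 1-based and a span's
# size in bp is `end - start`, i.e. spans behave as end-exclusive intervals
# for all size and overlap arithmetic. On-disk BED-like files are 0-based
# half-open and are converted at the read/write boundary.

# intersection length under the end-exclusive convention (vectorized)
intersect_len <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

assert_cols <- function(df, cols, name = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("`", name, "` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# derive a sub-seed from a base seed, kept inside 32-bit integer range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

# ensure an event/call table has a unique id column
ensure_call_id <- function(calls, col = "call_id") {
  if (!col %in% names(calls)) {
    calls[[col]] <- paste0("call_", seq_len(nrow(calls)))
  } else if (anyDuplicated(calls[[col]])) {
    stop("`", col, "` values must be unique", call. = FALSE)
  }
  calls
}

clean_dna <- function(x, name = "sequence") {
  x <- toupper(x)
  if (any(nchar(x) == 0)) stop("empty ", name, call. = FALSE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("`", name, "` contains non-ACGTN characters", call. = FALSE)
  x
}
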