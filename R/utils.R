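# Small sequence utilities shared across modules. Sequences are plain
# uppercase character scalars; coordinates are 0-based half-open internally
# and converted to 1-based only at I/O boundaries.

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

# Longest run of one repeated base.
max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  if (length(r$lengths) == 0L) return(0L)
  max(r$lengths)
}

# Longest perfect dinucleotide repeat, in repeat units, over all frames and
# all two-base motifs with distinct bases (e.g. "ATATATAT" -> 4).
max_dinuc_units <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(if (n >= 2L) 1L else 0L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  best <- 1L
  for (frame in c(1L, 2L)) {
    idx <- seq.int(frame, n - 1L, by = 2L)
    pairs <- paste0(chars[idx], chars[idx + 1L])
    r <- rle(pairs)
    keep <- substr(r$values, 1, 1) != substr(r$values, 2, 2)
    if (any(keep)) best <- max(best, r$lengths[keep])
  }
  as.integer(best)
}

# 0-based half-open substring.
substr0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

`%||%` <- function(a, b) if (is.null(a)) b else a
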