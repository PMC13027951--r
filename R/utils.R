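# Small shared helpers. All sequence strings are plain upper-case character
# scalars over {A,C,G,T,N}; gaps ("-") appear only in alignments.

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N, case kept).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# round-half-up, as printed tables do (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# positions of a 1-based inclusive interval on a circle of length L;
# s > e means the interval wraps the origin
circ_positions <- function(s, e, L) {
  if (s <= e) s:e else c(s:L, 1:e)
}

# length of the gap strictly between position `from_end` and `to_start`,
# walking forward on a circle of length L (0 when adjacent)
circ_gap <- function(from_end, to_start, L) {
  (to_start - from_end - 1L) %% L
}

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards; keeps all simulator randomness seed-local
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# split a CDS / alignment row into codon strings
split_codons <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
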