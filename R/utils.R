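# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes mapped to the base sets they denote.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

norm_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !is.character(seq))
    stop(what, " must be a single character string", call. = FALSE)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), names(IUPAC_SETS))
  if (length(bad))
    stop("non-IUPAC symbols in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  s
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  s <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  paste(rev(seq_chars(s)), collapse = "")
}

# Extract a subsequence on the circle; end < start wraps through the origin.
circ_subseq <- function(seq, start, end) {
  n <- nchar(seq)
  if (start < 1L || start > n || end < 1L || end > n)
    stop("coordinates outside [1, ", n, "]", call. = FALSE)
  if (end >= start) substr(seq, start, end)
  else paste0(substr(seq, start, n), substr(seq, 1L, end))
}

# Split a string into consecutive triplets, dropping a trailing partial.
triplets <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
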