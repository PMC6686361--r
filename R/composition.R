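#' Base composition and strand-skew statistics of a sequence
#'
#' Counts A, C, G, T (ambiguity codes, including `N`, are excluded from all
#' denominators) and computes per-base percentages, the A+T percentage, and
#' the strand-asymmetry skews `AT-skew = (A - T)/(A + T)` and
#' `GC-skew = (G - C)/(G + C)`. A skew whose denominator is zero is `NA`.
#' When more than 1% of the sequence is ambiguous a warning reports the
#' fraction excluded.
#'
#' @param seq nucleotide string.
#' @return Object of class `"composition_profile"`: list with `counts`
#'   (named integer, A/C/G/T), `n` (unambiguous bases), `freqs` (named
#'   percentages), `at_percent`, `at_skew`, `gc_skew`.
#' @examples
#' composition("ACGT")$at_skew   # 0
#' composition("AAAT")$at_skew   # 0.5
#' @export
composition <- function(seq) {
  s <- norm_seq(seq)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  ch <- seq_chars(s)
  counts <- vapply(DNA_BASES, function(b) sum(ch == b), integer(1))
  n <- sum(counts)
  n_amb <- length(ch) - n
  if (n_amb / length(ch) > 0.01)
    warning(sprintf("%.1f%% of bases are ambiguous and excluded",
                    100 * n_amb / length(ch)))
  if (n == 0L) stop("sequence contains no unambiguous bases", call. = FALSE)
  freqs <- 100 * counts / n
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(
    list(counts = counts, n = n, freqs = freqs,
         at_percent = 100 * at / n,
         at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at
                   else NA_real_,
         gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc
                   else NA_real_),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "%d bp: A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%  A+T %.2f%%\n",
    x$n, x$freqs[["A"]], x$freqs[["C"]], x$freqs[["G"]], x$freqs[["T"]],
    x$at_percent))
  cat(sprintf("AT-skew %.3f  GC-skew %.3f\n", x$at_skew, x$gc_skew))
  invisible(x)
}

profile_row <- function(name, n_bp, p) {
  data.frame(
    name = name, length_bp = n_bp,
    A = p$freqs[["A"]], C = p$freqs[["C"]],
    G = p$freqs[["G"]], T = p$freqs[["T"]],
    at_percent = p$at_percent, at_skew = p$at_skew, gc_skew = p$gc_skew,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Composition and skew table per gene
#'
#' One row per protein-coding gene, rRNA, control region and pseudo-control
#' region, plus a `"13PCG"` row for the concatenated protein-coding genes
#' and an `"overall"` row for the whole genome. In the default `"h_strand"`
#' mode every feature is measured on the H-strand subsequence regardless of
#' its coding strand, so light-strand genes (ND6) show inverted skew signs
#' relative to heavy-strand genes; `"sense"` mode measures each gene as
#' transcribed.
#'
#' @param genome a [mitogenome] with sequence.
#' @param strand_mode `"h_strand"` (default) or `"sense"`.
#' @return data.frame with columns `name`, `length_bp`, `A`, `C`, `G`, `T`,
#'   `at_percent`, `at_skew`, `gc_skew`.
#' @export
skew_table <- function(genome, strand_mode = c("h_strand", "sense")) {
  stopifnot(inherits(genome, "mitogenome"))
  strand_mode <- match.arg(strand_mode)
  if (is.null(genome$sequence))
    stop("sequence required for skew_table", call. = FALSE)
  f <- genome$features
  keep <- f[f$type %in% c("PCG", "rRNA", "CR", "CCR"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    s <- circ_subseq(genome$sequence, keep$start[i], keep$end[i])
    if (strand_mode == "sense" && keep$strand[i] == "L") s <- revcomp(s)
    profile_row(keep$name[i], nchar(s), composition(s))
  })
  pcg <- keep[keep$type == "PCG", , drop = FALSE]
  pcg_seq <- paste(vapply(seq_len(nrow(pcg)), function(i) {
    s <- circ_subseq(genome$sequence, pcg$start[i], pcg$end[i])
    if (strand_mode == "sense" && pcg$strand[i] == "L") revcomp(s) else s
  }, character(1)), collapse = "")
  rows <- c(rows, list(
    profile_row(sprintf("%dPCG", nrow(pcg)), nchar(pcg_seq),
                composition(pcg_seq)),
    profile_row("overall", genome$genome_length,
                composition(genome$sequence))
  ))
  do.call(rbind, rows)
}

#' Base composition by codon position over all protein-coding genes
#'
#' Pools the sense-strand codons of every protein-coding gene (trailing
#' incomplete codons excluded) and profiles the bases at the first, second
#' and third codon positions separately.
#'
#' @param genome a [mitogenome] with sequence and PCG annotations.
#' @return Named list of three `"composition_profile"` objects
#'   (`pos1`, `pos2`, `pos3`).
#' @export
codon_position_composition <- function(genome) {
  codons <- unlist(extract_codons(genome, per_gene = TRUE), use.names = FALSE)
  pos_seq <- function(k)
    paste(substr(codons, k, k), collapse = "")
  list(pos1 = composition(pos_seq(1L)),
       pos2 = composition(pos_seq(2L)),
       pos3 = composition(pos_seq(3L)))
}
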