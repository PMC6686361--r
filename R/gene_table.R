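#' Length of a feature on a circular genome
#'
#' Coordinates are 1-based inclusive; `end < start` denotes a feature that
#' wraps across the origin, whose length is
#' `genome_length - start + 1 + end`.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param genome_length length of the circle in bp.
#' @return Integer vector of lengths in bp.
#' @examples
#' feature_length(1, 70, 17381)       # tRNA-Phe: 70
#' feature_length(11834, 13648, 17381) # ND5: 1815
#' feature_length(17380, 12, 17381)   # wraps the origin: 14
#' @export
feature_length <- function(start, end, genome_length) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L | start > genome_length | end < 1L |
          end > genome_length))
    stop("coordinates outside [1, ", genome_length, "]", call. = FALSE)
  ifelse(end >= start, end - start + 1L, genome_length - start + 1L + end)
}

#' Signed gap between two adjacent features on the circle
#'
#' Returns `start2 - end1 - 1` computed on the circle and centred into
#' `(-genome_length/2, genome_length/2]`: positive values are intergenic
#' spacers, negative values overlaps, zero means the features abut.
#'
#' @param end1 end coordinate of the upstream feature.
#' @param start2 start coordinate of the downstream feature.
#' @param genome_length length of the circle in bp.
#' @return Integer vector of signed gaps in bp.
#' @examples
#' neighbor_gap(16075, 16084, 17381)  # CR -> tRNA-Pro: +8
#' neighbor_gap(1055, 1037, 17381)    # 12S rRNA -> tRNA-Val: -19
#' neighbor_gap(17381, 1, 17381)      # closes the circle: 0
#' @export
neighbor_gap <- function(end1, start2, genome_length) {
  g <- (as.integer(start2) - as.integer(end1) - 1L) %% genome_length
  as.integer(ifelse(g > genome_length / 2, g - genome_length, g))
}

#' Classify start and stop codons of a protein-coding sense sequence
#'
#' The first triplet is the start codon. The stop is classified from the
#' length modulo 3: a full terminal triplet must be one of the vertebrate
#' mitochondrial stops (TAA, TAG, AGA, AGG); a single trailing `T` is the
#' incomplete stop `"T--"` and a trailing `TA` is `"TA-"`, both completed to
#' UAA by polyadenylation of the transcript. Anything else (including codons
#' containing `N`) yields `NA` with a warning.
#'
#' @param seq sense-strand nucleotide string(s) of the gene (vectorized).
#' @return data.frame with columns `start_codon` and `stop_codon`.
#' @examples
#' classify_codons("ATGGCCTAA")
#' @export
classify_codons <- function(seq) {
  res <- lapply(seq, function(s) {
    s <- norm_seq(s, "PCG sequence")
    n <- nchar(s)
    if (n < 6L)
      stop("malformed PCG: sequence shorter than 6 nt", call. = FALSE)
    start <- substr(s, 1L, 3L)
    if (grepl("[^ACGT]", start)) {
      warning("start codon contains ambiguous bases; reported as NA")
      start <- NA_character_
    }
    r <- n %% 3L
    stop_c <- if (r == 0L) {
      last <- substr(s, n - 2L, n)
      if (last %in% MITO_STOPS) last
      else {
        warning("terminal triplet '", last,
                "' is not a vertebrate mitochondrial stop codon")
        NA_character_
      }
    } else if (r == 1L) {
      if (substr(s, n, n) == "T") "T--"
      else {
        warning("frame remainder 1 but last base is not T; no stop assigned")
        NA_character_
      }
    } else {
      if (substr(s, n - 1L, n) == "TA") "TA-"
      else {
        warning("frame remainder 2 but trailing bases are not TA; ",
                "no stop assigned")
        NA_character_
      }
    }
    c(start, stop_c)
  })
  res <- do.call(rbind, res)
  data.frame(start_codon = res[, 1L], stop_codon = res[, 2L],
             stringsAsFactors = FALSE)
}

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Build the gene table of an annotated mitogenome
#'
#' One row per feature in start order, with its length, the signed gap to the
#' next feature around the circle (positive = intergenic spacer, negative =
#' overlap, attributed to the upstream feature of each pair; the last feature
#' pairs with the first), and — when the sequence is present — start/stop
#' codons for protein-coding genes and the A+T percentage of each feature.
#'
#' @param genome a [mitogenome]. A sequence is optional; without it the codon
#'   and A+T columns are `NA`.
#' @return data.frame of class `"gene_table"` with columns `name`, `type`,
#'   `strand`, `start`, `end`, `length_bp`, `start_codon`, `stop_codon`,
#'   `gap_to_next`, `at_percent`, and attribute `genome_length`.
#' @examples
#' tbl <- build_gene_table(mitogenome(gyps_features()))
#' sum(tbl$length_bp[tbl$type == "tRNA"])  # 1548
#' @export
build_gene_table <- function(genome) {
  stopifnot(inherits(genome, "mitogenome"))
  f <- genome$features
  L <- genome$genome_length
  n <- nrow(f)
  len <- feature_length(f$start, f$end, L)
  nxt <- c(seq_len(n)[-1L], 1L)
  gap <- neighbor_gap(f$end, f$start[nxt], L)

  start_codon <- rep(NA_character_, n)
  stop_codon <- rep(NA_character_, n)
  at_percent <- rep(NA_real_, n)
  if (!is.null(genome$sequence)) {
    for (i in seq_len(n)) {
      s <- feature_seq(genome, f$name[i])
      at_percent[i] <- composition(s)$at_percent
      if (f$type[i] == "PCG") {
        cc <- classify_codons(s)
        start_codon[i] <- cc$start_codon
        stop_codon[i] <- cc$stop_codon
      }
    }
  }
  out <- data.frame(
    name = f$name, type = f$type, strand = f$strand,
    start = f$start, end = f$end, length_bp = len,
    start_codon = start_codon, stop_codon = stop_codon,
    gap_to_next = gap, at_percent = at_percent,
    stringsAsFactors = FALSE
  )
  attr(out, "genome_length") <- L
  class(out) <- c("gene_table", "data.frame")
  out
}

#' @export
print.gene_table <- function(x, ...) {
  cat("Gene table: ", nrow(x), " features on a ",
      format(attr(x, "genome_length"), big.mark = ","),
      " bp circle\n", sep = "")
  y <- as.data.frame(x)
  y$at_percent <- round(y$at_percent, 1)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Summarize intergenic spacers and gene overlaps
#'
#' Spacers are rows of the gene table with a positive gap to the next
#' feature, overlaps rows with a negative gap; totals sum magnitudes.
#'
#' @param tbl a `"gene_table"` from [build_gene_table()].
#' @return List with `n_spacers`, `total_spacer_bp`, `longest_spacer`
#'   (`bp`, `upstream`, `downstream`), `n_overlaps`, `total_overlap_bp`,
#'   `longest_overlap` (same shape). The longest-element entries are `NULL`
#'   when no spacer/overlap exists.
#' @examples
#' spacer_overlap_summary(build_gene_table(mitogenome(gyps_features())))
#' @export
spacer_overlap_summary <- function(tbl) {
  stopifnot(inherits(tbl, "gene_table"))
  nxt <- c(tbl$name[-1L], tbl$name[1L])
  pick <- function(idx, sign) {
    if (!length(idx)) return(NULL)
    i <- idx[which.max(sign * tbl$gap_to_next[idx])]
    list(bp = abs(tbl$gap_to_next[i]), upstream = tbl$name[i],
         downstream = nxt[i])
  }
  sp <- which(tbl$gap_to_next > 0L)
  ov <- which(tbl$gap_to_next < 0L)
  list(
    n_spacers = length(sp),
    total_spacer_bp = sum(tbl$gap_to_next[sp]),
    longest_spacer = pick(sp, 1),
    n_overlaps = length(ov),
    total_overlap_bp = sum(-tbl$gap_to_next[ov]),
    longest_overlap = pick(ov, -1)
  )
}
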