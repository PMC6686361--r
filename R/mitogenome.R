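#' Construct an annotated circular mitogenome record
#'
#' Bundles an (optional) H-strand nucleotide sequence with an ordered feature
#' annotation. Coordinates are 1-based inclusive on the heavy strand; a
#' feature whose `end` is smaller than its `start` wraps across the origin of
#' the circle. Features on the light strand keep H-strand coordinates; their
#' sense sequence is obtained by reverse complement at extraction time.
#'
#' @param features data.frame with columns `name`, `type` (one of `"PCG"`,
#'   `"tRNA"`, `"rRNA"`, `"CR"`, `"CCR"`), `start`, `end` (1-based inclusive)
#'   and `strand` (`"H"` or `"L"`). Duplicate tRNA names (the two serine and
#'   two leucine tRNAs) must already carry disambiguating suffixes.
#' @param sequence optional H-strand nucleotide string (IUPAC alphabet;
#'   `U` is accepted and mapped to `T`).
#' @param genome_length total length of the circle in bp. Defaults to
#'   `nchar(sequence)` when a sequence is given, otherwise to the maximum
#'   `end` over non-wrapping features.
#' @return An object of class `"mitogenome"`: a list with elements
#'   `sequence` (or `NULL`), `genome_length`, `features` (sorted by start)
#'   and `circular` (always `TRUE`).
#' @examples
#' g <- mitogenome(gyps_features())
#' g
#' @export
mitogenome <- function(features, sequence = NULL, genome_length = NULL) {
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("empty annotation: at least one feature is required", call. = FALSE)
  need <- c("name", "type", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  features <- features[need]
  features$name <- as.character(features$name)
  features$type <- as.character(features$type)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  if (!all(features$type %in% c("PCG", "tRNA", "rRNA", "CR", "CCR")))
    stop("feature type must be one of PCG, tRNA, rRNA, CR, CCR",
         call. = FALSE)
  if (!all(features$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'", call. = FALSE)
  if (anyDuplicated(features$name))
    stop("feature names must be unique (suffix duplicated tRNAs, e.g. ",
         "tRNA-Ser1/tRNA-Ser2)", call. = FALSE)

  if (!is.null(sequence)) sequence <- norm_seq(sequence)
  if (is.null(genome_length)) {
    genome_length <- if (!is.null(sequence)) nchar(sequence)
    else max(features$end[features$end >= features$start])
  }
  genome_length <- as.integer(genome_length)
  if (!is.null(sequence) && nchar(sequence) != genome_length)
    stop("genome_length (", genome_length, ") != sequence length (",
         nchar(sequence), ")", call. = FALSE)
  if (any(features$start < 1L | features$start > genome_length |
          features$end < 1L | features$end > genome_length))
    stop("feature coordinates outside [1, ", genome_length, "]",
         call. = FALSE)

  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(
    list(sequence = sequence, genome_length = genome_length,
         features = features, circular = TRUE),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("Circular mitogenome, ", format(x$genome_length, big.mark = ","),
      " bp, ", nrow(x$features), " features",
      if (is.null(x$sequence)) " (annotation only)", "\n", sep = "")
  tab <- table(factor(x$features$type,
                      levels = c("PCG", "tRNA", "rRNA", "CR", "CCR")))
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n",
      sep = "")
  invisible(x)
}

#' Sense-strand sequence of an annotated feature
#'
#' Extracts the feature's subsequence on the circle and reverse-complements
#' it for light-strand features, yielding the sequence as transcribed.
#'
#' @param genome a [mitogenome] with sequence.
#' @param name feature name.
#' @return Nucleotide string.
#' @export
feature_seq <- function(genome, name) {
  stopifnot(inherits(genome, "mitogenome"))
  if (is.null(genome$sequence))
    stop("sequence required: this mitogenome is annotation-only",
         call. = FALSE)
  i <- match(name, genome$features$name)
  if (is.na(i)) stop("no feature named '", name, "'", call. = FALSE)
  f <- genome$features[i, ]
  s <- circ_subseq(genome$sequence, f$start, f$end)
  if (f$strand == "L") revcomp(s) else s
}

#' Published annotation of the Gyps himalayensis mitogenome
#'
#' Feature coordinates of the Himalayan griffon mitochondrial genome
#' (GenBank KY594709; 17,381 bp): 13 protein-coding genes, 22 tRNAs, two
#' rRNAs, the control region and the pseudo-control region, in the
#' remnant-CCR raptor gene order. Coordinates are 1-based inclusive on the
#' heavy strand; ND6 and eight tRNAs lie on the light strand. The duplicated
#' serine and leucine tRNAs carry suffixes 1/2 in genome order.
#'
#' @return data.frame with columns `name`, `type`, `start`, `end`, `strand`.
#' @seealso [gyps_codon_counts()] for the matching codon-usage counts.
#' @export
gyps_features <- function() {
  df <- read.table(
    text = "
name type start end strand
tRNA-Phe tRNA 1 70 H
'12S rRNA' rRNA 71 1055 H
tRNA-Val tRNA 1037 1108 H
'16S rRNA' rRNA 1101 2730 H
tRNA-Leu1 tRNA 2711 2784 H
ND1 PCG 2794 3771 H
tRNA-Ile tRNA 3770 3841 L
tRNA-Gln tRNA 3855 3925 H
tRNA-Met tRNA 3925 3993 H
ND2 PCG 3994 5038 H
tRNA-Trp tRNA 5039 5110 H
tRNA-Ala tRNA 5112 5180 L
tRNA-Asn tRNA 5183 5255 L
tRNA-Cys tRNA 5258 5324 L
tRNA-Tyr tRNA 5324 5394 L
COXI PCG 5396 6946 H
tRNA-Ser1 tRNA 6938 7011 L
tRNA-Asp tRNA 7016 7084 H
COXII PCG 7087 7770 H
tRNA-Lys tRNA 7772 7843 H
ATP8 PCG 7844 8008 H
ATP6 PCG 7999 8682 H
COXIII PCG 8682 9464 H
tRNA-Gly tRNA 9466 9534 H
ND3 PCG 9535 9885 H
tRNA-Arg tRNA 9890 9958 H
ND4L PCG 9960 10256 H
ND4 PCG 10250 11626 H
tRNA-His tRNA 11627 11696 H
tRNA-Ser2 tRNA 11698 11762 H
tRNA-Leu2 tRNA 11763 11833 H
ND5 PCG 11834 13648 H
Cytb PCG 13661 14803 H
tRNA-Thr tRNA 14806 14873 H
'Control region' CR 14874 16075 H
tRNA-Pro tRNA 16084 16153 L
ND6 PCG 16176 16694 L
tRNA-Glu tRNA 16692 16762 L
'Pseudo-control region' CCR 16763 17381 H
", header = TRUE, stringsAsFactors = FALSE)
  df
}

# Start/stop codons of the 13 G. himalayensis PCGs as annotated on KY594709.
# "T--" marks the incomplete stop completed by polyadenylation.
gyps_pcg_codons <- function() {
  data.frame(
    name  = c("ND1", "ND2", "COXI", "COXII", "ATP8", "ATP6", "COXIII",
              "ND3", "ND4L", "ND4", "ND5", "Cytb", "ND6"),
    start = c("ATG", "ATG", "GTG", "ATG", "ATG", "ATG", "ATG",
              "ATT", "ATG", "ATG", "ATG", "ATG", "ATT"),
    stop  = c("AGG", "T--", "AGG", "TAA", "TAA", "TAA", "TAA",
              "TAA", "TAA", "TAA", "TAA", "TAA", "TAG"),
    stringsAsFactors = FALSE
  )
}

#' Published codon-usage counts of the Gyps himalayensis mitogenome
#'
#' The 64 codon counts pooled over the 13 protein-coding genes of the
#' Himalayan griffon mitogenome (GenBank KY594709), 3,765 codons in total,
#' under the vertebrate mitochondrial genetic code. Names use the RNA
#' alphabet.
#'
#' @return Named integer vector of length 64.
#' @seealso [rscu()], [codon_usage_table()].
#' @export
gyps_codon_counts <- function() {
  counts <- c(
    UUU = 188, UUC =  79, UUA = 137, UUG =  14,
    CUU = 169, CUC =  92, CUA = 144, CUG =  31,
    AUU = 269, AUC =  83, AUA = 139, AUG =  39,
    GUU =  63, GUC =  37, GUA =  63, GUG =  18,
    UCU =  59, UCC =  41, UCA = 137, UCG =   8,
    CCU =  20, CCC =  54, CCA = 117, CCG =   9,
    ACU =  69, ACC =  86, ACA = 127, ACG =   8,
    GCU =  73, GCC = 147, GCA =  94, GCG =   6,
    UAU =  59, UAC =  45, UAA =   3, UAG =   1,
    CAU =  27, CAC =  68, CAA =  79, CAG =   9,
    AAU =  64, AAC =  63, AAA =  74, AAG =   8,
    GAU =  29, GAC =  46, GAA =  64, GAG =  20,
    UGU =  17, UGC =  10, UGA =  95, UGG =  13,
    CGU =  13, CGC =  19, CGA =  38, CGG =   4,
    AGU =  21, AGC =  24, AGA =   1, AGG =   2,
    GGU =  45, GGC =  69, GGA =  73, GGG =  42
  )
  storage.mode(counts) <- "integer"
  counts
}
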