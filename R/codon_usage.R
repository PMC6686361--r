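#' The vertebrate mitochondrial genetic code
#'
#' Translation table 2: relative to the standard code, AUA encodes Met,
#' UGA encodes Trp, and AGA/AGG are stop codons, so the stop family has four
#' members (UAA, UAG, AGA, AGG) and serine keeps six codons.
#'
#' @return data.frame with columns `codon` (RNA alphabet) and `aa`
#'   (one-letter amino acid, `"*"` for stop), 64 rows in UCAG order.
#' @export
vertebrate_mito_code <- function() {
  b <- c("U", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- unlist(strsplit(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG", ""))
  data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
}

rna <- function(codon) chartr("T", "U", toupper(codon))
dna <- function(codon) chartr("U", "T", toupper(codon))

# codon (RNA) -> synonymous family members (RNA), under translation table 2
codon_families <- function() {
  code <- vertebrate_mito_code()
  split(code$codon, code$aa)
}

#' Count codons across the protein-coding genes of a mitogenome
#'
#' Each protein-coding gene is read on its sense strand from the start codon
#' in consecutive triplets; a trailing incomplete codon (1-2 nt, the
#' incomplete stop) is dropped. Counts are pooled over all genes unless
#' `per_gene = TRUE`.
#'
#' @param genome a [mitogenome] with sequence and PCG annotations.
#' @param per_gene if `TRUE`, return a named list of per-gene codon vectors
#'   (in gene order) instead of pooled counts.
#' @return Named integer vector over the 64 codons (RNA names), or a list of
#'   character vectors when `per_gene = TRUE`.
#' @examples
#' g <- mitogenome(data.frame(name = "orf", type = "PCG", start = 1, end = 9,
#'                            strand = "H"), sequence = "ATGGCCTAA")
#' cnt <- extract_codons(g)
#' cnt[cnt > 0]
#' @export
extract_codons <- function(genome, per_gene = FALSE) {
  stopifnot(inherits(genome, "mitogenome"))
  if (is.null(genome$sequence))
    stop("sequence required to extract codons", call. = FALSE)
  pcgs <- genome$features$name[genome$features$type == "PCG"]
  if (!length(pcgs))
    stop("empty annotation: no protein-coding genes", call. = FALSE)
  streams <- lapply(pcgs, function(nm) {
    s <- feature_seq(genome, nm)
    rna(triplets(s))
  })
  names(streams) <- pcgs
  if (per_gene) return(streams)
  all_codons <- vertebrate_mito_code()$codon
  tab <- table(factor(unlist(streams, use.names = FALSE),
                      levels = all_codons))
  counts <- as.integer(tab)
  names(counts) <- all_codons
  counts
}

check_counts <- function(counts) {
  all_codons <- vertebrate_mito_code()$codon
  if (is.null(names(counts)))
    stop("counts must be a named codon->count vector", call. = FALSE)
  names(counts) <- rna(names(counts))
  full <- setNames(rep(0L, 64L), all_codons)
  unknown <- setdiff(names(counts), all_codons)
  if (length(unknown))
    stop("unknown codons: ", paste(unknown, collapse = ", "), call. = FALSE)
  full[names(counts)] <- as.numeric(counts)
  full
}

#' Relative synonymous codon usage
#'
#' For a codon `c` in synonymous family `F`,
#' `RSCU(c) = count(c) / (mean count over F)`, so an unbiased family has
#' RSCU 1 for every member and family RSCU values sum to the family size.
#' Families follow the vertebrate mitochondrial code ([vertebrate_mito_code]);
#' the four stop codons form one family. A family with zero total yields
#' RSCU 0 for all members.
#'
#' @param counts named codon->count vector (RNA or DNA names; codons absent
#'   from the vector count as zero).
#' @return Named numeric vector of RSCU values over the 64 codons.
#' @examples
#' round(rscu(c(UUU = 188, UUC = 79))[["UUU"]], 2)  # 1.41
#' @export
rscu <- function(counts) {
  counts <- check_counts(counts)
  out <- setNames(numeric(64L), names(counts))
  for (fam in codon_families()) {
    tot <- sum(counts[fam])
    out[fam] <- if (tot > 0) counts[fam] / (tot / length(fam)) else 0
  }
  out
}

#' Codon percentages of total codon usage
#'
#' @param counts named codon->count vector.
#' @return Named numeric vector: `100 * count / total` per codon.
#' @export
codon_percentages <- function(counts) {
  counts <- check_counts(counts)
  tot <- sum(counts)
  if (tot == 0) stop("zero total codon count", call. = FALSE)
  100 * counts / tot
}

#' Amino-acid usage ranking
#'
#' Ranks amino-acid families (stop included, as `"*"`) by summed codon
#' count, descending, ties broken alphabetically, and reports the single
#' most frequent codon.
#'
#' @param counts named codon->count vector.
#' @return List with `ranking` (data.frame `aa`, `count`) and `top_codon`
#'   (name of the argmax codon).
#' @export
aa_usage <- function(counts) {
  counts <- check_counts(counts)
  fams <- codon_families()
  sums <- vapply(fams, function(f) sum(counts[f]), numeric(1))
  ord <- order(-sums, names(sums))
  list(
    ranking = data.frame(aa = names(sums)[ord], count = unname(sums[ord]),
                         stringsAsFactors = FALSE),
    top_codon = names(counts)[which.max(counts)]
  )
}

#' Full codon-usage table
#'
#' Combines counts, RSCU and percentages into one 64-row table in UCAG
#' codon order, RNA alphabet.
#'
#' @param counts named codon->count vector.
#' @return data.frame of class `"codon_usage"` with columns `codon`, `aa`,
#'   `count`, `rscu`, `percent` (unrounded; the print method shows RSCU to
#'   2 decimals and percentages to 2 decimals).
#' @examples
#' head(codon_usage_table(gyps_codon_counts()))
#' @export
codon_usage_table <- function(counts) {
  counts <- check_counts(counts)
  code <- vertebrate_mito_code()
  out <- data.frame(
    codon = code$codon, aa = code$aa,
    count = as.integer(counts[code$codon]),
    rscu = unname(rscu(counts)[code$codon]),
    percent = unname(codon_percentages(counts)[code$codon]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' @export
print.codon_usage <- function(x, ...) {
  y <- as.data.frame(x)
  y$rscu <- sprintf("%.2f", y$rscu)
  y$percent <- sprintf("%.2f", y$percent)
  cat("Codon usage (", sum(x$count), " codons, vertebrate mitochondrial ",
      "code)\n", sep = "")
  print(y, row.names = FALSE, ...)
  invisible(x)
}
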