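# Standard-format I/O and report writers.

#' Read a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, line breaks are ignored,
#' and any symbol outside the IUPAC nucleotide alphabet is an error.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- vapply(as.character(set), norm_seq, character(1))
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(vapply(seqs, norm_seq, character(1)))
  names(set) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a feature table
#'
#' Tab-separated, with header `name type start end strand`; coordinates are
#' 1-based inclusive.
#'
#' @param path file path.
#' @return data.frame suitable for [mitogenome()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "type", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("feature table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  df[need]
}

#' Write a feature table
#'
#' @param features feature data.frame (or a [mitogenome], whose features
#'   are written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (inherits(features, "mitogenome")) features <- features$features
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# GenBank flat-file feature keys -> feature types
GENBANK_TYPES <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   D_loop = "CR", misc_feature = "CCR")

#' Read a GenBank flat file into a mitogenome record
#'
#' A minimal reader for single-interval mitogenome records: parses the
#' FEATURES table (`CDS` -> PCG, `tRNA` -> tRNA, `rRNA` -> rRNA, `D-loop`
#' -> CR, `misc_feature` -> CCR; `complement(a..b)` -> strand L; coordinates
#' kept 1-based inclusive, with `/gene` or `/product` qualifiers as names)
#' and the ORIGIN sequence block. Join/multi-interval features are not
#' supported and raise an error.
#'
#' @param path file path.
#' @return A [mitogenome].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  o <- grep("^ORIGIN", lines)
  if (!length(o))
    stop("format error: GenBank record without ORIGIN block",
         call. = FALSE)
  f0 <- grep("^FEATURES", lines)
  if (!length(f0))
    stop("format error: GenBank record without FEATURES table",
         call. = FALSE)
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- norm_seq(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  feat_lines <- lines[(f0[1L] + 1L):(o[1L] - 1L)]
  key_idx <- grep("^ {5}\\S", feat_lines)
  feats <- list()
  for (j in seq_along(key_idx)) {
    i <- key_idx[j]
    block_end <- if (j < length(key_idx)) key_idx[j + 1L] - 1L
                 else length(feat_lines)
    parts <- strsplit(trimws(feat_lines[i]), "\\s+")[[1L]]
    key <- parts[1L]; loc <- parts[2L]
    type <- GENBANK_TYPES[sub("-", "_", key)]
    if (is.na(type)) next
    if (grepl("join|order", loc))
      stop("unsupported feature: multi-interval location '", loc, "'",
           call. = FALSE)
    strand <- if (grepl("^complement", loc)) "L" else "H"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) != 2L)
      stop("format error: cannot parse location '", loc, "'",
           call. = FALSE)
    qual <- paste(feat_lines[i:block_end], collapse = " ")
    name <- regmatches(qual,
                       regexpr('/(gene|product)="[^"]*"', qual))
    name <- if (length(name)) sub('^/[a-z]+="', "", sub('"$', "", name))
            else paste0(key, "_", nums[1L])
    feats[[length(feats) + 1L]] <- data.frame(
      name = name, type = unname(type), start = nums[1L], end = nums[2L],
      strand = strand, stringsAsFactors = FALSE)
  }
  if (!length(feats))
    stop("format error: no usable features", call. = FALSE)
  features <- do.call(rbind, feats)
  features$name <- make.unique(features$name, sep = "")
  mitogenome(features, sequence = sequence)
}

GENBANK_KEYS <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", CCR = "misc_feature")

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES with `/gene`
#' qualifiers, ORIGIN) that [read_genbank()] round-trips.
#'
#' @param genome a [mitogenome] with sequence.
#' @param path output path.
#' @param accession accession string for the LOCUS line.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path, accession = "SYNTHETIC") {
  stopifnot(inherits(genome, "mitogenome"))
  if (is.null(genome$sequence))
    stop("sequence required to write GenBank", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("LOCUS       %s %d bp    DNA     circular", accession,
     genome$genome_length)
  wr("FEATURES             Location/Qualifiers")
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    wr("     %-16s%s", GENBANK_KEYS[[f$type[i]]], loc)
    wr("                     /gene=\"%s\"", f$name[i])
  }
  wr("ORIGIN")
  s <- tolower(genome$sequence)
  for (p in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L),
                             nchar(chunk)))
    wr("%9d %s", p, paste(blocks, collapse = " "))
  }
  wr("//")
  invisible(path)
}

#' Run the full characterization pipeline on a mitogenome
#'
#' Convenience wrapper producing every report table: the gene table with
#' spacer/overlap summary, composition/skew tables, codon usage, codon
#' position composition, control-region motif scan and partition, and
#' pseudo-control-region decomposition.
#'
#' @param genome a [mitogenome] with sequence.
#' @param motif_library motif library for the CR scan
#'   (default [default_motif_library()]).
#' @param min_unit,max_unit,min_copies repeat-finder parameters passed to
#'   [decompose_ccr()].
#' @return List of class `"mito_characterization"` with elements
#'   `gene_table`, `spacers_overlaps`, `skew_table`, `codon_usage`,
#'   `codon_positions`, `cr_motifs`, `cr_partition` (or the partition
#'   error message), `ccr` (or `NULL` when no CCR is annotated), and
#'   `params`.
#' @export
characterize <- function(genome, motif_library = default_motif_library(),
                         min_unit = 5L, max_unit = 250L, min_copies = 2) {
  stopifnot(inherits(genome, "mitogenome"))
  tbl <- build_gene_table(genome)
  counts <- extract_codons(genome)
  cr_name <- genome$features$name[genome$features$type == "CR"]
  cr_motifs <- cr_partition <- NULL
  if (length(cr_name)) {
    cr_seq <- feature_seq(genome, cr_name[1L])
    cr_motifs <- scan_motifs(cr_seq, motif_library)
    cr_partition <- tryCatch(partition_cr(cr_seq, cr_motifs),
                             error = function(e) conditionMessage(e))
  }
  ccr_name <- genome$features$name[genome$features$type == "CCR"]
  ccr <- if (length(ccr_name))
    decompose_ccr(feature_seq(genome, ccr_name[1L]), min_unit, max_unit,
                  min_copies)
  structure(list(
    gene_table = tbl,
    spacers_overlaps = spacer_overlap_summary(tbl),
    skew_table = skew_table(genome),
    codon_usage = codon_usage_table(counts),
    codon_positions = codon_position_composition(genome),
    cr_motifs = cr_motifs,
    cr_partition = cr_partition,
    ccr = ccr,
    params = list(motif_library_version = attr(motif_library, "version"),
                  min_unit = min_unit, max_unit = max_unit,
                  min_copies = min_copies)
  ), class = "mito_characterization")
}

#' @export
print.mito_characterization <- function(x, ...) {
  cat("Mitogenome characterization\n")
  so <- x$spacers_overlaps
  cat(sprintf("  %d features; %d spacers (%d bp), %d overlaps (%d bp)\n",
              nrow(x$gene_table), so$n_spacers, so$total_spacer_bp,
              so$n_overlaps, so$total_overlap_bp))
  cat(sprintf("  %d codons counted; top codon %s\n", sum(x$codon_usage$count),
              x$codon_usage$codon[which.max(x$codon_usage$count)]))
  if (!is.null(x$ccr))
    cat(sprintf("  CCR: %d segments, %d repeat arrays\n",
                nrow(x$ccr$segments), nrow(x$ccr$repeats)))
  invisible(x)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), NA, formatC(round(x, digits), format = "f",
                               digits = digits))
}

#' Write characterization reports to a directory
#'
#' Writes deterministic TSV reports — `gene_table.tsv` (columns in the
#' conventional gene/position/size/codon/intergenic/strand/A+T order),
#' `skew_table.tsv`, `codon_usage.tsv`, `cr_motifs.tsv`,
#' `ccr_repeats.tsv` — plus `run_log.txt` recording the parameter set.
#' Percentages are written to 2 decimals and skews to 3.
#'
#' @param results a `"mito_characterization"` from [characterize()].
#' @param outdir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(results, outdir) {
  stopifnot(inherits(results, "mito_characterization"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L)
    stop("cannot write to directory: ", outdir, call. = FALSE)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    p
  }
  g <- as.data.frame(results$gene_table)
  gt <- data.frame(
    gene = g$name, from = g$start, to = g$end, size_bp = g$length_bp,
    codon_start = g$start_codon, codon_stop = g$stop_codon,
    intergenic_bp = g$gap_to_next, strand = g$strand,
    at_percent = fmt_num(g$at_percent, 1L), stringsAsFactors = FALSE)
  sk <- results$skew_table
  skt <- data.frame(
    gene = sk$name,
    a_percent = fmt_num(sk$A, 2L), c_percent = fmt_num(sk$C, 2L),
    g_percent = fmt_num(sk$G, 2L), t_percent = fmt_num(sk$T, 2L),
    at_percent = fmt_num(sk$at_percent, 2L),
    at_skew = fmt_num(sk$at_skew, 3L), gc_skew = fmt_num(sk$gc_skew, 3L),
    stringsAsFactors = FALSE)
  cu <- as.data.frame(results$codon_usage)
  cut <- data.frame(codon = cu$codon, aa = cu$aa, count = cu$count,
                    rscu = fmt_num(cu$rscu, 2L),
                    percent = fmt_num(cu$percent, 2L),
                    stringsAsFactors = FALSE)
  files <- c(
    wtsv(gt, "gene_table.tsv"),
    wtsv(skt, "skew_table.tsv"),
    wtsv(cut, "codon_usage.tsv"),
    wtsv(results$cr_motifs %||%
           data.frame(motif_name = character(0)), "cr_motifs.tsv"),
    wtsv(if (!is.null(results$ccr)) results$ccr$segments
         else data.frame(kind = character(0)), "ccr_repeats.tsv")
  )
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c(
    "mitochar run log",
    sprintf("motif_library: %s",
            results$params$motif_library_version %||% "none"),
    sprintf("repeat finder: min_unit=%d max_unit=%d min_copies=%s",
            results$params$min_unit, results$params$max_unit,
            format(results$params$min_copies)),
    sprintf("cr_partition: %s",
            if (is.character(results$cr_partition)) results$cr_partition
            else "DI/DII/DIII resolved")
  ), log_path)
  invisible(c(files, log_path))
}
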