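# Seeded synthetic-mitogenome generator with full ground truth.
#
# The generator emulates the architecture of a ~17 kb raptor mitogenome with
# a remnant pseudo-control region: 13 PCGs, 22 tRNAs, 2 rRNAs, CR and CCR in
# the published G. himalayensis layout (including its overlaps and spacers),
# strand-biased composition, planted CR motifs and planted CCR tandem-repeat
# cassettes. Every artifact is re-checked against its recorded truth before
# being returned.

MAX_REJECT <- 1000L

#' Random nucleotide sequence with given base frequencies
#'
#' @param n length in bp.
#' @param base_freqs named probabilities for A, C, G, T (normalized
#'   internally).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Nucleotide string of length `n`.
#' @export
random_sequence <- function(n, base_freqs = c(A = 0.25, C = 0.25, G = 0.25,
                                              T = 0.25), seed = NULL) {
  draw <- function() paste(sample(DNA_BASES, n, replace = TRUE,
                                  prob = base_freqs[DNA_BASES] /
                                    sum(base_freqs[DNA_BASES])),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Gene-order template of the synthetic generator
#'
#' Returns the ordered feature skeleton (name, type, strand, length and
#' signed gap to the next feature around the circle) of a mitogenome
#' layout. `"remnant_ccr_raptor"` is the G. himalayensis arrangement with
#' the pseudo-control region between tRNA-Glu and tRNA-Phe, reproducing the
#' published coordinates exactly; `"standard_avian"` is the common avian
#' order (tRNA-Thr, tRNA-Pro, ND6, tRNA-Glu, CR, no CCR) with the
#' rearranged tail abutting.
#'
#' @param template template name.
#' @return data.frame with columns `name`, `type`, `strand`, `length`,
#'   `gap_to_next`.
#' @export
mito_template <- function(template = c("remnant_ccr_raptor",
                                       "standard_avian")) {
  template <- match.arg(template)
  f <- gyps_features()
  L <- max(f$end)
  len <- feature_length(f$start, f$end, L)
  nxt <- c(seq_len(nrow(f))[-1L], 1L)
  gap <- neighbor_gap(f$end, f$start[nxt], L)
  t <- data.frame(name = f$name, type = f$type, strand = f$strand,
                  length = len, gap_to_next = gap,
                  stringsAsFactors = FALSE)
  if (template == "standard_avian") {
    t <- t[t$type != "CCR", , drop = FALSE]
    head_names <- t$name[seq_len(match("tRNA-Thr", t$name))]
    tail_names <- c("tRNA-Pro", "ND6", "tRNA-Glu", "Control region")
    t <- t[match(c(head_names, tail_names), t$name), , drop = FALSE]
    n <- nrow(t)
    t$gap_to_next[t$name %in% c("tRNA-Thr", tail_names)] <- 0L
    rownames(t) <- NULL
  }
  t
}

#' Configuration for the synthetic-mitogenome generator
#'
#' Defaults are the study conditions of the G. himalayensis mitogenome:
#' gene lengths, order, strands and signed gaps from its published
#' annotation; overall H-strand base frequencies from its published
#' composition (A 24.55, C 31.59, G 14.37, T 29.49 %) for tRNA/rRNA
#' content; protein-coding genes drawn from its published codon usage
#' (stops excluded for internal positions) with the annotated start and
#' stop codons planted; CR content with poly-C, TACAT/ATGTA, box and CSB
#' motifs planted at fixed offsets; CCR content as nr-CCR and two
#' tandem-repeat cassettes using the published repeat units, sized to the
#' 619 bp CCR (125 bp nr + 12 x 11 bp + 8 bp partial + 120 bp insert +
#' 5 x 44 bp + 14 bp partial).
#'
#' @param template gene-order template, see [mito_template()].
#' @param base_freqs named A/C/G/T probabilities for non-coding/structural
#'   RNA background (sense strand).
#' @param codon_freqs named probabilities over the 64 codons (RNA names)
#'   for internal PCG codons; stop-family codons are zeroed and the rest
#'   renormalized.
#' @param gene_lengths optional named overrides of feature lengths (bp).
#' @param gaps optional named overrides of the signed gap following a
#'   feature (named by the upstream feature).
#' @param cr_spec,ccr_spec layout of the control and pseudo-control
#'   regions; see [default_cr_spec()] and [default_ccr_spec()].
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(template = "remnant_ccr_raptor",
                             base_freqs = c(A = 0.2455, C = 0.3159,
                                            G = 0.1437, T = 0.2949),
                             codon_freqs = NULL,
                             gene_lengths = NULL, gaps = NULL,
                             cr_spec = default_cr_spec(),
                             ccr_spec = default_ccr_spec()) {
  layout <- mito_template(template)
  if (!is.null(gene_lengths)) {
    i <- match(names(gene_lengths), layout$name)
    if (anyNA(i)) stop("unknown feature in gene_lengths", call. = FALSE)
    layout$length[i] <- as.integer(gene_lengths)
  }
  if (!is.null(gaps)) {
    i <- match(names(gaps), layout$name)
    if (anyNA(i)) stop("unknown feature in gaps", call. = FALSE)
    layout$gap_to_next[i] <- as.integer(gaps)
  }
  if (is.null(codon_freqs)) {
    cnt <- gyps_codon_counts()
    cnt[codon_families()[["*"]]] <- 0L
    codon_freqs <- cnt / sum(cnt)
  } else {
    codon_freqs <- check_counts(codon_freqs)
    codon_freqs[codon_families()[["*"]]] <- 0
    codon_freqs <- codon_freqs / sum(codon_freqs)
  }
  bf <- base_freqs[DNA_BASES]
  if (anyNA(bf) || abs(sum(bf) - 1) > 0.01)
    stop("base_freqs must cover A, C, G, T and sum to 1", call. = FALSE)
  structure(
    list(template = template, layout = layout, base_freqs = bf / sum(bf),
         codon_freqs = codon_freqs, cr_spec = cr_spec,
         ccr_spec = ccr_spec),
    class = "generator_config"
  )
}

#' Default control-region layout for the generator
#'
#' A 1,202 bp CR with domain-I poly-C and palindromic motifs, central
#' F/E/D/C boxes and domain-III CSBs, at fixed offsets; background base
#' frequencies follow the published CR composition (T 33.1, C 25.9,
#' A 23.5, G 17.5 %).
#'
#' @param length CR length in bp.
#' @return List: `length`, `base_freqs`, `polyc` (`start`, `length`),
#'   `motifs` (named vector of start offsets for entries of the default
#'   motif library).
#' @export
default_cr_spec <- function(length = 1202L) {
  list(
    length = as.integer(length),
    base_freqs = c(A = 0.235, C = 0.259, G = 0.175, T = 0.331),
    polyc = list(start = 21L, length = 8L),
    motifs = c("TACAT" = 61L, "ATGTA" = 81L,
               "F-box" = 421L, "E-box" = 521L, "D-box" = 641L,
               "C-box" = 741L,
               "CSBa" = 861L, "CSBb" = 961L, "CSB1" = 1061L)
  )
}

#' Default pseudo-control-region layout for the generator
#'
#' The 619 bp CCR: a 125 bp 5' non-repetitive segment, 12 copies of the
#' 11 bp unit TCTTTTTTCAT plus its first 8 nt, a 120 bp insert, and 5
#' copies of a 44 bp unit plus its first 14 nt. Background base
#' frequencies follow the published CCR composition (T 35.2, C 21.5,
#' A 33.9, G 9.4 %).
#'
#' @return List: `base_freqs`, `segments` (list of `list(nr = <bp>)` or
#'   `list(unit =, copies =, partial =)` entries in 5'-to-3' order).
#' @export
default_ccr_spec <- function() {
  list(
    base_freqs = c(A = 0.339, C = 0.215, G = 0.094, T = 0.352),
    segments = list(
      list(nr = 125L),
      list(unit = "TCTTTTTTCAT", copies = 12L, partial = 8L),
      list(nr = 120L),
      list(unit = "CCCTAAACAAGTAATAATATAAGTAGATGAGCTATCTACAAAGC",
           copies = 5L, partial = 14L)
    )
  )
}

# draw one internal-codon stream (DNA alphabet, concatenated string)
draw_codons <- function(n, codon_freqs) {
  if (n == 0L) return("")
  paste(dna(sample(names(codon_freqs), n, replace = TRUE,
                   prob = codon_freqs)), collapse = "")
}

#' Generate a synthetic control region with planted motif truth
#'
#' Background bases are drawn from the layout's base frequencies; the
#' poly-C run
#' and every motif of the default library are spliced in at their planted
#' offsets. Accidental extra occurrences of any planted pattern (or of
#' C-runs of 4+) in the background are removed by targeted resampling, so
#' an exact-match scan recovers exactly the planted layout; resampling is
#' capped at 1,000 rounds.
#'
#' @param cr_spec see [default_cr_spec()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return List with `sequence` and `truth` (data.frame of planted motif
#'   positions, the poly-C run, and the implied DI/DII/DIII partition).
#' @export
generate_cr <- function(cr_spec = default_cr_spec(), seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, generate_cr(cr_spec, seed = NULL)))
  lib <- default_motif_library()
  pats <- setNames(vapply(lib$name, function(nm)
    norm_seq(lib$pattern[match(nm, lib$name)], "pattern"), character(1)),
    lib$name)
  plant <- cr_spec$motifs
  if (anyNA(match(names(plant), names(pats))))
    stop("cr_spec$motifs names must be motif-library entries",
         call. = FALSE)
  n <- cr_spec$length
  spans <- data.frame(
    start = c(cr_spec$polyc$start, unname(plant)),
    end = c(cr_spec$polyc$start + cr_spec$polyc$length - 1L,
            unname(plant) + nchar(pats[names(plant)]) - 1L))
  if (any(spans$end > n) || any(spans$start < 1L))
    stop("planted CR motifs fall outside the region", call. = FALSE)
  ord <- order(spans$start)
  if (any(spans$start[ord][-1L] <= spans$end[ord][-length(ord)]))
    stop("planted CR motifs overlap", call. = FALSE)

  ch <- seq_chars(random_sequence(n, cr_spec$base_freqs))
  ch[cr_spec$polyc$start:(cr_spec$polyc$start + cr_spec$polyc$length - 1L)] <-
    "C"
  for (nm in names(plant)) {
    p <- seq_chars(pats[[nm]])
    ch[plant[[nm]]:(plant[[nm]] + length(p) - 1L)] <- p
  }
  protected <- unlist(mapply(seq, spans$start, spans$end,
                             SIMPLIFY = FALSE))
  non_c <- c("A", "G", "T")

  for (round in seq_len(MAX_REJECT)) {
    s <- paste(ch, collapse = "")
    offend <- integer(0)
    for (nm in names(pats)) {
      occ <- find_fixed(s, pats[[nm]])
      extra <- setdiff(occ, if (nm %in% names(plant)) plant[[nm]]
                       else integer(0))
      for (o in extra)
        offend <- c(offend, o:(o + nchar(pats[[nm]]) - 1L))
    }
    runs <- find_poly_c(s, min_run = 4L)
    want <- cr_spec$polyc
    for (i in seq_len(nrow(runs)))
      if (!(runs$start[i] == want$start &&
            runs$length[i] == want$length))
        offend <- c(offend, runs$start[i]:runs$end[i])
    offend <- setdiff(unique(offend), protected)
    if (!length(offend)) break
    if (round == MAX_REJECT)
      stop("config error: could not generate a clean CR background in ",
           MAX_REJECT, " rounds", call. = FALSE)
    for (o in offend)
      ch[o] <- if (ch[o] == "C") sample(non_c, 1L)
               else sample(setdiff(DNA_BASES, ch[o]), 1L)
  }

  motif_truth <- data.frame(
    motif_name = names(plant), pattern = unname(pats[names(plant)]),
    start = unname(plant),
    end = unname(plant) + nchar(pats[names(plant)]) - 1L,
    strand = "forward", stringsAsFactors = FALSE)
  central <- motif_truth[motif_truth$motif_name %in% cr_central_box_names, ]
  truth <- list(
    motifs = motif_truth,
    polyc = data.frame(start = cr_spec$polyc$start,
                       end = cr_spec$polyc$start + cr_spec$polyc$length - 1L,
                       length = cr_spec$polyc$length),
    partition = data.frame(
      domain = c("DI", "DII", "DIII"),
      start = c(1L, min(central$start), max(central$end) + 1L),
      end = c(min(central$start) - 1L, max(central$end), n),
      stringsAsFactors = FALSE)
  )
  list(sequence = paste(ch, collapse = ""), truth = truth)
}

#' Generate a synthetic pseudo-control region with planted repeat truth
#'
#' Assembles the layout's segments in order (non-repetitive stretches from
#' the background frequencies, tandem cassettes as exact unit copies plus a
#' trailing partial), then resamples non-repetitive content until
#' [find_tandem_repeats()] recovers exactly the planted arrays (no
#' accidental arrays, no boundary extension); capped at 1,000 rounds.
#'
#' @param ccr_spec see [default_ccr_spec()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return List with `sequence` and `truth` (`repeats`: the planted
#'   `"tandem_repeats"` table; `segments`: planted segment boundaries).
#' @export
generate_ccr <- function(ccr_spec = default_ccr_spec(), seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, generate_ccr(ccr_spec, seed = NULL)))
  segs <- ccr_spec$segments
  lens <- vapply(segs, function(sg) {
    if (!is.null(sg$nr)) as.integer(sg$nr)
    else {
      if (sg$copies < 2L) stop("cassette copies must be >= 2",
                               call. = FALSE)
      as.integer(sg$copies * nchar(sg$unit) + (sg$partial %||% 0L))
    }
  }, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  n <- sum(lens)
  is_nr <- vapply(segs, function(sg) !is.null(sg$nr), logical(1))
  planted <- do.call(rbind, lapply(which(!is_nr), function(i) {
    sg <- segs[[i]]
    u <- nchar(sg$unit)
    span <- lens[i]
    data.frame(start = starts[i], end = ends[i],
               unit = norm_seq(sg$unit, "repeat unit"), unit_len = u,
               copy_number = round(span / u, 1L),
               partial_len = span %% u,
               end_anchor = if ((starts[i] + ends[i]) / 2 <= n / 2)
                 "5prime" else "3prime",
               stringsAsFactors = FALSE)
  }))
  for (i in which(!is_nr))
    if (!is_primitive_unit(segs[[i]]$unit))
      stop("config error: repeat unit is not primitive: ", segs[[i]]$unit,
           call. = FALSE)
  max_u <- if (is.null(planted)) 250L else max(50L, 2L * max(planted$unit_len))

  build <- function() {
    parts <- lapply(seq_along(segs), function(i) {
      sg <- segs[[i]]
      if (!is.null(sg$nr)) random_sequence(sg$nr, ccr_spec$base_freqs)
      else paste0(strrep(norm_seq(sg$unit, "repeat unit"), sg$copies),
                  substr(sg$unit, 1L, sg$partial %||% 0L))
    })
    paste(unlist(parts), collapse = "")
  }
  for (round in seq_len(MAX_REJECT)) {
    s <- build()
    got <- find_tandem_repeats(s, min_unit = 5L, max_unit = max_u,
                               min_copies = 2)
    ok <- if (is.null(planted)) nrow(got) == 0L else
      nrow(got) == nrow(planted) &&
      all(got$start == planted$start) && all(got$end == planted$end) &&
      all(got$unit_len == planted$unit_len)
    if (ok) break
    if (round == MAX_REJECT)
      stop("config error: could not realize the planted repeat layout in ",
           MAX_REJECT, " rounds", call. = FALSE)
  }
  truth <- list(
    repeats = if (is.null(planted)) find_tandem_repeats(s, 5L, max_u)
              else {
                class(planted) <- c("tandem_repeats", "data.frame")
                planted
              },
    segments = data.frame(kind = ifelse(is_nr, "nr-CCR", "r-CCR"),
                          start = starts, end = ends, length = lens,
                          stringsAsFactors = FALSE)
  )
  list(sequence = s, truth = truth)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Lays the configured features onto the circle (reproducing the template's
#' overlaps and spacers), fills structural-RNA features with
#' strand-appropriate background, protein-coding genes with codons drawn
#' from the configured codon distribution framed by the annotated start and
#' stop codons (incomplete stops included), and the CR/CCR with their
#' planted layouts. After assembly every protein-coding gene's codon
#' classification is re-verified against the plan, and the emitted truth's
#' codon stream is the stream actually on the sequence.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return List with `genome` (a [mitogenome]) and `truth` (features,
#'   genome_length, per-PCG `codon_stream` (RNA triplets), planted
#'   `pcg_codons`, `cr` and `ccr` truth with genome offsets, `base_freqs`).
#' @examples
#' \donttest{
#' sim <- generate_genome(generator_config(), seed = 1)
#' sim$genome
#' }
#' @export
generate_genome <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  lay <- config$layout
  n <- nrow(lay)

  # resolve CR/CCR lengths from their specs
  cr_len <- config$cr_spec$length
  lay$length[lay$type == "CR"] <- cr_len
  ccr_rows <- which(lay$type == "CCR")
  ccr <- NULL
  if (length(ccr_rows)) {
    ccr <- generate_ccr(config$ccr_spec)
    lay$length[ccr_rows] <- nchar(ccr$sequence)
  }

  # coordinates from lengths + signed gaps; the last gap closes the circle
  start <- integer(n); end <- integer(n)
  start[1L] <- 1L
  for (i in seq_len(n)) {
    end[i] <- start[i] + lay$length[i] - 1L
    if (i < n) start[i + 1L] <- end[i] + lay$gap_to_next[i] + 1L
  }
  L <- sum(lay$length) + sum(lay$gap_to_next)
  if (any(start < 1L) || any(end > L) ||
      any(lay$gap_to_next + pmin(lay$length, c(lay$length[-1L],
                                               lay$length[1L])) <= 0L))
    stop("config error: infeasible overlap/spacer plan (negative segment)",
         call. = FALSE)

  features <- data.frame(name = lay$name, type = lay$type,
                         start = start, end = end, strand = lay$strand,
                         stringsAsFactors = FALSE)
  ch <- seq_chars(random_sequence(L, config$base_freqs))
  write_span <- function(at_start, at_end, content, strand) {
    if (strand == "L") content <- revcomp(content)
    ch[at_start:at_end] <<- seq_chars(content)
  }

  # structural RNAs first, then CR/CCR, then PCGs (which own their edges)
  for (i in which(lay$type %in% c("tRNA", "rRNA")))
    write_span(start[i], end[i],
               random_sequence(lay$length[i], config$base_freqs),
               lay$strand[i])
  cr <- generate_cr(config$cr_spec)
  i_cr <- which(lay$type == "CR")
  write_span(start[i_cr], end[i_cr], cr$sequence, lay$strand[i_cr])
  if (length(ccr_rows))
    write_span(start[ccr_rows], end[ccr_rows], ccr$sequence,
               lay$strand[ccr_rows])

  plan <- gyps_pcg_codons()
  pcg_idx <- which(lay$type == "PCG")
  stop_tail <- function(stp) switch(stp, "T--" = "T", "TA-" = "TA", stp)
  for (i in pcg_idx) {
    p <- plan[match(lay$name[i], plan$name), ]
    if (is.na(p$name))
      stop("no codon plan for PCG '", lay$name[i], "'", call. = FALSE)
    tail <- stop_tail(p$stop)
    n_internal <- (lay$length[i] - 3L - nchar(tail))
    if (n_internal < 0L || n_internal %% 3L != 0L)
      stop("config error: length of ", lay$name[i],
           " incompatible with start/stop plan", call. = FALSE)
    sense <- paste0(p$start, draw_codons(n_internal %/% 3L,
                                         config$codon_freqs), tail)
    write_span(start[i], end[i], sense, lay$strand[i])
  }
  # fix-up pass: overlaps may have clobbered a PCG edge; rewrite edges
  for (i in pcg_idx) {
    p <- plan[match(lay$name[i], plan$name), ]
    tail <- stop_tail(p$stop)
    if (lay$strand[i] == "H") {
      ch[start[i]:(start[i] + 2L)] <- seq_chars(p$start)
      ch[(end[i] - nchar(tail) + 1L):end[i]] <- seq_chars(tail)
    } else {
      ch[(end[i] - 2L):end[i]] <- seq_chars(revcomp(p$start))
      ch[start[i]:(start[i] + nchar(tail) - 1L)] <-
        seq_chars(revcomp(tail))
    }
  }

  genome <- mitogenome(features, sequence = paste(ch, collapse = ""),
                       genome_length = L)

  # self-validation against the plan
  tbl <- build_gene_table(genome)
  stopifnot(sum(tbl$length_bp) + sum(tbl$gap_to_next) == L)
  got <- tbl[tbl$type == "PCG", c("name", "start_codon", "stop_codon")]
  want <- plan[match(got$name, plan$name), ]
  if (!all(got$start_codon == want$start) ||
      !all(got$stop_codon == want$stop))
    stop("config error: feature overlaps destroyed a planted codon; ",
         "adjust the overlap plan", call. = FALSE)
  cr_off <- start[i_cr] - 1L
  cr_truth <- cr$truth
  cr_truth$motifs$genome_start <- cr_truth$motifs$start + cr_off
  cr_truth$motifs$genome_end <- cr_truth$motifs$end + cr_off

  truth <- list(
    features = features, genome_length = L,
    codon_stream = extract_codons(genome, per_gene = TRUE),
    pcg_codons = plan,
    cr = cr_truth, cr_offset = cr_off,
    ccr = if (length(ccr_rows)) ccr$truth,
    ccr_offset = if (length(ccr_rows)) start[ccr_rows] - 1L,
    base_freqs = config$base_freqs
  )
  list(genome = genome, truth = truth)
}

#' Generate a synthetic alignment with planted site classes
#'
#' Builds an alignment column by column with exactly the requested number
#' of constant, parsimony-informative and singleton columns (allocated by
#' largest remainder from `class_mix`), shuffled into random order, with
#' the per-column truth labels recorded.
#'
#' @param n_taxa number of rows (>= 4 when informative columns are
#'   requested).
#' @param n_sites number of columns.
#' @param class_mix named proportions for `constant`, `informative`,
#'   `singleton`; must sum to 1.
#' @param seed integer seed.
#' @return List with `aln` (named character vector) and `truth` (list with
#'   `classes`, per-column labels, and `counts`).
#' @export
generate_alignment <- function(n_taxa, n_sites,
                               class_mix = c(constant = 0.5,
                                             informative = 0.3,
                                             singleton = 0.2),
                               seed) {
  mix <- class_mix[c("constant", "informative", "singleton")]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8)
    stop("class_mix must name constant/informative/singleton and sum to 1",
         call. = FALSE)
  if (n_taxa < 4L && mix[["informative"]] > 0)
    stop("config error: informative columns need at least 4 taxa",
         call. = FALSE)
  if (n_taxa < 2L) stop("need at least 2 taxa", call. = FALSE)
  counts <- floor(mix * n_sites)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    frac <- mix * n_sites - counts
    add <- order(-frac)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  with_seed(seed, {
    labels <- sample(rep(names(counts), counts))
    m <- matrix("", nrow = n_taxa, ncol = n_sites)
    for (j in seq_len(n_sites)) {
      m[, j] <- switch(labels[j],
        constant = rep(sample(DNA_BASES, 1L), n_taxa),
        singleton = {
          b <- sample(DNA_BASES, 2L)
          col <- rep(b[1L], n_taxa)
          col[sample(n_taxa, 1L)] <- b[2L]
          col
        },
        informative = {
          b <- sample(DNA_BASES, 2L)
          ks <- 2L:(n_taxa - 2L)
          k <- ks[sample.int(length(ks), 1L)]
          col <- rep(b[1L], n_taxa)
          col[sample(n_taxa, k)] <- b[2L]
          col
        })
    }
    aln <- setNames(apply(m, 1L, paste, collapse = ""),
                    paste0("taxon", seq_len(n_taxa)))
    list(aln = aln,
         truth = list(classes = labels, counts = as.list(counts)))
  })
}
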