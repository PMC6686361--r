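#' Find poly-C runs
#'
#' Maximal runs of consecutive `C` of at least `min_run` bases, as found at
#' the 5' end of domain I of avian control regions.
#'
#' @param region nucleotide string.
#' @param min_run minimum run length (>= 2).
#' @return data.frame with columns `start`, `end`, `length` (1-based
#'   inclusive positions within `region`), ordered by start; zero rows when
#'   no run qualifies.
#' @examples
#' find_poly_c("AACCCCCCAA", min_run = 4)  # one run at 3..8
#' @export
find_poly_c <- function(region, min_run = 4L) {
  if (min_run < 2L) stop("min_run must be >= 2", call. = FALSE)
  ch <- seq_chars(norm_seq(region))
  r <- rle(ch == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

find_fixed <- function(region, pattern) {
  m <- gregexpr(pattern, region, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find TACAT/ATGTA palindromic motif pairs
#'
#' Locates every occurrence of the conserved palindromic motifs
#' `5'-TACAT-3'` and `5'-ATGTA-3'` (ATGTA is the reverse complement of
#' TACAT) and pairs each TACAT with its nearest downstream ATGTA.
#'
#' @param region nucleotide string.
#' @return List with data.frames `tacat` and `atgta` (columns `start`,
#'   `end`) and `pairs` (columns `tacat_start`, `tacat_end`, `atgta_start`,
#'   `atgta_end`; one row per TACAT that has a downstream ATGTA).
#' @examples
#' find_palindrome_pairs("GTACATTTATGTAG")
#' @export
find_palindrome_pairs <- function(region) {
  region <- norm_seq(region)
  ta <- find_fixed(region, "TACAT")
  at <- find_fixed(region, "ATGTA")
  pairs <- do.call(rbind, lapply(ta, function(p) {
    dn <- at[at > p + 4L]
    if (!length(dn)) return(NULL)
    data.frame(tacat_start = p, tacat_end = p + 4L,
               atgta_start = dn[1L], atgta_end = dn[1L] + 4L)
  }))
  if (is.null(pairs))
    pairs <- data.frame(tacat_start = integer(0), tacat_end = integer(0),
                        atgta_start = integer(0), atgta_end = integer(0))
  list(tacat = data.frame(start = ta, end = ta + 4L),
       atgta = data.frame(start = at, end = at + 4L),
       pairs = pairs)
}

# does text base `t` match IUPAC pattern symbol `p`? (subset semantics:
# every base the text symbol could be must be allowed by the pattern symbol)
iupac_match_matrix <- function() {
  syms <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(syms), length(syms),
              dimnames = list(text = syms, pattern = syms))
  for (t in syms) for (p in syms)
    m[t, p] <- all(IUPAC_SETS[[t]] %in% IUPAC_SETS[[p]])
  m
}

#' Scan a region for motifs with mismatch tolerance
#'
#' Slides each IUPAC pattern over the region and reports every window with
#' at most the entry's allowed number of mismatching positions; overlapping
#' hits are all reported. Entries with `strand = "both"` are also scanned as
#' their reverse complement, reported with `strand = "reverse"` at forward
#' coordinates.
#'
#' @param region nucleotide string.
#' @param library data.frame with columns `name`, `pattern` (IUPAC),
#'   `max_mismatch` and `strand` (`"forward"` or `"both"`); defaults to
#'   [default_motif_library()].
#' @return data.frame of hits: `motif_name`, `pattern`, `start`, `end`,
#'   `strand`, `mismatches`, sorted by start.
#' @examples
#' scan_motifs("GGTACATGG",
#'             data.frame(name = "pal", pattern = "TAYAT",
#'                        max_mismatch = 0, strand = "forward"))
#' @export
scan_motifs <- function(region, library = default_motif_library()) {
  region <- norm_seq(region)
  ch <- seq_chars(region)
  n <- length(ch)
  mm_tab <- iupac_match_matrix()
  stopifnot(all(c("name", "pattern", "max_mismatch", "strand")
                %in% names(library)))
  hits <- list()
  for (i in seq_len(nrow(library))) {
    pats <- list(forward = norm_seq(library$pattern[i], "pattern"))
    if (identical(library$strand[i], "both"))
      pats$reverse <- revcomp(pats$forward)
    for (dir in names(pats)) {
      p <- seq_chars(pats[[dir]])
      m <- length(p)
      if (m == 0L) stop("empty pattern '", library$name[i], "'",
                        call. = FALSE)
      if (m > n) next
      nw <- n - m + 1L
      mism <- integer(nw)
      for (k in seq_len(m))
        mism <- mism + !mm_tab[ch[k:(nw + k - 1L)], p[k]]
      at <- which(mism <= library$max_mismatch[i])
      if (length(at))
        hits[[length(hits) + 1L]] <- data.frame(
          motif_name = library$name[i], pattern = library$pattern[i],
          start = at, end = at + m - 1L, strand = dir,
          mismatches = mism[at], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif_name = character(0), pattern = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default motif library for avian control regions
#'
#' Reads the motif library shipped with the package: the TACAT/ATGTA
#' palindromes, the four central conserved boxes (F, E, D, C) and the
#' conserved sequence blocks CSBa, CSBb and CSB1. The box and CSB sequences
#' are provisional placeholder consensi (synthetic; avian CR box sequences
#' vary and no single canonical sequence exists), intended to be edited for
#' the taxon at hand; the library version is recorded in the `version`
#' attribute and echoed in every report.
#'
#' @param path optional path to a library file, tab-separated with columns
#'   `name`, `pattern`, `max_mismatch`, `strand` and `#` comment lines.
#' @return data.frame with attribute `version`.
#' @export
default_motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motif_library.tsv",
                        package = "mitochar", mustWork = TRUE)
  first <- readLines(path, n = 1L)
  lib <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  attr(lib, "version") <- sub("^#\\s*", "", first)
  lib
}

cr_central_box_names <- c("F-box", "E-box", "D-box", "C-box")

#' Partition a control region into domains I, II and III
#'
#' Domain II (the conserved central domain) spans from the first to the last
#' hit of the central conserved boxes (F, E, D, C); domain I is everything
#' 5' of it and domain III everything 3'. At least one central-box hit and
#' one CSB-class hit are required to anchor the partition.
#'
#' @param cr control-region nucleotide string.
#' @param hits motif hits from [scan_motifs()].
#' @return Object of class `"cr_partition"`: data.frame with columns
#'   `domain`, `start`, `end`, `length` covering the CR contiguously.
#' @export
partition_cr <- function(cr, hits) {
  cr <- norm_seq(cr)
  n <- nchar(cr)
  central <- hits[hits$motif_name %in% cr_central_box_names, , drop = FALSE]
  csb <- hits[grepl("^CSB", hits$motif_name), , drop = FALSE]
  missing <- c(
    if (nrow(central) == 0L) "central conserved box (F/E/D/C)",
    if (nrow(csb) == 0L) "CSB-class hit"
  )
  if (length(missing))
    stop("partition undefined; missing anchors: ",
         paste(missing, collapse = "; "), call. = FALSE)
  d2s <- min(central$start)
  d2e <- max(central$end)
  out <- data.frame(
    domain = c("DI", "DII", "DIII"),
    start = c(1L, d2s, d2e + 1L),
    end = c(d2s - 1L, d2e, n),
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start + 1L
  class(out) <- c("cr_partition", "data.frame")
  out
}

#' Find perfect tandem-repeat arrays
#'
#' Detects maximal, non-extendable arrays of a perfectly repeated unit
#' (no internal mismatches), each reported once with its smallest primitive
#' unit. The copy number is the span divided by the unit length, rounded to
#' one decimal, so a trailing partial unit contributes fractionally — the
#' `"12.7 x (11)"` notation of control-region repeat reports. Arrays wholly
#' contained in a longer array are suppressed.
#'
#' @param region nucleotide string.
#' @param min_unit,max_unit unit-length search range in bp (`min_unit >= 2`).
#' @param min_copies minimum copies (span / unit length) for an array to be
#'   reported; must be >= 2.
#' @return data.frame of class `"tandem_repeats"`: columns `start`, `end`,
#'   `unit`, `unit_len`, `copy_number`, `partial_len`, `end_anchor`
#'   (`"5prime"`/`"3prime"` by which half of the region holds the array
#'   midpoint), sorted by start.
#' @examples
#' find_tandem_repeats("ATATATATAT", min_unit = 2)
#' @export
find_tandem_repeats <- function(region, min_unit = 5L, max_unit = 250L,
                                min_copies = 2) {
  region <- norm_seq(region)
  n <- nchar(region)
  if (min_unit < 2L) stop("min_unit must be >= 2", call. = FALSE)
  if (min_copies < 2) stop("min_copies must be >= 2", call. = FALSE)
  max_unit <- min(max_unit, n %/% 2L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      copy_number = numeric(0), partial_len = integer(0),
                      end_anchor = character(0))
  class(empty) <- c("tandem_repeats", "data.frame")
  if (max_unit < min_unit) return(empty)
  ch <- seq_chars(region)
  found <- list()
  for (u in min_unit:max_unit) {
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & (r$lengths + u) >= min_copies * u)
    for (j in ok) {
      start <- starts[j]
      span <- r$lengths[j] + u
      unit <- substr(region, start, start + u - 1L)
      if (!is_primitive_unit(unit)) next
      found[[length(found) + 1L]] <-
        list(start = start, end = start + span - 1L, unit = unit,
             unit_len = u, span = span)
    }
  }
  if (!length(found)) return(empty)
  # suppress arrays contained in a longer one (ties favour shorter units)
  spans <- vapply(found, `[[`, numeric(1), "span")
  ulens <- vapply(found, `[[`, numeric(1), "unit_len")
  ord <- order(-spans, ulens)
  kept <- list()
  for (i in ord) {
    a <- found[[i]]
    inside <- any(vapply(kept, function(b)
      a$start >= b$start && a$end <= b$end, logical(1)))
    if (!inside) kept[[length(kept) + 1L]] <- a
  }
  out <- do.call(rbind, lapply(kept, function(a) {
    data.frame(start = a$start, end = a$end, unit = a$unit,
               unit_len = a$unit_len,
               copy_number = round(a$span / a$unit_len, 1L),
               partial_len = a$span %% a$unit_len,
               end_anchor = if ((a$start + a$end) / 2 <= n / 2) "5prime"
                            else "3prime",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tandem_repeats", "data.frame")
  out
}

# TRUE unless the unit is itself a perfect tandem of a shorter unit
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u %/% 2L)) {
    if (u %% d != 0L) next
    if (strrep(substr(unit, 1L, d), u %/% d) == unit) return(FALSE)
  }
  TRUE
}

#' @export
print.tandem_repeats <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No tandem repeats found\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x)))
    cat(sprintf("%s-%.1f x (%d)  %s  [%d..%d]\n",
                if (x$end_anchor[i] == "5prime") "5'" else "3'",
                x$copy_number[i], x$unit_len[i], x$unit[i],
                x$start[i], x$end[i]))
  invisible(x)
}

#' Decompose a pseudo-control region into repetitive and non-repetitive
#' segments
#'
#' Runs [find_tandem_repeats()] and labels the gaps between and around the
#' repeat arrays as non-repetitive (`nr-CCR`) segments, so that the reported
#' segments tile the input exactly.
#'
#' @param ccr pseudo-control-region nucleotide string.
#' @inheritParams find_tandem_repeats
#' @return Object of class `"ccr_decomposition"`: list with `segments`
#'   (data.frame `kind` (`"nr-CCR"`/`"r-CCR"`), `start`, `end`, `length`,
#'   and for repeat segments `unit`, `unit_len`, `copy_number`,
#'   `partial_len`, `end_anchor`) and `repeats` (the `"tandem_repeats"`
#'   table).
#' @export
decompose_ccr <- function(ccr, min_unit = 5L, max_unit = 250L,
                          min_copies = 2) {
  ccr <- norm_seq(ccr)
  n <- nchar(ccr)
  reps <- find_tandem_repeats(ccr, min_unit, max_unit, min_copies)
  segs <- list()
  pos <- 1L
  add_nr <- function(s, e) data.frame(
    kind = "nr-CCR", start = s, end = e, length = e - s + 1L,
    unit = NA_character_, unit_len = NA_integer_, copy_number = NA_real_,
    partial_len = NA_integer_, end_anchor = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reps))) {
    if (reps$end[i] < pos) next   # swallowed by an earlier overlapping array
    if (reps$start[i] > pos)
      segs[[length(segs) + 1L]] <- add_nr(pos, reps$start[i] - 1L)
    seg_start <- max(reps$start[i], pos)
    segs[[length(segs) + 1L]] <- data.frame(
      kind = "r-CCR", start = seg_start, end = reps$end[i],
      length = reps$end[i] - seg_start + 1L, unit = reps$unit[i],
      unit_len = reps$unit_len[i], copy_number = reps$copy_number[i],
      partial_len = reps$partial_len[i], end_anchor = reps$end_anchor[i],
      stringsAsFactors = FALSE)
    pos <- reps$end[i] + 1L
  }
  if (pos <= n) segs[[length(segs) + 1L]] <- add_nr(pos, n)
  structure(list(segments = do.call(rbind, segs), repeats = reps),
            class = "ccr_decomposition")
}

#' @export
print.ccr_decomposition <- function(x, ...) {
  s <- x$segments
  cat("Pseudo-control region, ", max(s$end), " bp, ", nrow(s),
      " segments\n", sep = "")
  for (i in seq_len(nrow(s))) {
    if (s$kind[i] == "nr-CCR")
      cat(sprintf("  nr-CCR  %d..%d (%d bp)\n", s$start[i], s$end[i],
                  s$length[i]))
    else
      cat(sprintf("  r-CCR   %d..%d  %.1f x (%d)  %s\n", s$start[i],
                  s$end[i], s$copy_number[i], s$unit_len[i], s$unit[i]))
  }
  invisible(x)
}
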