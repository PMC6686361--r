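# Independent brute-force oracles and random-fixture builders used across
# the suite. Oracles deliberately re-derive results from first principles
# (tile-and-compare, per-position scans) rather than reusing package
# internals.

rand_seq <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# --- tandem repeats: exhaustive tile-and-compare over (start, unit_len) ---
oracle_tandem_repeats <- function(region, min_unit, max_unit,
                                  min_copies = 2) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  found <- list()
  for (u in min_unit:min(max_unit, n %/% 2L)) {
    for (i in seq_len(n - 2L * u + 1L)) {
      # left-maximality: the array must not extend by one to the left
      if (i > 1L && ch[i - 1L] == ch[i + u - 1L]) next
      unit <- ch[i:(i + u - 1L)]
      j <- 0L
      while (i + u + j <= n && ch[i + u + j] == unit[(j %% u) + 1L])
        j <- j + 1L
      span <- u + j
      if (span < min_copies * u) next
      # primitive unit?
      prim <- TRUE
      for (d in seq_len(u %/% 2L)) {
        if (u %% d != 0L) next
        if (all(unit == rep(unit[1:d], u %/% d))) { prim <- FALSE; break }
      }
      if (!prim) next
      found[[length(found) + 1L]] <-
        data.frame(start = i, end = i + span - 1L, unit_len = u,
                   span = span)
    }
  }
  if (!length(found)) return(data.frame(start = integer(0),
                                        end = integer(0),
                                        unit_len = integer(0)))
  df <- unique(do.call(rbind, found))
  # containment: keep only maximal arrays (ties favour shorter units)
  df <- df[order(-df$span, df$unit_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (a in seq_len(nrow(df))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(df))) {
      if (a == b || !keep[b]) next
      if (df$start[b] >= df$start[a] && df$end[b] <= df$end[a] &&
          !(df$start[b] == df$start[a] && df$end[b] == df$end[a] &&
            df$unit_len[b] < df$unit_len[a]))
        keep[b] <- FALSE
    }
  }
  df <- df[keep, c("start", "end", "unit_len")]
  df[order(df$start, df$unit_len), , drop = FALSE]
}

# --- motif scan: per-window position-by-position comparison ---
oracle_scan <- function(region, pattern, max_mismatch) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  ch <- strsplit(region, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(ch) - length(p) + 1L)) {
    mm <- 0L
    for (k in seq_along(p))
      if (!all(iupac[[ch[i + k - 1L]]] %in% iupac[[p[k]]])) mm <- mm + 1L
    if (mm <= max_mismatch) hits <- c(hits, i)
  }
  hits
}

# --- poly-C runs: linear scan ---
oracle_polyc <- function(region, min_run) {
  ch <- strsplit(region, "")[[1]]
  runs <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "C") {
      j <- i
      while (j < length(ch) && ch[j + 1L] == "C") j <- j + 1L
      if (j - i + 1L >= min_run)
        runs[[length(runs) + 1L]] <- c(start = i, end = j,
                                       length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) data.frame(start = integer(0), end = integer(0),
                                length = integer(0))
  else as.data.frame(do.call(rbind, runs))
}

# --- site classification: direct per-column tally ---
oracle_site_counts <- function(m) {
  res <- c(constant = 0L, variable = 0L, informative = 0L,
           singleton = 0L)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2L) next
    tab <- table(col)
    if (length(tab) == 1L) res["constant"] <- res["constant"] + 1L
    else {
      res["variable"] <- res["variable"] + 1L
      if (sum(tab >= 2L) >= 2L)
        res["informative"] <- res["informative"] + 1L
      else res["singleton"] <- res["singleton"] + 1L
    }
  }
  res
}

# --- random circular annotations with only adjacent pairwise overlaps ---
# (so that per-position occupancy counts equal the pairwise gap totals)
random_annotation <- function(n_feat = NULL, max_len = 2000L) {
  n_feat <- n_feat %||% sample(4:12, 1L)
  lens <- sample(20:120, n_feat, replace = TRUE)
  gaps <- integer(n_feat)
  for (i in seq_len(n_feat - 1L)) {
    prev_neg <- i > 1L && gaps[i - 1L] < 0L
    if (!prev_neg && runif(1) < 0.3) {
      cap <- min(lens[i], lens[i + 1L]) - 1L
      gaps[i] <- -sample(seq_len(max(cap %/% 2L, 1L)), 1L)
    } else gaps[i] <- sample(0:25, 1L)
  }
  gaps[n_feat] <- sample(0:25, 1L)   # closes the circle, no wrap overlap
  start <- integer(n_feat); end <- integer(n_feat)
  start[1L] <- 1L
  for (i in seq_len(n_feat)) {
    end[i] <- start[i] + lens[i] - 1L
    if (i < n_feat) start[i + 1L] <- end[i] + gaps[i] + 1L
  }
  L <- sum(lens) + sum(gaps)
  stopifnot(L <= max_len, L >= max(end))
  mitogenome(data.frame(
    name = paste0("f", seq_len(n_feat)), type = "tRNA",
    start = start, end = end, strand = "H",
    stringsAsFactors = FALSE), genome_length = L)
}

# per-position occupancy totals for an annotation without wrap features
oracle_occupancy <- function(genome) {
  cov <- integer(genome$genome_length)
  f <- genome$features
  for (i in seq_len(nrow(f)))
    cov[f$start[i]:f$end[i]] <- cov[f$start[i]:f$end[i]] + 1L
  c(spacer_bp = sum(cov == 0L), overlap_bp = sum(pmax(cov - 1L, 0L)))
}
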