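test_that("poly-C runs are maximal runs above the threshold", {
  expect_equal(find_poly_c("AACCCCCCAA", min_run = 4),
               data.frame(start = 3L, end = 8L, length = 6L))
  expect_equal(nrow(find_poly_c("ACACAC", min_run = 3)), 0L)
  expect_error(find_poly_c("ACGT", min_run = 1), "min_run")
  set.seed(51)
  for (i in 1:20) {
    s <- rand_seq(sample(30:300, 1), c(A = .2, C = .4, G = .2, T = .2))
    expect_equal(find_poly_c(s, 3), oracle_polyc(s, 3))
  }
})

test_that("TACAT/ATGTA palindromes pair with the nearest downstream partner", {
  pp <- find_palindrome_pairs("GTACATTTATGTAG")
  expect_equal(pp$pairs,
               data.frame(tacat_start = 2L, tacat_end = 6L,
                          atgta_start = 9L, atgta_end = 13L))
  # unpaired TACAT still reported
  pp2 <- find_palindrome_pairs("GGTACATGG")
  expect_equal(pp2$tacat$start, 3L)
  expect_equal(nrow(pp2$pairs), 0L)
  # ATGTA is the reverse complement of TACAT
  expect_equal(mitochar:::revcomp("TACAT"), "ATGTA")
  set.seed(52)
  for (i in 1:10) {
    bg <- gsub("TACAT|ATGTA", "GGGGG",
               rand_seq(200, c(A = .25, C = .25, G = .25, T = .25)))
    at <- sample(50:120, 1)
    s <- paste0(substr(bg, 1, at - 1), "TACAT",
                substr(bg, at + 5, at + 24), "ATGTA",
                substr(bg, at + 30, 200))
    pp <- find_palindrome_pairs(s)
    expect_equal(nrow(pp$pairs), 1L)
    expect_equal(pp$pairs$tacat_start, at)
    expect_equal(pp$pairs$atgta_start, at + 25L)
  }
})

test_that("motif scanning honours IUPAC codes and mismatch budgets", {
  lib1 <- data.frame(name = "pal", pattern = "TAYAT", max_mismatch = 0,
                     strand = "forward")
  h <- scan_motifs("GGTACATGG", lib1)
  expect_equal(h$start, 3L)
  expect_equal(h$mismatches, 0L)
  lib2 <- data.frame(name = "pal", pattern = "TACAT", max_mismatch = 1,
                     strand = "forward")
  h2 <- scan_motifs("GGTACGTGG", lib2)
  expect_equal(h2$start, 3L)
  expect_equal(h2$mismatches, 1L)
  # both strands
  lib3 <- data.frame(name = "pal", pattern = "TACAT", max_mismatch = 0,
                     strand = "both")
  h3 <- scan_motifs("GGATGTAGG", lib3)
  expect_equal(h3$strand, "reverse")
  expect_equal(h3$start, 3L)
  expect_error(scan_motifs("ACGT", data.frame(
    name = "bad", pattern = "AXG", max_mismatch = 0, strand = "forward")),
    "non-IUPAC")
})

test_that("motif scanning equals the brute-force sliding window", {
  set.seed(53)
  for (i in 1:15) {
    s <- rand_seq(sample(60:200, 1))
    pat <- rand_seq(sample(4:8, 1))
    mm <- sample(0:2, 1)
    lib <- data.frame(name = "p", pattern = pat, max_mismatch = mm,
                      strand = "forward")
    expect_equal(scan_motifs(s, lib)$start, oracle_scan(s, pat, mm))
  }
})

test_that("CR partition is anchored on the central boxes", {
  cr <- generate_cr(seed = 54)
  hits <- scan_motifs(cr$sequence)
  part <- partition_cr(cr$sequence, hits)
  expect_equal(as.data.frame(part)[, c("domain", "start", "end")],
               cr$truth$partition)
  expect_equal(sum(part$length), nchar(cr$sequence))
  # anchors missing: informative errors
  only_di <- hits[hits$motif_name %in% c("TACAT", "ATGTA"), ]
  expect_error(partition_cr(cr$sequence, only_di), "central conserved box")
  expect_error(partition_cr(cr$sequence, hits[0, ]), "missing anchors")
})

test_that("tandem repeats report primitive units with fractional copies", {
  tr <- find_tandem_repeats("ATATATATAT", min_unit = 2)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, "AT")
  expect_equal(tr$unit_len, 2L)
  expect_equal(tr$copy_number, 5.0)
  expect_equal(tr$partial_len, 0L)

  unit <- "TCTTTTTTCAT"
  arr <- paste0(strrep(unit, 12), substr(unit, 1, 8))
  s <- paste0(strrep("G", 30), arr, strrep("G", 30))
  tr2 <- find_tandem_repeats(s, min_unit = 5, max_unit = 50)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$unit, unit)
  expect_equal(tr2$copy_number, 12.7)   # 140/11
  expect_equal(tr2$partial_len, 8L)
  expect_equal(tr2$start, 31L)
})

test_that("every reported repeat re-verifies against the sequence", {
  set.seed(55)
  for (i in 1:10) {
    u <- rand_seq(sample(5:12, 1))
    if (!mitochar:::is_primitive_unit(u)) next
    s <- paste0(rand_seq(40), strrep(u, sample(3:6, 1)),
                substr(u, 1, sample(0:(nchar(u) - 1), 1)), rand_seq(40))
    tr <- find_tandem_repeats(s, min_unit = 3, max_unit = 30)
    for (j in seq_len(nrow(tr))) {
      span <- tr$end[j] - tr$start[j] + 1L
      tiled <- substr(strrep(tr$unit[j], span %/% tr$unit_len[j] + 1L),
                      1L, span)
      expect_equal(substr(s, tr$start[j], tr$end[j]), tiled)
      expect_true(mitochar:::is_primitive_unit(tr$unit[j]))
      expect_equal(tr$copy_number[j], round(span / tr$unit_len[j], 1))
      expect_equal(tr$partial_len[j], span %% tr$unit_len[j])
    }
  }
})

test_that("repeat finder equals exhaustive search on small regions", {
  set.seed(56)
  for (i in 1:40) {
    n <- sample(30:120, 1)
    s <- rand_seq(n)
    if (i %% 2 == 0) {  # plant an array in half the trials
      u <- rand_seq(sample(3:10, 1))
      pos <- sample(seq_len(max(n - 40, 1)), 1)
      s <- paste0(substr(s, 1, pos), strrep(u, sample(2:4, 1)),
                  substr(s, pos + 1, n))
    }
    got <- find_tandem_repeats(s, min_unit = 3, max_unit = 20)
    want <- oracle_tandem_repeats(s, 3, 20)
    expect_equal(got[, c("start", "end", "unit_len")],
                 want, ignore_attr = TRUE)
  }
})

test_that("CCR decomposition tiles the region", {
  ccr <- generate_ccr(seed = 57)
  d <- decompose_ccr(ccr$sequence)
  expect_equal(d$segments[, c("kind", "start", "end", "length")],
               ccr$truth$segments, ignore_attr = TRUE)
  expect_equal(sum(d$segments$length), nchar(ccr$sequence))
  expect_equal(d$repeats$copy_number, c(12.7, 5.3))
  expect_equal(d$repeats$end_anchor, c("5prime", "3prime"))
  # repeat-free region: one nr-CCR segment
  set.seed(58)
  plain <- generate_ccr(list(base_freqs = c(A = .3, C = .2, G = .2, T = .3),
                             segments = list(list(nr = 200L))))
  d2 <- decompose_ccr(plain$sequence)
  expect_equal(d2$segments$kind, "nr-CCR")
  expect_equal(d2$segments$length, 200L)
  # tiling holds on arbitrary random inputs too
  for (i in 1:10) {
    s <- rand_seq(sample(50:250, 1))
    d3 <- decompose_ccr(s, min_unit = 3, max_unit = 30)
    expect_equal(sum(d3$segments$length), nchar(s))
    expect_true(all(d3$segments$start[-1] ==
                      d3$segments$end[-nrow(d3$segments)] + 1L))
  }
})
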