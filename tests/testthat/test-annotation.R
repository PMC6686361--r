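test_that("feature lengths follow circular 1-based inclusive arithmetic", {
  expect_equal(feature_length(1, 70, 17381), 70L)
  expect_equal(feature_length(11834, 13648, 17381), 1815L)
  # wrap across the origin
  expect_equal(feature_length(17380, 12, 17381), 14L)
  expect_error(feature_length(0, 10, 100), "coordinates")
  expect_error(feature_length(5, 101, 100), "coordinates")
})

test_that("neighbor gaps are signed and close the circle", {
  expect_equal(neighbor_gap(16075, 16084, 17381), 8L)    # spacer
  expect_equal(neighbor_gap(1055, 1037, 17381), -19L)    # overlap
  expect_equal(neighbor_gap(100, 101, 17381), 0L)        # abutting
  expect_equal(neighbor_gap(17381, 1, 17381), 0L)        # wrap, abutting
  expect_equal(neighbor_gap(17375, 3, 17381), 8L)        # wrap spacer
  # gap 0 iff start2 == end1 + 1 (mod L)
  for (e in c(1L, 50L, 99L, 100L))
    expect_equal(neighbor_gap(e, e %% 100L + 1L, 100L), 0L)
})

test_that("start/stop codon classification handles complete and incomplete stops", {
  expect_equal(classify_codons("ATGGCCTAA"),
               data.frame(start_codon = "ATG", stop_codon = "TAA",
                          stringsAsFactors = FALSE))
  # AGA/AGG are stops under the vertebrate mitochondrial code
  expect_equal(classify_codons("GTGAAACCCAGG")$stop_codon, "AGG")
  # length mod 3 == 1 with terminal T: incomplete stop T--
  expect_equal(classify_codons("ATGGCCAAAT")$stop_codon, "T--")
  # length mod 3 == 2 with terminal TA: incomplete stop TA-
  expect_equal(classify_codons("ATGGCCAAATA")$stop_codon, "TA-")
  # non-stop terminal triplet: NA with a warning
  expect_warning(out <- classify_codons("ATGGCCAAACCC"), "stop")
  expect_true(is.na(out$stop_codon))
  # ambiguous start: NA with warning
  expect_warning(out <- classify_codons("ANGGCCTAA"), "ambiguous")
  expect_true(is.na(out$start_codon))
  expect_error(classify_codons("ATGA"), "malformed")
})

test_that("gene table reproduces the published G. himalayensis annotation", {
  g <- mitogenome(gyps_features())
  tbl <- build_gene_table(g)
  expect_s3_class(tbl, "gene_table")
  expect_equal(nrow(tbl), 39L)
  expect_equal(attr(tbl, "genome_length"), 17381L)
  expect_equal(tbl$length_bp[tbl$name == "ND5"], 1815L)
  expect_equal(tbl$length_bp[tbl$name == "12S rRNA"], 985L)
  expect_equal(tbl$length_bp[tbl$name == "Control region"], 1202L)
  expect_equal(tbl$gap_to_next[tbl$name == "Control region"], 8L)
  expect_equal(tbl$gap_to_next[tbl$name == "12S rRNA"], -19L)
  # last feature closes on the first
  expect_equal(tbl$gap_to_next[nrow(tbl)], 0L)
  # circular closure
  expect_equal(sum(tbl$length_bp) + sum(tbl$gap_to_next), 17381L)
})

test_that("annotation-only records omit codon and A+T columns", {
  tbl <- build_gene_table(mitogenome(gyps_features()))
  expect_true(all(is.na(tbl$start_codon)))
  expect_true(all(is.na(tbl$at_percent)))
})

test_that("a single feature spanning the whole circle abuts itself", {
  g <- mitogenome(data.frame(name = "only", type = "rRNA", start = 1,
                             end = 500, strand = "H"))
  tbl <- build_gene_table(g)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$gap_to_next, 0L)
})

test_that("spacer/overlap summary matches the published layout", {
  so <- spacer_overlap_summary(build_gene_table(mitogenome(gyps_features())))
  expect_equal(so$n_spacers, 17L)
  expect_equal(so$longest_spacer$bp, 22L)
  expect_equal(so$longest_spacer$upstream, "tRNA-Pro")
  expect_equal(so$longest_spacer$downstream, "ND6")
  expect_equal(so$longest_overlap$bp, 20L)
  expect_equal(so$longest_overlap$upstream, "16S rRNA")
})

test_that("features tiling the circle exactly give no spacers or overlaps", {
  g <- mitogenome(data.frame(
    name = paste0("f", 1:4), type = "tRNA",
    start = c(1, 101, 201, 301), end = c(100, 200, 300, 400),
    strand = "H"), genome_length = 400)
  so <- spacer_overlap_summary(build_gene_table(g))
  expect_equal(so$n_spacers, 0L)
  expect_equal(so$n_overlaps, 0L)
})

test_that("pairwise gap totals agree with per-position occupancy on random annotations", {
  set.seed(401)
  for (i in 1:30) {
    g <- random_annotation()
    tbl <- build_gene_table(g)
    expect_equal(sum(tbl$length_bp) + sum(tbl$gap_to_next),
                 g$genome_length)
    so <- spacer_overlap_summary(tbl)
    occ <- oracle_occupancy(g)
    expect_equal(so$total_spacer_bp, unname(occ["spacer_bp"]))
    expect_equal(so$total_overlap_bp, unname(occ["overlap_bp"]))
  }
})

test_that("mitogenome constructor validates its inputs", {
  expect_error(mitogenome(data.frame()), "empty annotation")
  f <- gyps_features()
  expect_error(mitogenome(f, sequence = "ACGT", genome_length = 17381),
               "genome_length")
  f2 <- f; f2$strand[1] <- "X"
  expect_error(mitogenome(f2), "strand")
  f3 <- rbind(f, f[1, ])
  expect_error(mitogenome(f3), "unique")
})
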