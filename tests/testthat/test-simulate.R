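test_that("the generator is deterministic in its seed", {
  a <- generate_genome(generator_config(), seed = 81)
  b <- generate_genome(generator_config(), seed = 81)
  c <- generate_genome(generator_config(), seed = 82)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth$codon_stream, b$truth$codon_stream)
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("default genomes follow the remnant-CCR raptor architecture", {
  sim <- generate_genome(generator_config(), seed = 83)
  f <- sim$genome$features
  expect_equal(nrow(f), 39L)
  expect_equal(sum(f$type == "PCG"), 13L)
  expect_equal(sum(f$type == "tRNA"), 22L)
  expect_equal(sum(f$type == "rRNA"), 2L)
  # ND6 and exactly 8 tRNAs on the light strand
  expect_equal(f$strand[f$name == "ND6"], "L")
  expect_equal(sum(f$strand == "L" & f$type == "tRNA"), 8L)
  tbl <- build_gene_table(sim$genome)
  expect_equal(tbl$gap_to_next[tbl$name == "tRNA-Pro"], 22L)
  expect_equal(sum(tbl$length_bp) + sum(tbl$gap_to_next),
               sim$genome$genome_length)
  # planted start/stop codons survive assembly, including incomplete stops
  pcg <- tbl[tbl$type == "PCG", ]
  plan <- mitochar:::gyps_pcg_codons()
  expect_equal(pcg$start_codon, plan$start[match(pcg$name, plan$name)])
  expect_equal(pcg$stop_codon, plan$stop[match(pcg$name, plan$name)])
})

test_that("the standard avian template drops the CCR and reorders the tail", {
  sim <- generate_genome(generator_config(template = "standard_avian"),
                         seed = 84)
  f <- sim$genome$features
  expect_equal(nrow(f), 38L)
  expect_equal(sum(f$type == "CCR"), 0L)
  ord <- f$name[order(f$start)]
  expect_equal(tail(ord, 4),
               c("tRNA-Pro", "ND6", "tRNA-Glu", "Control region"))
})

test_that("planted gap and length overrides are honoured; infeasible plans error", {
  cfg <- generator_config(gaps = c("tRNA-Pro" = 5L))
  sim <- generate_genome(cfg, seed = 85)
  tbl <- build_gene_table(sim$genome)
  expect_equal(tbl$gap_to_next[tbl$name == "tRNA-Pro"], 5L)
  bad <- generator_config(gaps = c("tRNA-Lys" = -5000L))
  expect_error(generate_genome(bad, seed = 85), "infeasible")
})

test_that("generated control regions carry their planted motif layout", {
  for (s in 86:95) {
    cr <- generate_cr(seed = s)
    runs <- find_poly_c(cr$sequence, min_run = 4)
    expect_equal(runs$start, cr$truth$polyc$start)
    expect_equal(runs$length, cr$truth$polyc$length)
    pp <- find_palindrome_pairs(cr$sequence)
    expect_equal(nrow(pp$pairs), 1L)
    hits <- scan_motifs(cr$sequence)
    exact <- hits[hits$mismatches == 0, ]
    expect_equal(exact$start, cr$truth$motifs$start)
    expect_equal(exact$motif_name, cr$truth$motifs$motif_name)
  }
})

test_that("generated CCRs decompose into their planted cassettes", {
  ccr <- generate_ccr(seed = 96)
  expect_equal(nchar(ccr$sequence), 619L)
  d <- decompose_ccr(ccr$sequence)
  expect_equal(nrow(d$segments), 4L)
  expect_equal(d$repeats$start, ccr$truth$repeats$start)
  expect_equal(d$repeats$unit_len, c(11L, 44L))
  expect_equal(d$repeats$copy_number, c(12.7, 5.3))
  # non-primitive planted units are rejected
  expect_error(generate_ccr(list(
    base_freqs = c(A = .25, C = .25, G = .25, T = .25),
    segments = list(list(nr = 50L),
                    list(unit = "ATAT", copies = 3L, partial = 0L))),
    seed = 97), "primitive")
})

test_that("synthetic alignments plant exact site-class counts", {
  al <- generate_alignment(6, 1000, c(constant = 0.5, informative = 0.3,
                                      singleton = 0.2), seed = 98)
  cs <- classify_sites(al$aln)
  expect_equal(cs$constant, 500L)
  expect_equal(cs$variable, 500L)
  expect_equal(cs$parsimony_informative, 300L)
  expect_equal(cs$singleton, 200L)
  expect_equal(cs$classes, al$truth$classes)
  # all-constant mix
  al2 <- generate_alignment(5, 40, c(constant = 1, informative = 0,
                                     singleton = 0), seed = 99)
  expect_equal(classify_sites(al2$aln)$variable, 0L)
  # informative columns need 4 taxa
  expect_error(generate_alignment(3, 10, c(constant = .5,
                                           informative = .5,
                                           singleton = 0), seed = 1),
               "4 taxa")
})

test_that("background sampling matches the requested base frequencies", {
  freqs <- c(A = 0.2455, C = 0.3159, G = 0.1437, T = 0.2949)
  s <- random_sequence(20000, freqs, seed = 100)
  cnt <- composition(s)$counts
  for (b in names(freqs)) {
    se <- sqrt(20000 * freqs[[b]] * (1 - freqs[[b]]))
    expect_lt(abs(cnt[[b]] - 20000 * freqs[[b]]), 3 * se)
  }
})
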