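sense_codon_list <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"]

test_that("count_sites matches the single-mutant enumeration oracle", {
  s <- count_sites("TTT")
  expect_equal(unname(s["N"]), 8 / 3, tolerance = 1e-12)
  expect_equal(unname(s["S"]), 1 / 3, tolerance = 1e-12)
  # a 4-fold degenerate third position contributes a full synonymous site
  expect_gte(unname(count_sites("GGG")["S"]), 1)

  for (cd in sample(sense_codon_list, 12)) {
    o <- oracle_codon_sites(cd)
    s <- count_sites(cd)
    expect_equal(unname(s["N"]), unname(o["N"]), tolerance = 1e-9)
    expect_equal(unname(s["S"]), unname(o["S"]), tolerance = 1e-9)
  }
})

test_that("site counts conserve N + S = 3L and ignore stops/Ns", {
  set.seed(31)
  for (i in 1:25) {
    L <- sample(1:120, 1)
    codons <- sample(sense_codon_list, L, replace = TRUE)
    s <- count_sites(codons)
    expect_equal(unname(s["N"] + s["S"]), 3 * L, tolerance = 1e-9)
    # reversal invariance
    expect_equal(count_sites(rev(codons)), s, tolerance = 1e-12)
  }
  expect_equal(unname(sum(count_sites(c("TAA", "NNN", "TTT")))), 3)
})

test_that("count_differences handles single and multi-step codon pairs", {
  d <- count_differences(list(target_codons = "TTT", subject_codons = "TTC"))
  expect_equal(unname(d), c(0, 1))
  d <- count_differences(list(target_codons = "TTT", subject_codons = "GTT"))
  expect_equal(unname(d), c(1, 0))
  # two-position difference: average over both pathways
  o <- oracle_pair_diffs("TTT", "GTC")
  d <- count_differences(list(target_codons = "TTT", subject_codons = "GTC"))
  expect_equal(unname(d["Nd"]), unname(o["Nd"]), tolerance = 1e-12)
  expect_equal(unname(d["Sd"]), unname(o["Sd"]), tolerance = 1e-12)

  # symmetry in the two sequences
  set.seed(13)
  for (i in 1:30) {
    c1 <- sample(sense_codon_list, 1); c2 <- sample(sense_codon_list, 1)
    d12 <- count_differences(list(target_codons = c1, subject_codons = c2))
    d21 <- count_differences(list(target_codons = c2, subject_codons = c1))
    expect_equal(d12, d21, tolerance = 1e-12)
  }
})

test_that("codon alignment drops gapped/partial codons and honours frame", {
  chrom <- paste0(strrep("C", 50), "ATGAAAGGGTTTCCC", strrep("C", 50))
  genome_seq <- chrom
  est <- psl_record("e", 15, 0, 15, "chr1", nchar(chrom), 50, 65, "+",
                    blockSizes = 15L, qStarts = 0L, tStarts = 50L)
  aln <- build_codon_alignment(data.frame(start = 50L, end = 65L), "+", 0L,
                               genome_seq, est, "ATGAAAGGGTTTCCC")
  expect_identical(aln$target_codons, c("ATG", "AAA", "GGG", "TTT", "CCC"))
  expect_identical(aln$subject_codons, aln$target_codons)

  # frame offset 2 discards the first two bases
  aln2 <- build_codon_alignment(data.frame(start = 50L, end = 65L), "+", 2L,
                                genome_seq, est, "ATGAAAGGGTTTCCC")
  expect_identical(aln2$target_codons, c("GAA", "AGG", "GTT", "TCC"))

  # an unaligned base mid-codon drops that codon only
  est_gap <- psl_record("e", 14, 0, 14, "chr1", nchar(chrom), 50, 65, "+",
                        blockSizes = c(7L, 7L), qStarts = c(0L, 7L),
                        tStarts = c(50L, 58L))
  aln3 <- build_codon_alignment(data.frame(start = 50L, end = 65L), "+", 0L,
                                genome_seq, est_gap, "ATGAAAGGGTTTCC")
  expect_identical(aln3$target_codons, c("ATG", "AAA", "TTT", "CCC"))

  expect_error(
    build_codon_alignment(data.frame(start = 50L, end = 52L), "+", 2L,
                          genome_seq, est, "ATGAAAGGGTTTCCC"),
    "no complete")
})

test_that("minus-strand codon alignment reverse-complements both sequences", {
  # minus-strand region: genome holds the reverse complement of the mRNA
  mrna <- "ATGAAAGGG"
  region_fwd <- revcomp_str <- chartr("ACGT", "TGCA",
                                      paste(rev(strsplit(mrna, "")[[1]]),
                                            collapse = ""))
  chrom <- paste0(strrep("C", 30), region_fwd, strrep("C", 30))
  est <- psl_record("e", 9, 0, 9, "chr1", nchar(chrom), 30, 39, "+",
                    blockSizes = 9L, qStarts = 0L, tStarts = 30L)
  aln <- build_codon_alignment(data.frame(start = 30L, end = 39L), "-", 0L,
                               chrom, est, region_fwd)
  expect_identical(aln$target_codons, c("ATG", "AAA", "GGG"))
  expect_identical(aln$subject_codons, aln$target_codons)
})

test_that("estimate_rates applies the Jukes-Cantor correction", {
  aln <- list(target_codons = c("TTT", "AAA"), subject_codons = c("TTT", "AAA"))
  est <- estimate_rates(aln)
  expect_identical(est$dn, 0)
  expect_identical(est$ds, 0)

  # closed form: p = 0.1 -> d = -0.75 log(1 - 0.4/3)
  p <- 0.1
  expect_equal(-0.75 * log(1 - 4 * p / 3), 0.10732563,
               tolerance = 1e-7)

  # pn = 0, ps > 0 (unsaturated) gives omega 0
  aln2 <- list(target_codons = c(rep("AAA", 20), "TTT"),
               subject_codons = c(rep("AAA", 20), "TTC"))
  est2 <- estimate_rates(aln2)
  expect_identical(est2$Nd, 0)
  expect_gt(est2$ds, 0)
  expect_identical(est2$omega, 0)

  # saturation flag at ps >= 3/4
  many <- rep("TTT", 2)
  div <- rep("TTC", 2)
  est3 <- estimate_rates(list(target_codons = many, subject_codons = div))
  expect_true(est3$saturated)
  expect_true(is.na(est3$ds))
})

test_that("fisher_exact_2x2 equals oracle and stats::fisher.test", {
  cases <- list(c(5, 45, 5, 45), c(0, 50, 0, 80), c(8, 12, 2, 78),
                c(1, 0, 0, 1), c(10, 0, 0, 10), c(3, 7, 9, 1))
  for (cs in cases) {
    p <- fisher_exact_2x2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, oracle_fisher_2x2(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(cs, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_identical(fisher_exact_2x2(5, 45, 5, 45), 1)
  expect_identical(fisher_exact_2x2(0, 50, 0, 80), 1)
})

test_that("p-values never decrease as tables approach independence", {
  # fixed margins: rows 20/80, column total 10; independence at a = 2
  ps <- vapply(0:10, function(a) fisher_exact_2x2(a, 20 - a, 10 - a,
                                                  70 + a), numeric(1))
  expect_true(all(diff(ps[1:3]) >= -1e-12))   # rising toward a = 2
  expect_true(all(diff(ps[3:11]) <= 1e-12))   # falling beyond it
})

test_that("rate-difference and neutrality tests build the right tables", {
  novel <- structure(list(N = 60, S = 20, Nd = 8, Sd = 2), class = "RateEstimate")
  flank <- structure(list(N = 180, S = 60, Nd = 2, Sd = 12), class = "RateEstimate")
  p <- fisher_rate_difference(novel, flank)
  expect_equal(unname(p["p_dn"]), oracle_fisher_2x2(8, 52, 2, 178),
               tolerance = 1e-12)
  expect_equal(unname(p["p_ds"]), oracle_fisher_2x2(2, 18, 12, 48),
               tolerance = 1e-12)

  # fractional counts are rounded half-up by default
  novel2 <- structure(list(N = 59.5, S = 20.4, Nd = 7.5, Sd = 2),
                      class = "RateEstimate")
  p2 <- fisher_rate_difference(novel2, flank)
  expect_equal(unname(p2["p_dn"]), oracle_fisher_2x2(8, 52, 2, 178),
               tolerance = 1e-12)

  nt <- test_neutrality(novel)
  expect_equal(nt$p, oracle_fisher_2x2(8, 52, 2, 18), tolerance = 1e-12)
  expect_identical(nt$direction, "omega>1")
  nt2 <- test_neutrality(structure(list(N = 60, S = 20, Nd = 1, Sd = 10),
                                   class = "RateEstimate"))
  expect_identical(nt2$direction, "omega<1")
  nt3 <- test_neutrality(structure(list(N = 60, S = 20, Nd = 0, Sd = 0),
                                   class = "RateEstimate"))
  expect_identical(nt3$p, 1)
  expect_identical(nt3$direction, "none")
})

test_that("flank concatenation follows transcript order and frame", {
  fx <- generate_fixture(fixture_spec(seed = 19, n_genes = 4, events = list(
    event_spec("cassette", "CDS", "VALID"),
    event_spec("cassette", "CDS", "VALID"))))
  cfg <- discovery_config()
  res <- run_discovery(cfg, fx$genome, fx$annotation, fx$subject_psl,
                       fx$target_psl)
  expect_length(res$candidates, 2)
  for (cc in res$candidates) {
    tx <- fx$annotation$transcripts[[cc$host_transcript]]
    fl <- concatenate_flanking(cc, tx, fx$genome)
    # fixture CDS segments have phase 0 at every junction
    expect_identical(fl$frame_offset, 0L)
    # the concatenated flanks translate without internal stops
    aa <- translate_in_frame(fl$seq, fl$frame_offset)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    # regions come from the two exons adjacent to the host intron
    k <- which(tx$introns$start == cc$host_intron[1])
    expect_true(all(fl$regions$start >= tx$exons$start[k]))
    expect_true(all(fl$regions$end <= tx$exons$end[k + 1]))
  }

  # UTR-only flank errors
  tx_nc <- transcript_model("tnc", "g", "chr1", "+",
                            data.frame(start = c(0L, 100L), end = c(50L, 150L)))
  cc <- res$candidates[[1]]
  expect_error(concatenate_flanking(cc, tx_nc, fx$genome), "non-coding")
})

test_that("planted substitution divergence is recovered exactly", {
  evs <- lapply(1:4, function(i) event_spec(
    "cassette", "CDS", "VALID",
    divergence = list(novel = c(syn = 0.02, nonsyn = 0.03),
                      flank = c(syn = 0.06, nonsyn = 0.005))))
  fx <- generate_fixture(fixture_spec(seed = 77, n_genes = 4, events = evs))
  cfg <- discovery_config()
  res <- run_discovery(cfg, fx$genome, fx$annotation, fx$subject_psl,
                       fx$target_psl)
  idx <- est_index(fx)
  for (cc in res$candidates) {
    rc <- compare_rates(cc, fx$annotation, fx$genome, idx$ests, fx$est_seqs)
    tr <- fx$truth[fx$truth$transcript == cc$host_transcript, ]
    expect_equal(rc$novel$Nd, tr$novel_Nd, tolerance = 1e-9)
    expect_equal(rc$novel$Sd, tr$novel_Sd, tolerance = 1e-9)
    expect_equal(rc$flanking$Nd, tr$flank_Nd, tolerance = 1e-9)
    expect_equal(rc$flanking$Sd, tr$flank_Sd, tolerance = 1e-9)
    expect_true(is.finite(rc$p_dn) && rc$p_dn >= 0 && rc$p_dn <= 1)
    expect_true(is.finite(rc$p_ds) && rc$p_ds >= 0 && rc$p_ds <= 1)
  }
})
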