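make_cassette_est <- function(qname, blocks, chrom = "chr1", tsize = 10000L) {
  sizes <- blocks$end - blocks$start
  psl_record(qName = qname, qSize = sum(sizes), qStart = 0L,
             qEnd = sum(sizes), tName = chrom, tSize = tsize,
             tStart = blocks$start[1], tEnd = blocks$end[nrow(blocks)],
             strand = "+", blockSizes = sizes,
             qStarts = cumsum(c(0L, sizes[-length(sizes)])),
             tStarts = blocks$start)
}

test_that("best_hit maximises matches minus mismatches with stable ties", {
  r1 <- psl_record("q", 600, 0, 500, "chr2", 1e4, 0, 500, "+",
                   blockSizes = 500L, qStarts = 0L, tStarts = 0L,
                   matches = 490, misMatches = 10)   # score 480
  r2 <- psl_record("q", 600, 0, 500, "chr1", 1e4, 100, 600, "+",
                   blockSizes = 500L, qStarts = 0L, tStarts = 100L,
                   matches = 480, misMatches = 10)   # score 470
  expect_identical(best_hit(list(r1, r2))$tName, "chr2")

  r3 <- psl_record("q", 600, 0, 500, "chr1", 1e4, 0, 500, "+",
                   blockSizes = 500L, qStarts = 0L, tStarts = 0L,
                   matches = 490, misMatches = 10)   # tie with r1
  expect_identical(best_hit(list(r1, r3))$tName, "chr1")
  expect_identical(best_hit(list(r1))$tName, "chr2")
  expect_error(best_hit(list()), "empty")
  expect_error(best_hit(list(r1, psl_record("other", 600, 0, 500, "chr1",
                                            1e4, 0, 500, "+",
                                            blockSizes = 500L, qStarts = 0L,
                                            tStarts = 0L))),
               "qName")
})

test_that("detect_candidates finds cassettes and retained introns with flags", {
  loc <- toy_coding_locus()
  cfg <- discovery_config()
  # exon1 [100,160), intron [160,460), exon2 [460,520): the 60-bp exons
  # bound flank overlap at 60
  est <- make_cassette_est("e1", data.frame(start = c(105L, 250L, 460L),
                                            end = c(160L, 340L, 515L)))
  cands <- detect_candidates(est, loc$annotation, loc$genome, cfg)
  expect_length(cands, 1)
  cc <- cands[[1]]
  expect_identical(cc$type, "cassette")
  expect_identical(c(cc$start, cc$end), c(250L, 340L))
  expect_true(cc$filter_flags[["length"]])     # 90 > 50
  expect_true(cc$filter_flags[["flank_overlap"]])  # 55 and 55
  expect_identical(cc$flank_overlaps, c(55L, 55L))

  # 50-bp middle block fails the strict length bound
  est50 <- make_cassette_est("e2", data.frame(start = c(105L, 250L, 460L),
                                              end = c(160L, 300L, 515L)))
  cc50 <- detect_candidates(est50, loc$annotation, loc$genome, cfg)[[1]]
  expect_false(cc50$filter_flags[["length"]])

  # retained intron: one block covering the entire intron plus flanks
  ri <- make_cassette_est("e3", data.frame(start = 105L, end = 515L))
  ccri <- detect_candidates(ri, loc$annotation, loc$genome, cfg)[[1]]
  expect_identical(ccri$type, "retained_intron")
  expect_identical(c(ccri$start, ccri$end), c(160L, 460L))
  expect_true(ccri$filter_flags[["flank_overlap"]])

  # an EST entirely within exons yields nothing
  none <- make_cassette_est("e4", data.frame(start = 105L, end = 155L))
  expect_length(detect_candidates(none, loc$annotation, loc$genome, cfg), 0)
})

test_that("flank overlap threshold is inclusive at 50 and fails at 49", {
  loc <- toy_coding_locus()
  cfg <- discovery_config()
  est49 <- make_cassette_est("e", data.frame(start = c(111L, 250L, 460L),
                                             end = c(160L, 340L, 510L)))
  cc <- detect_candidates(est49, loc$annotation, loc$genome, cfg)[[1]]
  expect_identical(cc$flank_overlaps[1], 49L)
  expect_false(cc$filter_flags[["flank_overlap"]])

  est50 <- make_cassette_est("e", data.frame(start = c(110L, 250L, 460L),
                                             end = c(160L, 340L, 510L)))
  cc <- detect_candidates(est50, loc$annotation, loc$genome, cfg)[[1]]
  expect_identical(cc$flank_overlaps, c(50L, 50L))
  expect_true(cc$filter_flags[["flank_overlap"]])
})

# Build a plus-strand locus whose intron is all "C" except planted splice
# dinucleotides around a candidate at [250,340).
splice_locus <- function(acceptor_at, donor_at, acceptor = "AG",
                         donor = "GT") {
  loc <- toy_coding_locus()
  chrom <- loc$genome[["chr1"]]
  plant <- function(chrom, pos0, di) {
    substr(chrom, pos0 + 1L, pos0 + 2L) <- di
    chrom
  }
  if (!is.na(acceptor_at)) chrom <- plant(chrom, acceptor_at, acceptor)
  if (!is.na(donor_at)) chrom <- plant(chrom, donor_at, donor)
  loc$genome <- structure(c(chr1 = chrom), class = "SequenceSet")
  loc
}

make_raw_cassette <- function(loc, s = 250L, e = 340L) {
  cc <- exonscout:::new_candidate("chr1", s, e, "cassette", "+", "txA",
                                  "geneA", c(160L, 460L), c(55L, 55L),
                                  "est1", "sp")
  cc$filter_flags["length"] <- TRUE
  cc$filter_flags["flank_overlap"] <- TRUE
  cc
}

test_that("splice refinement finds planted pairs and records shifts", {
  cfg <- discovery_config()
  # zero-shift plant: acceptor just before 250, donor just after 340
  loc <- splice_locus(248L, 340L)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$splice_class, "GT-AG")
  expect_identical(cc$boundary_shifts, c(0L, 0L))
  expect_true(cc$filter_flags[["splice_site"]])

  # planted at shifts (+3, -2)
  loc <- splice_locus(248L + 3L, 340L - 2L)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$boundary_shifts, c(3L, -2L))
  expect_identical(c(cc$start, cc$end), c(253L, 338L))

  # no pair anywhere in the window
  loc <- splice_locus(NA, NA)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$splice_class, "none")
  expect_false(cc$filter_flags[["splice_site"]])

  # canonical pair priority: GC-AG planted, GT absent
  loc <- splice_locus(248L, 340L, donor = "GC")
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$splice_class, "GC-AG")
  expect_true(cc$splice_canonical)

  # non-canonical fallback: GT-GG needs donor GT and acceptor GG
  loc <- splice_locus(248L, 340L, acceptor = "GG")
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$splice_class, "GT-GG")
  expect_false(cc$splice_canonical)
  cfg_canon <- discovery_config(allow_noncanonical = FALSE)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg_canon)
  expect_identical(cc$splice_class, "none")

  expect_error(
    refine_splice_sites(local({
      x <- make_raw_cassette(loc); x$type <- "retained_intron"; x
    }), loc$genome, cfg), "not a cassette")
})

test_that("splice window boundary: shift 10 accepted, 11 rejected", {
  cfg <- discovery_config()
  loc <- splice_locus(248L - 10L, 340L + 10L)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$boundary_shifts, c(-10L, 10L))
  expect_true(cc$filter_flags[["splice_site"]])

  loc <- splice_locus(248L - 11L, 340L + 11L)
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_false(cc$filter_flags[["splice_site"]])
})

test_that("smallest shift wins with ties to the lower coordinate", {
  cfg <- discovery_config()
  loc <- splice_locus(248L - 4L, 340L)
  # plant a second, farther acceptor
  chrom <- loc$genome[["chr1"]]
  substr(chrom, 248L + 6L + 1L, 248L + 6L + 2L) <- "AG"
  loc$genome <- structure(c(chr1 = chrom), class = "SequenceSet")
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$boundary_shifts[1], -4L)

  # exact tie at +/-5: the negative (lower-coordinate) shift wins
  loc <- splice_locus(248L - 5L, 340L)
  chrom <- loc$genome[["chr1"]]
  substr(chrom, 248L + 5L + 1L, 248L + 5L + 2L) <- "AG"
  loc$genome <- structure(c(chr1 = chrom), class = "SequenceSet")
  cc <- refine_splice_sites(make_raw_cassette(loc), loc$genome, cfg)
  expect_identical(cc$boundary_shifts[1], -5L)
})

test_that("frame criterion: mod-3 and premature stops on reconstructed CDS", {
  loc <- toy_coding_locus()
  cfg <- discovery_config()
  stopfree99 <- paste(rep("CTT", 33), collapse = "")
  chrom <- loc$genome[["chr1"]]
  substr(chrom, 251L, 349L) <- stopfree99
  loc$genome <- structure(c(chr1 = chrom), class = "SequenceSet")

  cc99 <- make_raw_cassette(loc, 250L, 349L)
  res <- check_cds_frame(cc99, loc$tx, loc$genome)
  expect_true(res$pass)

  cc100 <- make_raw_cassette(loc, 250L, 350L)
  res <- check_cds_frame(cc100, loc$tx, loc$genome)
  expect_false(res$frame_ok)
  expect_true(is.na(res$stop_ok))

  # in-frame TAA inside the insert: caught by full re-translation
  chrom2 <- loc$genome[["chr1"]]
  substr(chrom2, 251L + 45L, 253L + 45L) <- "TAA"
  g2 <- structure(c(chr1 = chrom2), class = "SequenceSet")
  res <- check_cds_frame(cc99, loc$tx, g2)
  expect_false(res$pass)

  # oracle: translate the reconstructed CDS independently
  cds_seq <- paste0(substr(chrom2, 101, 160),
                    substr(chrom2, 251, 349),
                    substr(chrom2, 461, 520))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  expect_true(any(stops < nchar(aa)))  # confirms a premature stop exists

  expect_error(
    check_cds_frame(cc99, transcript_model("tnc", "g", "chr1", "+",
                                           data.frame(start = 0L, end = 10L)),
                    loc$genome),
    "no CDS")
})

test_that("frame criterion catches junction-spanning stop codons", {
  # phase-1 insertion point: upstream CDS ends ...T | insert starts AA...
  # would form TAA across the junction if the insert length were kept mod 3
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  set.seed(17)
  # CDS: ATG + codons, exon1 carries 61 bases (phase 1 at intron)
  cds <- paste0("ATG", paste(sample(setdiff(sense, "TAA"), 40,
                                    replace = TRUE), collapse = ""), "TAA")
  e1 <- substr(cds, 1, 61)
  # force the last exon1 base to T so "T" + "AA..." spans the junction
  substr(e1, 61, 61) <- "T"
  e2 <- substr(cds, 62, 126)
  chrom <- paste0(strrep("C", 100), e1,
                  paste0("GT", strrep("C", 296), "AG"),
                  e2, strrep("C", 100))
  # exon1 [100,161), intron [161,461), exon2 [461,526)
  tx <- transcript_model("t", "g", "chr1", "+",
                         exons = data.frame(start = c(100L, 461L),
                                            end = c(161L, 526L)),
                         cds = data.frame(start = c(100L, 461L),
                                          end = c(161L, 526L)))
  insert <- paste0("AA", paste(rep("C", 97), collapse = ""))  # 99 bp
  substr(chrom, 252L, 350L) <- insert
  genome <- structure(c(chr1 = chrom), class = "SequenceSet")
  cc <- exonscout:::new_candidate("chr1", 251L, 350L, "cassette", "+", "t",
                                  "g", c(161L, 461L), c(55L, 55L),
                                  "est", "sp")
  res <- check_cds_frame(cc, tx, genome)
  expect_true(res$frame_ok)
  expect_false(res$stop_ok)  # TAA spans the upstream junction
})

test_that("novelty filter flags 1-bp overlaps with ESTs and any exon", {
  loc <- toy_coding_locus()
  cc <- make_raw_cassette(loc)  # [250,340) inside the intron
  # target EST block overlapping by exactly 1 bp
  tgt1 <- psl_record("t_est1", 50, 0, 50, "chr1", 1e4, 339, 389, "+",
                     blockSizes = 50L, qStarts = 0L, tStarts = 339L)
  out <- novelty_filter(list(cc), list(tgt1), loc$annotation)
  expect_length(out$known, 1)
  expect_length(out$novel, 0)

  out <- novelty_filter(list(cc), list(), loc$annotation)
  expect_length(out$novel, 1)
  expect_true(out$novel[[1]]$filter_flags[["novelty"]])

  # an exon of a different gene overlapping the candidate makes it known
  other <- transcript_model("tB", "geneB", "chr1", "+",
                            exons = data.frame(start = c(320L, 600L),
                                               end = c(360L, 700L)))
  ann2 <- build_annotation(list(loc$tx, other))
  out <- novelty_filter(list(cc), list(), ann2)
  expect_length(out$known, 1)
})

test_that("one EST with two intronic blocks yields one ASV with two exons", {
  # three annotated exons separated by two introns
  # layout: e1 [100,200) | i1 [200,500) | e2 [500,600) | i2 [600,900) |
  # e3 [900,1000); plant candidates in i1 [260,350) and i2 [660,750)
  base <- strrep("C", 1200)
  plant <- function(s, pos0, what) { substr(s, pos0 + 1, pos0 + nchar(what)) <- what; s }
  base <- plant(base, 200L, "GT"); base <- plant(base, 498L, "AG")
  base <- plant(base, 600L, "GT"); base <- plant(base, 898L, "AG")
  base <- plant(base, 258L, "AG"); base <- plant(base, 350L, "GT")
  base <- plant(base, 658L, "AG"); base <- plant(base, 750L, "GT")
  genome <- structure(c(chr1 = base), class = "SequenceSet")
  tx <- transcript_model("t", "g", "chr1", "+",
                         exons = data.frame(start = c(100L, 500L, 900L),
                                            end = c(200L, 600L, 1000L)))
  ann <- build_annotation(list(tx))
  est <- make_cassette_est("multi", data.frame(
    start = c(140L, 260L, 500L, 660L, 900L),
    end = c(200L, 350L, 600L, 750L, 960L)), tsize = 1200L)
  cfg <- discovery_config()
  res <- run_discovery(cfg, genome, ann, list(sp = list(est)), NULL)
  expect_length(res$candidates, 2)
  expect_length(res$asvs, 1)
  expect_length(res$asvs[[1]]$exon_ids, 2)
  # flank segments are the EST's non-novel blocks
  expect_identical(nrow(res$asvs[[1]]$flank_segments), 3L)

  # two ESTs with different flank extents: 2 ASVs, 1 unique exon
  est2 <- make_cassette_est("multi2", data.frame(
    start = c(150L, 260L, 500L),
    end = c(200L, 350L, 590L)), tsize = 1200L)
  res2 <- run_discovery(cfg, genome, ann,
                        list(sp = list(est, est2)), NULL)
  keys <- unique(vapply(res2$candidates, function(cc)
    paste(cc$start, cc$end), character(1)))
  expect_length(res2$asvs, 2)
  expect_true("260 350" %in% keys)
  expect_length(res2$candidates, 2)  # unique exons: [260,350) and [660,750)
})

test_that("accepted candidates revalidate against all criteria", {
  fx <- generate_fixture(fixture_spec(seed = 42, n_genes = 14,
                                      events = mixed_event_list()))
  cfg <- discovery_config()
  res <- run_discovery(cfg, fx$genome, fx$annotation, fx$subject_psl,
                       fx$target_psl)
  expect_gt(length(res$candidates), 0)
  for (cc in res$candidates) {
    expect_true(isTRUE(revalidate_candidate(cc, fx$genome, fx$annotation,
                                            cfg, fx$target_psl)))
    # candidate intervals never overlap annotated exons of the host
    tx <- fx$annotation$transcripts[[cc$host_transcript]]
    expect_false(any(cc$start < tx$exons$end & tx$exons$start < cc$end))
  }
})

test_that("discovery output is deterministic across reruns", {
  fx1 <- generate_fixture(fixture_spec(seed = 8, n_genes = 8,
                                       events = mixed_event_list()[1:6]))
  fx2 <- generate_fixture(fixture_spec(seed = 8, n_genes = 8,
                                       events = mixed_event_list()[1:6]))
  cfg <- discovery_config()
  r1 <- run_discovery(cfg, fx1$genome, fx1$annotation, fx1$subject_psl,
                      fx1$target_psl)
  r2 <- run_discovery(cfg, fx2$genome, fx2$annotation, fx2$subject_psl,
                      fx2$target_psl)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_novel_gff3(r1$candidates, r1$asvs, f1)
  write_novel_gff3(r2$candidates, r2$asvs, f2)
  expect_identical(readLines(f1), readLines(f2))
})
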