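## Synthetic-data generator: a multi-gene genome with UTR/CDS structure,
## planted novel-exon events that satisfy or violate each discovery
## criterion by construction, subject "EST" alignments emitted as exact PSL
## (no aligner involved), optional planted substitution divergence with
## exact truth bookkeeping, and a truth table for every event.
##
## Gene template (5' -> 3'): exon1 (5'UTR) | intron1 | exon2 (5'UTR + CDS)
## | intron2 | exon3 (CDS) | intron3 | exon4 (CDS + 3'UTR) | intron4 |
## exon5 (3'UTR). Events are planted in intron1 (5'UTR), intron2 (CDS) or
## intron4 (3'UTR). CDS segment lengths are multiples of 3 so every planted
## CDS event starts at codon phase 0, which keeps planted frame/stop
## properties exact.

#' Specify one planted alternative-splicing event
#'
#' @param type `"cassette"` or `"retained_intron"`.
#' @param region `"FIVE_UTR"`, `"CDS"` or `"THREE_UTR"`.
#' @param validity `"VALID"` or one of `VIOLATES_LENGTH`,
#'   `VIOLATES_FLANK_OVERLAP`, `VIOLATES_SPLICE`, `VIOLATES_FRAME`,
#'   `VIOLATES_STOP`, `VIOLATES_NOVELTY` — a valid event satisfies every
#'   discovery criterion by construction; each violation mode breaks exactly
#'   one.
#' @param n_supporting_ests Number of subject ESTs emitted for the event.
#' @param species Subject-species labels, recycled over the ESTs.
#' @param len Cassette exon length (default depends on validity/region).
#' @param shifts Planted boundary shifts (5', 3') in transcript orientation;
#'   non-zero shifts are only supported for UTR cassette events.
#' @param splice_class Planted donor-acceptor pair for cassette events.
#' @param divergence Optional list with `novel` and `flank`, each
#'   `c(syn = , nonsyn = )` per-site substitution rates applied to the
#'   subject EST copy (CDS cassette events only).
#' @return A list of class `EventSpec`.
#' @export
event_spec <- function(type = "cassette", region = "CDS",
                       validity = "VALID", n_supporting_ests = 1L,
                       species = "subjectA", len = NULL,
                       shifts = c(0L, 0L), splice_class = "GT-AG",
                       divergence = NULL) {
  type <- match.arg(type, c("cassette", "retained_intron"))
  region <- match.arg(region, c("FIVE_UTR", "CDS", "THREE_UTR"))
  validity <- match.arg(validity,
                        c("VALID", "VIOLATES_LENGTH",
                          "VIOLATES_FLANK_OVERLAP", "VIOLATES_SPLICE",
                          "VIOLATES_FRAME", "VIOLATES_STOP",
                          "VIOLATES_NOVELTY"))
  if (type == "retained_intron" &&
      validity %in% c("VIOLATES_LENGTH", "VIOLATES_SPLICE")) {
    stop_fmt("infeasible event: retained introns have no %s criterion",
             if (validity == "VIOLATES_LENGTH") "length" else "splice-site")
  }
  if (validity %in% c("VIOLATES_FRAME", "VIOLATES_STOP") && region != "CDS") {
    stop_fmt("infeasible event: %s requires a CDS region", validity)
  }
  if (any(shifts != 0L) && (region == "CDS" || type != "cassette")) {
    stop_fmt("planted boundary shifts are only supported for UTR cassette events")
  }
  if (!is.null(len)) {
    if (validity == "VIOLATES_FRAME" && len %% 3L == 0L) {
      stop_fmt("infeasible event: VIOLATES_FRAME with length %d (multiple of 3)",
               len)
    }
    if (validity == "VIOLATES_LENGTH" && len > 50L) {
      stop_fmt("infeasible event: VIOLATES_LENGTH with length %d (> 50)", len)
    }
  }
  if (!is.null(divergence) && !(type == "cassette" && region == "CDS")) {
    stop_fmt("divergence is only supported for CDS cassette events")
  }
  structure(list(type = type, region = region, validity = validity,
                 n_supporting_ests = as.integer(n_supporting_ests),
                 species = species, len = len,
                 shifts = as.integer(shifts), splice_class = splice_class,
                 divergence = divergence),
            class = "EventSpec")
}

#' Specify a synthetic fixture
#'
#' @param seed Integer RNG seed; the same spec always produces byte-identical
#'   outputs.
#' @param n_genes Number of genes (must be >= number of events; each gene
#'   hosts at most one event).
#' @param events List of [event_spec()] objects.
#' @param exon_len Range (length-2) of UTR exon lengths in bp.
#' @param intron_len Range of lengths for introns without planted events.
#' @param gc GC fraction of untranslated/intronic background sequence.
#' @return A list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed, n_genes = 10L, events = list(),
                         exon_len = c(120L, 200L),
                         intron_len = c(250L, 400L), gc = 0.44) {
  if (length(events) > n_genes) {
    stop_fmt("fixture needs n_genes >= number of events (%d < %d)",
             n_genes, length(events))
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 events = events, exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len), gc = gc),
            class = "FixtureSpec")
}

#' Standard validation event set
#'
#' The event mix used for end-to-end validation of the discovery pipeline:
#' 20 valid events (10 cassette exons, 10 retained introns, spread over the
#' 5'UTR/CDS/3'UTR regions and both strands) and 24 events violating exactly
#' one criterion each (4 per violation mode: length, flank overlap, splice
#' site, reading frame, premature stop, novelty).
#'
#' @return List of [event_spec()] objects (length 44).
#' @export
default_validation_events <- function() {
  c(
    ## 10 valid cassettes
    list(event_spec("cassette", "CDS", "VALID", n_supporting_ests = 2,
                    species = c("wheat", "barley"))),
    lapply(1:3, function(i) event_spec("cassette", "CDS", "VALID")),
    lapply(1:3, function(i) event_spec("cassette", "FIVE_UTR", "VALID")),
    list(event_spec("cassette", "THREE_UTR", "VALID", shifts = c(4L, -3L)),
         event_spec("cassette", "THREE_UTR", "VALID"),
         event_spec("cassette", "FIVE_UTR", "VALID", shifts = c(-6L, 2L))),
    ## 10 valid retained introns
    lapply(1:4, function(i) event_spec("retained_intron", "CDS", "VALID")),
    lapply(1:3, function(i) event_spec("retained_intron", "FIVE_UTR",
                                       "VALID")),
    lapply(1:3, function(i) event_spec("retained_intron", "THREE_UTR",
                                       "VALID")),
    ## 4 x 6 violations
    list(event_spec("cassette", "CDS", "VIOLATES_LENGTH"),
         event_spec("cassette", "CDS", "VIOLATES_LENGTH", len = 42L),
         event_spec("cassette", "FIVE_UTR", "VIOLATES_LENGTH"),
         event_spec("cassette", "THREE_UTR", "VIOLATES_LENGTH")),
    list(event_spec("cassette", "CDS", "VIOLATES_FLANK_OVERLAP"),
         event_spec("cassette", "FIVE_UTR", "VIOLATES_FLANK_OVERLAP"),
         event_spec("retained_intron", "CDS", "VIOLATES_FLANK_OVERLAP"),
         event_spec("retained_intron", "THREE_UTR",
                    "VIOLATES_FLANK_OVERLAP")),
    list(event_spec("cassette", "CDS", "VIOLATES_SPLICE"),
         event_spec("cassette", "CDS", "VIOLATES_SPLICE"),
         event_spec("cassette", "FIVE_UTR", "VIOLATES_SPLICE"),
         event_spec("cassette", "THREE_UTR", "VIOLATES_SPLICE")),
    list(event_spec("cassette", "CDS", "VIOLATES_FRAME"),
         event_spec("cassette", "CDS", "VIOLATES_FRAME", len = 77L),
         event_spec("retained_intron", "CDS", "VIOLATES_FRAME"),
         event_spec("retained_intron", "CDS", "VIOLATES_FRAME")),
    list(event_spec("cassette", "CDS", "VIOLATES_STOP"),
         event_spec("cassette", "CDS", "VIOLATES_STOP"),
         event_spec("retained_intron", "CDS", "VIOLATES_STOP"),
         event_spec("retained_intron", "CDS", "VIOLATES_STOP")),
    list(event_spec("cassette", "CDS", "VIOLATES_NOVELTY"),
         event_spec("cassette", "FIVE_UTR", "VIOLATES_NOVELTY"),
         event_spec("retained_intron", "CDS", "VIOLATES_NOVELTY"),
         event_spec("retained_intron", "THREE_UTR", "VIOLATES_NOVELTY")))
}

#' @noRd
rand_dna <- function(n, gc = 0.44) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' @noRd
rand_cds <- function(n_bases) {
  stopifnot(n_bases %% 3L == 0L, n_bases >= 9L)
  inner <- sample(sense_codons(), n_bases / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(inner, collapse = ""), "TAA")
}

## codons over {C,T} only: always sense, never form a stop in any frame
#' @noRd
ct_filler <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("C", "T"), n, replace = TRUE, prob = c(0.6, 0.4)),
        collapse = "")
}

#' Apply random substitutions to an in-frame coding sequence
#'
#' Draws, for each site, a synonymous substitution with probability
#' `syn_rate` and a nonsynonymous one with probability `nonsyn_rate`
#' (single-nucleotide neighbour enumeration; substitutions creating stop
#' codons are never used). At most one site per codon is mutated (the first
#' selected in codon order), so every mutated codon differs by a single
#' step and the realized counts are exact.
#'
#' @param sequence In-frame, stop-free CDS string (length a multiple of 3).
#' @param syn_rate,nonsyn_rate Per-site substitution probabilities in [0,1).
#' @param seed Optional seed; by default the surrounding RNG stream is used.
#' @return List with `seq` (mutated sequence), `Nd` and `Sd` (realized
#'   counts of nonsynonymous/synonymous substitutions).
#' @export
mutate_coding <- function(sequence, syn_rate, nonsyn_rate, seed = NULL) {
  if (syn_rate < 0 || syn_rate >= 1 || nonsyn_rate < 0 || nonsyn_rate >= 1) {
    stop_fmt("substitution rates must lie in [0, 1)")
  }
  if (nchar(sequence) %% 3L != 0L) {
    stop_fmt("mutate_coding: sequence length not a multiple of 3")
  }
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n_codon <- nchar(sequence) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(sequence, starts, starts + 2L)
  if (any(gc[codons] == "*")) stop_fmt("mutate_coding: sequence contains a stop codon")
  nd <- 0L; sd <- 0L
  u <- matrix(stats::runif(3L * n_codon), nrow = 3L)
  for (k in seq_len(n_codon)) {
    cd <- codons[k]
    for (pos in 1:3) {
      want <- if (u[pos, k] < syn_rate) "syn"
              else if (u[pos, k] < syn_rate + nonsyn_rate) "nonsyn"
              else next
      cur <- substr(cd, pos, pos)
      opts <- character(0)
      for (b in setdiff(bases, cur)) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (gc[[mut]] == "*") next
        syn <- gc[[mut]] == gc[[cd]]
        if ((want == "syn") == syn) opts <- c(opts, b)
      }
      if (length(opts) == 0L) next
      b <- if (length(opts) == 1L) opts else sample(opts, 1L)
      substr(cd, pos, pos) <- b
      if (want == "syn") sd <- sd + 1L else nd <- nd + 1L
      break  # at most one substitution per codon
    }
    codons[k] <- cd
  }
  list(seq = paste(codons, collapse = ""), Nd = nd, Sd = sd)
}

## ---- gene construction in "sense space" -----------------------------------
## A gene is first laid out in transcript orientation (sense space) with
## relative coordinates, then mirrored into genome space for minus-strand
## genes. ESTs are built in sense space too and mirrored alongside.

#' @noRd
default_cassette_len <- function(ev) {
  if (!is.null(ev$len)) return(as.integer(ev$len))
  switch(ev$validity,
         VIOLATES_LENGTH = 48L,
         VIOLATES_FRAME = 91L,
         3L * sample(24:36, 1L))  # 72..108, multiple of 3
}

#' @noRd
build_gene <- function(ev, spec, w = 10L) {
  rng <- function(r) sample(seq.int(r[1], r[2]), 1L)
  u1 <- rng(spec$exon_len); u4 <- rng(spec$exon_len)
  u2 <- 60L; u3 <- 60L
  c1 <- 3L * sample(40:60, 1L); c2 <- 3L * sample(40:60, 1L)
  c3 <- 3L * sample(40:60, 1L)
  exon_lens <- c(u1, u2 + c1, c2, c3 + u3, u4)

  ev_intron <- if (is.null(ev)) 0L else switch(ev$region,
    FIVE_UTR = 1L, CDS = 2L, THREE_UTR = 4L)

  cand_len <- NULL
  intron_lens <- vapply(1:4, function(i) rng(spec$intron_len), integer(1))
  if (!is.null(ev)) {
    if (ev$type == "cassette") {
      cand_len <- default_cassette_len(ev)
      # cassette-hosting introns run long relative to ordinary introns
      intron_lens[ev_intron] <- cand_len + 2L * (w + 12L) + sample(350:650, 1L)
    } else {
      li <- intron_lens[ev_intron]
      if (ev$region == "CDS") {
        li <- li - li %% 3L
        if (ev$validity == "VIOLATES_FRAME") li <- li + 1L
      }
      intron_lens[ev_intron] <- li
      cand_len <- intron_lens[ev_intron]
    }
  }

  ## intron sequences
  intron_seq <- function(i) {
    li <- intron_lens[i]
    if (is.null(ev) || i != ev_intron) {
      return(paste0("GT", rand_dna(li - 4L, spec$gc), "AG"))
    }
    if (ev$type == "retained_intron") {
      if (ev$region == "CDS") {
        body <- ct_filler(li - 4L)
        # phase 0 at the intron: avoid T|AG stop at the tail codon
        if (li >= 6L) substr(body, nchar(body), nchar(body)) <- "C"
        s <- paste0("GT", body, "AG")
        if (ev$validity == "VIOLATES_STOP") {
          m <- max(2L, (li %/% 3L) %/% 2L)
          substr(s, 3L * m + 1L, 3L * m + 3L) <- "TAA"
        }
        return(s)
      }
      return(paste0("GT", ct_filler(li - 4L), "AG"))
    }
    ## cassette: GT | fill | scrubL(C) | candidate | scrubR(C) | fill | AG
    off <- w + 8L
    stopifnot(li >= off + cand_len + w + 12L)
    content <- if (ev$region == "CDS") {
      cs <- ct_filler(cand_len)
      if (ev$validity == "VIOLATES_STOP") {
        m <- max((cand_len %/% 3L) %/% 2L, ceiling((w + 2L) / 3) + 1L)
        substr(cs, 3L * m + 1L, 3L * m + 3L) <- "TAA"
      }
      cs
    } else {
      ct_filler(cand_len)
    }
    left_fill <- rand_dna(off - 2L - w - 2L, spec$gc)
    right_fill <- rand_dna(li - (off + cand_len + 2L + w) - 2L, spec$gc)
    s <- paste0("GT", left_fill, strrep("C", w + 2L), content,
                strrep("C", w + 2L), right_fill, "AG")
    stopifnot(nchar(s) == li)
    if (ev$validity != "VIOLATES_SPLICE") {
      pair <- strsplit(ev$splice_class, "-", fixed = TRUE)[[1]]
      sl <- ev$shifts[1]; sr <- ev$shifts[2]
      substr(s, off - 2L + sl + 1L, off + sl) <- pair[2]      # acceptor
      substr(s, off + cand_len + sr + 1L,
             off + cand_len + sr + 2L) <- pair[1]             # donor
    }
    s
  }

  introns <- vapply(1:4, intron_seq, character(1))

  ## exon sequences
  cds_seq <- rand_cds(c1 + c2 + c3)
  exon_seq <- c(
    rand_dna(u1, spec$gc),
    paste0(rand_dna(u2, spec$gc), substr(cds_seq, 1L, c1)),
    substr(cds_seq, c1 + 1L, c1 + c2),
    paste0(substr(cds_seq, c1 + c2 + 1L, c1 + c2 + c3),
           rand_dna(u3, spec$gc)),
    rand_dna(u4, spec$gc))

  ## relative layout
  pieces <- character(9); lens <- integer(9)
  pieces[c(1, 3, 5, 7, 9)] <- exon_seq
  pieces[c(2, 4, 6, 8)] <- introns
  lens[c(1, 3, 5, 7, 9)] <- exon_lens
  lens[c(2, 4, 6, 8)] <- intron_lens
  starts <- cumsum(c(0L, lens[-9]))
  seq <- paste(pieces, collapse = "")
  exons_rel <- data.frame(start = starts[c(1, 3, 5, 7, 9)],
                          end = starts[c(1, 3, 5, 7, 9)] + exon_lens)
  introns_rel <- data.frame(start = starts[c(2, 4, 6, 8)],
                            end = starts[c(2, 4, 6, 8)] + intron_lens)
  cds_rel <- data.frame(
    start = c(exons_rel$start[2] + u2, exons_rel$start[3], exons_rel$start[4]),
    end = c(exons_rel$end[2], exons_rel$end[3], exons_rel$start[4] + c3))

  cand_rel <- NULL
  if (!is.null(ev)) {
    is_rel <- introns_rel$start[ev_intron]
    if (ev$type == "cassette") {
      off <- w + 8L
      cand_rel <- c(is_rel + off, is_rel + off + cand_len)
    } else {
      cand_rel <- c(is_rel, introns_rel$end[ev_intron])
    }
  }

  list(seq = seq, len = sum(lens), exons_rel = exons_rel,
       introns_rel = introns_rel, cds_rel = cds_rel, cand_rel = cand_rel,
       ev_intron = ev_intron, cds_lens = c(c1, c2, c3))
}

#' @noRd
mirror_iv <- function(iv, L) {
  data.frame(start = L - iv$end, end = L - iv$start)[rev(seq_len(nrow(iv))), ,
                                                     drop = FALSE]
}

#' Generate a synthetic fixture
#'
#' Builds the genome, annotation, subject EST alignments (exact PSL derived
#' from construction) with sequences, optional target-species EST alignments
#' (planted for novelty-violating events) and a truth table listing every
#' event with the discovery flag it is expected to fail, if any.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `subject_<species>.psl`, `subject_ests.fa`,
#'   `target.psl` and `truth.tsv` there.
#' @return List with `genome` (`SequenceSet`), `annotation`
#'   (`GenomeAnnotation`), `subject_psl` (named list species -> list of
#'   `PslRecord`), `est_seqs` (`SequenceSet`), `target_psl`, `truth`
#'   (data.frame) and, if written, `paths`.
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  w <- 10L

  n_ev <- length(spec$events)
  chroms <- c("chr1", "chr2")
  chrom_parts <- list(chr1 = list(), chr2 = list())
  chrom_len <- c(chr1 = 0L, chr2 = 0L)

  transcripts <- list()
  ests <- list()        # per-EST: qname, species, blocks (abs), qseq
  target_blocks <- list()
  truth <- list()

  for (g in seq_len(spec$n_genes)) {
    ev <- if (g <= n_ev) spec$events[[g]] else NULL
    strand <- if (g %% 2L == 1L) "+" else "-"
    chrom <- chroms[(g - 1L) %% 2L + 1L]
    gene_id <- sprintf("gene%03d", g)
    tx_id <- sprintf("tx%03d", g)

    gb <- build_gene(ev, spec, w = w)

    spacer <- rand_dna(sample(300:500, 1L), spec$gc)
    offset <- chrom_len[[chrom]] + nchar(spacer)
    gseq <- if (strand == "+") gb$seq else revcomp(gb$seq)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], spacer, gseq)
    chrom_len[[chrom]] <- offset + gb$len

    to_abs <- function(iv) {
      iv <- as.data.frame(iv)
      if (strand == "+") data.frame(start = offset + iv$start,
                                    end = offset + iv$end)
      else {
        m <- mirror_iv(iv, gb$len)
        data.frame(start = offset + m$start, end = offset + m$end)
      }
    }
    exons_abs <- to_abs(gb$exons_rel)
    cds_abs <- to_abs(gb$cds_rel)
    transcripts[[tx_id]] <- transcript_model(
      id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
      exons = exons_abs, cds = cds_abs)

    if (is.null(ev)) next

    ## ---- event bookkeeping -------------------------------------------
    ei <- gb$ev_intron
    cand_rel <- gb$cand_rel
    refined_rel <- if (ev$type == "cassette") {
      c(cand_rel[1] + ev$shifts[1], cand_rel[2] + ev$shifts[2])
    } else cand_rel
    refined_abs <- to_abs(data.frame(start = refined_rel[1],
                                     end = refined_rel[2]))

    ## ---- subject ESTs (sense space, then mirrored) -------------------
    A <- ei            # upstream exon index (sense order)
    B <- ei + 1L
    exr <- gb$exons_rel
    full_cover <- !is.null(ev$divergence)
    div_truth <- c(novel_Nd = NA_integer_, novel_Sd = NA_integer_,
                   flank_Nd = NA_integer_, flank_Sd = NA_integer_)
    species_vec <- rep(ev$species, length.out = ev$n_supporting_ests)
    for (j in seq_len(ev$n_supporting_ests)) {
      if (ev$validity == "VIOLATES_FLANK_OVERLAP") {
        fo_up <- 40L + (j - 1L); fo_dn <- 40L + (j - 1L)
      } else if (full_cover) {
        fo_up <- exr$end[A] - exr$start[A]
        fo_dn <- exr$end[B] - exr$start[B]
      } else {
        fo_up <- 55L + 3L * (j - 1L); fo_dn <- 55L + 3L * (j - 1L)
      }
      blocks_rel <- if (ev$type == "cassette") {
        data.frame(start = c(exr$end[A] - fo_up, cand_rel[1], exr$start[B]),
                   end = c(exr$end[A], cand_rel[2], exr$start[B] + fo_dn))
      } else {
        data.frame(start = exr$end[A] - fo_up,
                   end = exr$start[B] + fo_dn)
      }
      qparts <- vapply(seq_len(nrow(blocks_rel)), function(i) {
        seq_sub(gb$seq, blocks_rel$start[i], blocks_rel$end[i])
      }, character(1))

      if (full_cover && j == 1L) {
        ## mutate the candidate and the flank CDS portions (all phase 0)
        mv <- mutate_coding(qparts[2], ev$divergence$novel["syn"],
                            ev$divergence$novel["nonsyn"])
        qparts[2] <- mv$seq
        div_truth["novel_Nd"] <- mv$Nd; div_truth["novel_Sd"] <- mv$Sd
        fNd <- 0L; fSd <- 0L
        cdsr <- gb$cds_rel
        for (side in c(1L, 3L)) {
          bi <- side  # block index: 1 = upstream exon, 3 = downstream
          bs <- blocks_rel$start[bi]; be <- blocks_rel$end[bi]
          for (ci in seq_len(nrow(cdsr))) {
            s <- max(bs, cdsr$start[ci]); e <- min(be, cdsr$end[ci])
            if (s >= e) next
            mvf <- mutate_coding(seq_sub(gb$seq, s, e),
                                 ev$divergence$flank["syn"],
                                 ev$divergence$flank["nonsyn"])
            substr(qparts[bi], s - bs + 1L, e - bs) <- mvf$seq
            fNd <- fNd + mvf$Nd; fSd <- fSd + mvf$Sd
          }
        }
        div_truth["flank_Nd"] <- fNd; div_truth["flank_Sd"] <- fSd
      }
      qseq_sense <- paste(qparts, collapse = "")

      blocks_abs <- to_abs(blocks_rel)
      blocks_abs <- blocks_abs[order(blocks_abs$start), , drop = FALSE]
      qseq <- if (strand == "+") qseq_sense else revcomp(qseq_sense)
      qname <- sprintf("%s_EV%03d_est%d", species_vec[j], g, j)
      ests[[qname]] <- list(qname = qname, species = species_vec[j],
                            chrom = chrom, blocks = blocks_abs, qseq = qseq)
    }

    ## ---- target-species EST for novelty violations -------------------
    if (ev$validity == "VIOLATES_NOVELTY") {
      tb_s <- refined_abs$start + (refined_abs$end - refined_abs$start) %/% 3L
      tb_e <- min(refined_abs$end, tb_s + 40L)
      target_blocks[[length(target_blocks) + 1L]] <-
        list(chrom = chrom, start = tb_s, end = tb_e,
             qname = sprintf("target_EV%03d", g))
    }

    expected_flag <- switch(ev$validity,
      VALID = "none",
      VIOLATES_LENGTH = "length",
      VIOLATES_FLANK_OVERLAP = "flank_overlap",
      VIOLATES_SPLICE = "splice_site",
      VIOLATES_FRAME = "frame",
      VIOLATES_STOP = "premature_stop",
      VIOLATES_NOVELTY = "novelty")
    truth[[length(truth) + 1L]] <- data.frame(
      event = sprintf("EV%03d", g), gene = gene_id, transcript = tx_id,
      chrom = chrom, strand = strand, type = ev$type, region = ev$region,
      validity = ev$validity, start = refined_abs$start,
      end = refined_abs$end, expected_flag = expected_flag,
      splice_class = if (ev$type == "cassette" &&
                         ev$validity != "VIOLATES_SPLICE") ev$splice_class
                     else "none",
      n_ests = ev$n_supporting_ests,
      novel_Nd = div_truth[["novel_Nd"]], novel_Sd = div_truth[["novel_Sd"]],
      flank_Nd = div_truth[["flank_Nd"]], flank_Sd = div_truth[["flank_Sd"]],
      stringsAsFactors = FALSE)
  }

  genome <- structure(vapply(chroms, function(ch)
    paste(unlist(chrom_parts[[ch]]), collapse = ""), character(1)),
    class = "SequenceSet")
  annotation <- build_annotation(transcripts)

  ## PSL records (tSize needs final chromosome lengths)
  make_psl <- function(e) {
    sizes <- e$blocks$end - e$blocks$start
    qstarts <- cumsum(c(0L, sizes[-length(sizes)]))
    tchars <- unlist(lapply(seq_len(nrow(e$blocks)), function(i)
      strsplit(seq_sub(genome[[e$chrom]], e$blocks$start[i],
                       e$blocks$end[i]), "")[[1]]))
    qchars <- strsplit(e$qseq, "")[[1]]
    mism <- sum(tchars != qchars)
    psl_record(qName = e$qname, qSize = nchar(e$qseq), qStart = 0L,
               qEnd = nchar(e$qseq), tName = e$chrom,
               tSize = nchar(genome[[e$chrom]]),
               tStart = e$blocks$start[1],
               tEnd = e$blocks$end[nrow(e$blocks)], strand = "+",
               blockSizes = sizes, qStarts = qstarts,
               tStarts = e$blocks$start,
               matches = sum(sizes) - mism, misMatches = mism)
  }
  subject_psl <- list()
  est_seqs <- character(0)
  for (e in ests) {
    rec <- make_psl(e)
    subject_psl[[e$species]] <- c(subject_psl[[e$species]], list(rec))
    est_seqs[e$qname] <- e$qseq
  }
  est_seqs <- structure(est_seqs, class = "SequenceSet")
  target_psl <- lapply(target_blocks, function(tb) {
    len <- tb$end - tb$start
    psl_record(qName = tb$qname, qSize = len, qStart = 0L, qEnd = len,
               tName = tb$chrom, tSize = nchar(genome[[tb$chrom]]),
               tStart = tb$start, tEnd = tb$end, strand = "+",
               blockSizes = len, qStarts = 0L, tStarts = tb$start)
  })
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event = character(0))

  out <- list(genome = genome, annotation = annotation,
              subject_psl = subject_psl, est_seqs = est_seqs,
              target_psl = target_psl, truth = truth_df)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      annotation = file.path(out_dir, "annotation.gff3"),
      est_fasta = file.path(out_dir, "subject_ests.fa"),
      target_psl = file.path(out_dir, "target.psl"),
      truth = file.path(out_dir, "truth.tsv"))
    write_fasta(genome, paths$genome)
    write_annotation_gff3(annotation, paths$annotation)
    write_fasta(est_seqs, paths$est_fasta)
    write_psl(target_psl, paths$target_psl)
    for (sp in names(subject_psl)) {
      p <- file.path(out_dir, sprintf("subject_%s.psl", sp))
      write_psl(subject_psl[[sp]], p)
      paths[[paste0("psl_", sp)]] <- p
    }
    utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
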