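## Evolutionary-rate comparison between a novel exon and its concatenated
## flanking exons: Nei-Gojobori (1986) counting of synonymous and
## nonsynonymous sites and differences, Jukes-Cantor distance correction,
## and exact contingency tests on the rounded site/substitution counts.

.codon_env <- new.env(parent = emptyenv())

#' @noRd
aa_of <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

#' @noRd
is_stop <- function(codon) {
  !is.na(codon) & Biostrings::GENETIC_CODE[codon] == "*"
}

#' Synonymous site count of a single codon (NG86)
#'
#' Each of the three codon positions contributes the fraction of its three
#' single-nucleotide changes that are synonymous; changes creating a stop
#' codon count as nonsynonymous. Memoised per codon.
#' @noRd
codon_syn_sites <- function(codon) {
  if (is.null(.codon_env$S)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    S <- setNames(numeric(length(codons)), codons)
    bases <- c("A", "C", "G", "T")
    for (cd in codons) {
      if (gc[[cd]] == "*") { S[cd] <- NA_real_; next }
      s <- 0
      for (pos in 1:3) {
        for (b in setdiff(bases, substr(cd, pos, pos))) {
          mut <- cd
          substr(mut, pos, pos) <- b
          if (gc[[mut]] != "*" && gc[[mut]] == gc[[cd]]) s <- s + 1 / 3
        }
      }
      S[cd] <- s
    }
    .codon_env$S <- S
  }
  .codon_env$S[codon]
}

#' Count synonymous and nonsynonymous sites of a codon sequence (NG86)
#'
#' Codons containing `N` or equal to a stop codon are skipped. The identity
#' `N + S = 3 * L` holds over the `L` counted codons.
#'
#' @param codons Character vector of codons.
#' @return Named numeric vector `c(N = , S = )` (fractional site counts).
#' @export
count_sites <- function(codons) {
  ok <- !grepl("N", codons) & !is_stop(codons)
  codons <- codons[ok]
  if (length(codons) == 0L) return(c(N = 0, S = 0))
  S <- sum(codon_syn_sites(codons))
  c(N = 3 * length(codons) - S, S = S)
}

#' @noRd
.perms <- list(`1` = list(1L),
               `2` = list(c(1L, 2L), c(2L, 1L)),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Partition the differences between two codons into syn/nonsyn (NG86)
#'
#' Averages over all shortest mutational pathways with equal weights;
#' pathways passing through a stop codon are excluded. In the degenerate case
#' where every pathway is blocked, all pathways are used with steps into or
#' out of a stop codon counted as nonsynonymous.
#' @noRd
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- .perms[[as.character(length(pos))]]
  paths <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  blocked <- logical(length(perms))
  for (p in seq_along(perms)) {
    cur <- c1
    sd <- 0; nd <- 0; has_stop <- FALSE
    for (k in perms[[p]]) {
      nxt <- cur
      substr(nxt, pos[k], pos[k]) <- substr(c2, pos[k], pos[k])
      if (is_stop(cur) || is_stop(nxt)) {
        has_stop <- TRUE
        nd <- nd + 1
      } else if (aa_of(cur) == aa_of(nxt)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    paths[p, ] <- c(nd, sd)
    blocked[p] <- has_stop
  }
  use <- if (all(blocked)) rep(TRUE, length(perms)) else !blocked
  c(mean(paths[use, 1]), mean(paths[use, 2]))
}

#' Count synonymous and nonsynonymous differences in a codon alignment
#'
#' NG86 pathway-averaged counting over the aligned codon pairs. Columns where
#' either codon contains `N` or is a stop codon are skipped.
#'
#' @param pair A `CodonAlignment` (see [build_codon_alignment()]), or any
#'   list with `target_codons` and `subject_codons` of equal length.
#' @return Named numeric vector `c(Nd = , Sd = )`.
#' @export
count_differences <- function(pair) {
  t <- pair$target_codons; s <- pair$subject_codons
  stopifnot(length(t) == length(s))
  nd <- 0; sd <- 0
  for (i in seq_along(t)) {
    if (grepl("N", t[i]) || grepl("N", s[i])) next
    if (is_stop(t[i]) || is_stop(s[i])) next
    d <- codon_pair_diffs(t[i], s[i])
    nd <- nd + d[1]; sd <- sd + d[2]
  }
  c(Nd = nd, Sd = sd)
}

#' Build a gapless codon alignment between a target region and a subject EST
#'
#' Pairs each genomic base of `regions` (ascending genome order) with the
#' subject EST base aligned to it via the PSL blocks, reorients to the
#' transcript strand, discards `frame_offset` leading bases and any trailing
#' partial codon, and drops codon columns containing an unaligned base or an
#' `N` in either sequence.
#'
#' @param regions data.frame of genomic intervals (`start`, `end`, 0-based
#'   half-open, ascending).
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @param frame_offset Bases to discard before the first complete codon
#'   (transcript orientation).
#' @param chrom_seq Target chromosome sequence (character scalar).
#' @param est A `PslRecord` aligning the subject EST to this chromosome.
#' @param est_seq The subject EST sequence (as submitted to the aligner).
#' @return A list of class `CodonAlignment` with `target_codons` and
#'   `subject_codons`. Errors when no complete codon survives.
#' @export
build_codon_alignment <- function(regions, strand, frame_offset, chrom_seq,
                                  est, est_seq) {
  stopifnot(strand %in% c("+", "-"), frame_offset %in% 0:2)
  positions <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    seq.int(regions$start[i], regions$end[i] - 1L)
  }))
  tbase <- strsplit(chrom_seq, "")[[1]][positions + 1L]

  ## subject base aligned to each target position (NA where unaligned)
  qchars <- strsplit(est_seq, "")[[1]]
  if (est$strand == "-") {
    # PSL '-' strand: block qStarts are coordinates on the reverse-
    # complemented query; the base aligned at such a position is the
    # complement of the query read from its other end.
    qchars <- strsplit(revcomp(est_seq), "")[[1]]
  }
  sbase <- rep(NA_character_, length(positions))
  for (b in seq_len(est$blockCount)) {
    ts <- est$tStarts[b]; size <- est$blockSizes[b]; qs <- est$qStarts[b]
    hit <- positions >= ts & positions < ts + size
    sbase[hit] <- qchars[qs + (positions[hit] - ts) + 1L]
  }

  if (strand == "-") {
    tbase <- rev(chartr("ACGTN", "TGCAN", tbase))
    sbase <- rev(chartr("ACGTN", "TGCAN", sbase))
  }
  if (frame_offset > 0L) {
    tbase <- tbase[-seq_len(frame_offset)]
    sbase <- sbase[-seq_len(frame_offset)]
  }
  n_codon <- length(tbase) %/% 3L
  if (n_codon == 0L) stop_fmt("codon alignment: no complete codons")
  keep_t <- character(0); keep_s <- character(0)
  for (k in seq_len(n_codon)) {
    idx <- (3L * (k - 1L) + 1L):(3L * k)
    ct <- paste(tbase[idx], collapse = "")
    cs <- paste(sbase[idx], collapse = "")
    if (anyNA(sbase[idx]) || grepl("N", ct) || grepl("N", cs)) next
    keep_t <- c(keep_t, ct); keep_s <- c(keep_s, cs)
  }
  if (length(keep_t) == 0L) {
    stop_fmt("codon alignment: no complete gapless codons")
  }
  structure(list(target_codons = keep_t, subject_codons = keep_s),
            class = "CodonAlignment")
}

#' Estimate dn, ds and omega from a codon alignment (NG86 + Jukes-Cantor)
#'
#' Site counts are averaged over the two sequences; proportions
#' `pn = Nd/N`, `ps = Sd/S` are corrected with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - (4/3) p)`. A proportion at or beyond the saturation
#' point 3/4 leaves the corresponding rate `NA` (flagged `saturated`).
#'
#' @param pair A `CodonAlignment`.
#' @return A list of class `RateEstimate` with fields N, S, Nd, Sd, pn, ps,
#'   dn, ds, omega, saturated, codons.
#' @export
estimate_rates <- function(pair) {
  L <- length(pair$target_codons)
  if (L == 0L) stop_fmt("estimate_rates: zero analyzable codons")
  st <- count_sites(pair$target_codons)
  ss <- count_sites(pair$subject_codons)
  N <- unname(st[["N"]] + ss[["N"]]) / 2
  S <- unname(st[["S"]] + ss[["S"]]) / 2
  d <- count_differences(pair)
  pn <- if (N > 0) d[["Nd"]] / N else NA_real_
  ps <- if (S > 0) d[["Sd"]] / S else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3) + 0  # + 0 normalises IEEE negative zero
  }
  dn <- jc(pn); ds <- jc(ps)
  saturated <- (!is.na(pn) && pn >= 0.75) || (!is.na(ps) && ps >= 0.75)
  omega <- if (!is.na(dn) && !is.na(ds) && ds > 0) dn / ds else NA_real_
  structure(list(N = unname(N), S = unname(S),
                 Nd = d[["Nd"]], Sd = d[["Sd"]],
                 pn = unname(pn), ps = unname(ps),
                 dn = dn, ds = ds, omega = omega,
                 saturated = saturated, codons = L),
            class = "RateEstimate")
}

#' Two-sided exact hypergeometric test for a 2x2 table
#'
#' Sums, over the support of the hypergeometric distribution given the fixed
#' margins, the probabilities of all tables no more probable than the
#' observed one (with the conventional 1e-7 relative tolerance for ties).
#'
#' @param a,b,c2,d2 Non-negative integer cells, rows (a,b) and (c2,d2).
#' @return Two-sided p-value in [0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c2, d2) {
  if (any(c(a, b, c2, d2) < 0)) stop_fmt("fisher_exact_2x2: negative cell")
  m <- a + b; n <- c2 + d2; k <- a + c2
  if (m + n == 0L || k == 0L || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' @noRd
round_counts <- function(x, rounding) {
  switch(rounding,
         half_up = round_half_up(x),
         half_even = round(x),
         stop_fmt("unknown rounding mode '%s'", rounding))
}

#' Exact tests for dn and ds differences between two exon sets
#'
#' Builds, for the nonsynonymous rate, a 2x2 table with rows (novel,
#' flanking) and columns (changed nonsynonymous sites, unchanged
#' nonsynonymous sites) from the rounded NG86 counts, and tests independence
#' with the two-sided exact hypergeometric test; analogously for the
#' synonymous rate.
#'
#' @param novel,flanking `RateEstimate` objects.
#' @param rounding `"half_up"` (default) or `"half_even"` — how fractional
#'   NG86 site counts are rounded to the integers the tables require.
#' @return Named numeric vector `c(p_dn = , p_ds = )`.
#' @export
fisher_rate_difference <- function(novel, flanking, rounding = "half_up") {
  cells <- function(nd, n) {
    ch <- round_counts(nd, rounding)
    un <- round_counts(n - nd, rounding)
    if (ch < 0 || un < 0) stop_fmt("negative rounded cell")
    c(ch, un)
  }
  rn <- cells(novel$Nd, novel$N); rf <- cells(flanking$Nd, flanking$N)
  p_dn <- fisher_exact_2x2(rn[1], rn[2], rf[1], rf[2])
  sn <- cells(novel$Sd, novel$S); sf <- cells(flanking$Sd, flanking$S)
  p_ds <- fisher_exact_2x2(sn[1], sn[2], sf[1], sf[2])
  c(p_dn = p_dn, p_ds = p_ds)
}

#' Exact test of dn/ds against neutrality (omega = 1)
#'
#' Tests independence in the table [[Nd, N - Nd], [Sd, S - Sd]] (rounded
#' counts) with the two-sided exact hypergeometric test; the one-sided
#' direction is reported alongside.
#'
#' @param estimate A `RateEstimate`.
#' @param rounding As in [fisher_rate_difference()].
#' @return List with `p` (two-sided) and `direction` (`"omega<1"`,
#'   `"omega>1"` or `"none"`).
#' @export
test_neutrality <- function(estimate, rounding = "half_up") {
  nd <- round_counts(estimate$Nd, rounding)
  nu <- round_counts(estimate$N - estimate$Nd, rounding)
  sd <- round_counts(estimate$Sd, rounding)
  su <- round_counts(estimate$S - estimate$Sd, rounding)
  if (any(c(nd, nu, sd, su) < 0)) stop_fmt("negative rounded cell")
  p <- fisher_exact_2x2(nd, nu, sd, su)
  pn <- if (estimate$N > 0) estimate$Nd / estimate$N else NA_real_
  ps <- if (estimate$S > 0) estimate$Sd / estimate$S else NA_real_
  direction <- if (is.na(pn) || is.na(ps) || pn == ps) "none"
               else if (pn < ps) "omega<1" else "omega>1"
  list(p = p, direction = direction)
}

## ---- assembling the comparison for a discovered candidate -----------------

#' Cumulative exonic CDS length 5' of a genomic position, transcript strand
#' @noRd
cds_length_before <- function(transcript, pos) {
  cds <- transcript$cds
  if (transcript$strand == "+") {
    sum(pmax(0L, pmin(cds$end, pos) - cds$start))
  } else {
    sum(pmax(0L, cds$end - pmax(cds$start, pos)))
  }
}

#' Frame offset (bases to skip) for a CDS region starting at a position
#' @noRd
frame_offset_at <- function(transcript, pos) {
  phase <- cds_length_before(transcript, pos) %% 3L
  (3L - phase) %% 3L
}

#' Concatenate the CDS portions of a novel exon's flanking exons
#'
#' Joins the CDS portions of the exons immediately upstream and downstream of
#' the candidate's host intron, in transcript order, and records the frame
#' offset of the first retained codon position according to the annotation.
#' In the annotated isoform the two flanks are adjacent in the CDS, so the
#' concatenation is frame-continuous.
#'
#' @param novel A CDS-region `NovelExonCandidate`.
#' @param transcript Its host `TranscriptModel`.
#' @param genome A `SequenceSet`.
#' @return List with `seq` (transcript-orientation nucleotide string),
#'   `frame_offset`, and `regions` (genomic intervals, ascending).
#' @export
concatenate_flanking <- function(novel, transcript, genome) {
  if (!transcript$coding) stop_fmt("no CDS flank: transcript %s non-coding",
                                   transcript$id)
  k <- which(transcript$introns$start == novel$host_intron[1] &
             transcript$introns$end == novel$host_intron[2])
  if (length(k) != 1L) {
    stop_fmt("candidate host intron not found in transcript %s",
             transcript$id)
  }
  flanks <- transcript$exons[c(k, k + 1L), , drop = FALSE]
  cds <- transcript$cds
  regions <- do.call(rbind, lapply(seq_len(2L), function(i) {
    s <- pmax(flanks$start[i], cds$start)
    e <- pmin(flanks$end[i], cds$end)
    keep <- s < e
    if (!any(keep)) return(NULL)
    data.frame(start = s[keep], end = e[keep])
  }))
  if (is.null(regions) || nrow(regions) == 0L) {
    stop_fmt("no CDS flank for candidate at [%d,%d)", novel$start, novel$end)
  }
  has_up <- any(overlaps(regions$start, regions$end,
                         flanks$start[1], flanks$end[1]))
  has_dn <- any(overlaps(regions$start, regions$end,
                         flanks$start[2], flanks$end[2]))
  if (!has_up || !has_dn) {
    stop_fmt("no CDS flank for candidate at [%d,%d)", novel$start, novel$end)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  first_pos <- if (transcript$strand == "+") regions$start[1]
               else regions$end[nrow(regions)]
  list(seq = spliced_sequence(genome, transcript$chrom, regions,
                              transcript$strand),
       frame_offset = frame_offset_at(transcript, first_pos),
       regions = regions)
}

#' Pick the subject EST used for rate estimation
#'
#' Among the ESTs supporting a candidate, the best hit is the one with the
#' most aligned bases over the candidate and flank regions; ties are broken
#' by higher `matches`, then EST id.
#' @noRd
pick_rate_est <- function(candidate, regions, ests) {
  ids <- candidate$supporting_ests$est
  cover <- vapply(ids, function(q) {
    r <- ests[[q]]
    if (is.null(r)) return(-1L)
    sum(vapply(seq_len(r$blockCount), function(b) {
      sum(overlap_len(r$tStarts[b], r$tStarts[b] + r$blockSizes[b],
                      regions$start, regions$end))
    }, integer(1)))
  }, integer(1))
  matches <- vapply(ids, function(q) {
    r <- ests[[q]]
    if (is.null(r)) -1L else r$matches
  }, integer(1))
  o <- order(-cover, -matches, ids, method = "radix")
  ids[o[1]]
}

#' Compare evolutionary rates between a novel exon and its flanking exons
#'
#' Builds codon alignments for the novel exon and the concatenated CDS
#' portions of its flanking exons against the same best-supporting subject
#' EST, estimates NG86/Jukes-Cantor rates for both, and runs the exact tests
#' for the dn and ds differences plus the neutrality test on the novel exon.
#'
#' @param candidate An accepted CDS-region `NovelExonCandidate`.
#' @param annotation A `GenomeAnnotation`.
#' @param genome A `SequenceSet`.
#' @param ests Named list of `PslRecord`s (EST id -> best hit).
#' @param est_seqs `SequenceSet` of subject EST sequences.
#' @param rounding Rounding mode for the contingency tables.
#' @return A list of class `RateComparison` with `novel`, `flanking`,
#'   `delta_dn`, `delta_ds`, `delta_omega`, `p_dn`, `p_ds`, `neutrality`,
#'   and `est` (the EST used).
#' @export
compare_rates <- function(candidate, annotation, genome, ests, est_seqs,
                          rounding = "half_up") {
  if (candidate$region != "CDS") {
    stop_fmt("compare_rates: candidate %s is not in CDS", candidate$id)
  }
  tx <- annotation$transcripts[[candidate$host_transcript]]
  flank <- concatenate_flanking(candidate, tx, genome)
  novel_regions <- data.frame(start = candidate$start, end = candidate$end)
  novel_pos <- if (tx$strand == "+") candidate$start else candidate$end
  novel_offset <- frame_offset_at(tx, novel_pos)
  all_regions <- rbind(novel_regions, flank$regions)
  est_id <- pick_rate_est(candidate, all_regions, ests)
  rec <- ests[[est_id]]
  eseq <- est_seqs[[est_id]]
  chrom_seq <- genome[[candidate$chrom]]
  novel_aln <- build_codon_alignment(novel_regions, tx$strand, novel_offset,
                                     chrom_seq, rec, eseq)
  flank_aln <- build_codon_alignment(flank$regions, tx$strand,
                                     flank$frame_offset, chrom_seq, rec, eseq)
  novel_est <- estimate_rates(novel_aln)
  flank_est <- estimate_rates(flank_aln)
  p <- fisher_rate_difference(novel_est, flank_est, rounding)
  structure(list(
    novel = novel_est, flanking = flank_est,
    delta_dn = novel_est$dn - flank_est$dn,
    delta_ds = novel_est$ds - flank_est$ds,
    delta_omega = novel_est$omega - flank_est$omega,
    p_dn = unname(p["p_dn"]), p_ds = unname(p["p_ds"]),
    neutrality = test_neutrality(novel_est, rounding),
    est = est_id), class = "RateComparison")
}
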