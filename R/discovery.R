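## Core discovery stage: turn subject-species spliced EST alignments into
## validated novel cassette-exon / retained-intron candidates and assemble
## the supported novel isoforms (ASVs).
##
## Filter criteria (each tracked as a named flag on every candidate):
##   length        - cassette exon length strictly greater than min_exon_len
##   flank_overlap - both adjacent EST segments overlap an annotated exon of
##                   the host transcript by >= min_flank_overlap bp
##   splice_site   - cassette exon flanked by an allowed splice-site pair
##                   within +/- splice_window bp of each boundary
##   frame         - CDS events: inserted length is a multiple of 3
##   premature_stop- CDS events: reconstructed CDS translates without a stop
##                   before the annotated one (evaluated only if frame holds)
##   novelty       - no overlap with target-species EST blocks or annotated
##                   exons of any transcript

#' Discovery configuration
#'
#' @param min_exon_len Minimum cassette exon length in bp, exclusive bound
#'   (a candidate must be strictly longer). Default 50.
#' @param min_flank_overlap Minimum overlap of each flanking EST segment with
#'   an annotated exon of the host transcript, inclusive bound. Default 50.
#' @param splice_window Maximum boundary shift (bp) when searching for splice
#'   sites, applied independently at each boundary. Default 10.
#' @param canonical_sites,noncanonical_sites Ordered character vectors of
#'   donor-acceptor dinucleotide pairs, searched in order; non-canonical
#'   pairs are only considered when no canonical pair exists in the window.
#' @param allow_noncanonical Accept non-canonical pairs? Default `TRUE`
#'   (candidates record whether their site is canonical, so downstream
#'   analyses can restrict to canonical events).
#' @return A list of class `DiscoveryConfig`.
#' @export
discovery_config <- function(min_exon_len = 50L,
                             min_flank_overlap = 50L,
                             splice_window = 10L,
                             canonical_sites = c("GT-AG", "GC-AG", "AT-AC"),
                             noncanonical_sites = c("AT-AA", "AT-AG", "AT-AT",
                                                    "GT-AT", "GT-GG"),
                             allow_noncanonical = TRUE) {
  stopifnot(min_exon_len >= 1L, splice_window >= 0L, min_flank_overlap >= 0L)
  structure(list(min_exon_len = as.integer(min_exon_len),
                 min_flank_overlap = as.integer(min_flank_overlap),
                 splice_window = as.integer(splice_window),
                 canonical_sites = canonical_sites,
                 noncanonical_sites = noncanonical_sites,
                 allow_noncanonical = isTRUE(allow_noncanonical)),
            class = "DiscoveryConfig")
}

#' Select the best hit among a query's alignments
#'
#' The best hit maximises `matches - misMatches`; ties are broken
#' deterministically by ascending (tName, tStart).
#'
#' @param alignments List of `PslRecord` objects sharing one `qName`.
#' @return The selected `PslRecord`.
#' @export
best_hit <- function(alignments) {
  if (length(alignments) == 0L) stop_fmt("best_hit: empty alignment list")
  qn <- unique(vapply(alignments, `[[`, character(1), "qName"))
  if (length(qn) != 1L) stop_fmt("best_hit: records have differing qName")
  score <- vapply(alignments, function(r) r$matches - r$misMatches, numeric(1))
  tn <- vapply(alignments, `[[`, character(1), "tName")
  ts <- vapply(alignments, function(r) r$tStart, integer(1))
  o <- order(-score, tn, ts, method = "radix")
  alignments[[o[1]]]
}

#' @noRd
new_candidate <- function(chrom, start, end, type, strand, host_transcript,
                          host_gene, host_intron, flank_overlaps,
                          est, species) {
  structure(list(
    id = NA_character_, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    type = type, strand = strand,
    host_transcript = host_transcript, host_gene = host_gene,
    host_intron = as.integer(host_intron),
    region = NA_character_, splice_class = NA_character_,
    splice_canonical = NA,
    boundary_shifts = c(0L, 0L),
    supporting_ests = data.frame(est = est, species = species,
                                 stringsAsFactors = FALSE),
    flank_overlaps = as.integer(flank_overlaps),
    filter_flags = c(length = NA, flank_overlap = NA, splice_site = NA,
                     frame = NA, premature_stop = NA, novelty = NA)),
    class = "NovelExonCandidate")
}

#' Detect raw cassette / retained-intron candidates from one EST alignment
#'
#' Cassette: an internal EST block lying strictly inside one annotated intron
#' of a host transcript, whose adjacent blocks each overlap an annotated exon
#' of the same transcript. Retained intron: a single EST block covering an
#' entire annotated intron and reaching into both flanking exons. Length and
#' flank-overlap flags are evaluated here; candidates failing them are still
#' returned (flagged) so attrition can be reported.
#'
#' @param est A `PslRecord` (the best hit for its query).
#' @param annotation A `GenomeAnnotation`.
#' @param genome A `SequenceSet` (unused here; kept for interface symmetry).
#' @param config A `DiscoveryConfig`.
#' @param species Subject species label recorded on the supporting-EST list.
#' @return List of `NovelExonCandidate` objects (possibly empty).
#' @export
detect_candidates <- function(est, annotation, genome, config,
                              species = NA_character_) {
  itab <- annotation$intron_tbl
  itab <- itab[itab$chrom == est$tName, , drop = FALSE]
  if (nrow(itab) == 0L) return(list())
  bs <- est$tStarts
  be <- est$tStarts + est$blockSizes
  n <- est$blockCount
  out <- list()

  max_exon_overlap <- function(tx, s, e) {
    if (s >= e) return(0L)
    max(c(0L, overlap_len(s, e, tx$exons$start, tx$exons$end)))
  }

  ## cassette: internal blocks strictly inside an intron
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      hosts <- which(itab$start < bs[i] & be[i] < itab$end)
      for (h in hosts) {
        tx <- annotation$transcripts[[itab$transcript[h]]]
        up <- max_exon_overlap(tx, bs[i - 1L], be[i - 1L])
        dn <- max_exon_overlap(tx, bs[i + 1L], be[i + 1L])
        cand <- new_candidate(
          chrom = est$tName, start = bs[i], end = be[i], type = "cassette",
          strand = tx$strand, host_transcript = tx$id, host_gene = tx$gene_id,
          host_intron = c(itab$start[h], itab$end[h]),
          flank_overlaps = c(up, dn), est = est$qName, species = species)
        cand$filter_flags["length"] <- (be[i] - bs[i]) > config$min_exon_len
        cand$filter_flags["flank_overlap"] <-
          up >= config$min_flank_overlap && dn >= config$min_flank_overlap
        out[[length(out) + 1L]] <- cand
      }
    }
  }

  ## retained intron: one block covering an intron plus both flanks
  for (i in seq_len(n)) {
    hosts <- which(itab$start >= bs[i] & itab$end <= be[i] &
                   itab$start > bs[i] & itab$end < be[i])
    for (h in hosts) {
      tx <- annotation$transcripts[[itab$transcript[h]]]
      k <- itab$index[h]
      up_exon <- c(tx$exons$start[k], tx$exons$end[k])
      dn_exon <- c(tx$exons$start[k + 1L], tx$exons$end[k + 1L])
      up <- overlap_len(bs[i], be[i], up_exon[1], up_exon[2])
      dn <- overlap_len(bs[i], be[i], dn_exon[1], dn_exon[2])
      cand <- new_candidate(
        chrom = est$tName, start = itab$start[h], end = itab$end[h],
        type = "retained_intron", strand = tx$strand,
        host_transcript = tx$id, host_gene = tx$gene_id,
        host_intron = c(itab$start[h], itab$end[h]),
        flank_overlaps = c(up, dn), est = est$qName, species = species)
      cand$splice_class <- "none"
      cand$filter_flags["flank_overlap"] <-
        up >= config$min_flank_overlap && dn >= config$min_flank_overlap
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Dinucleotides flanking a candidate exon, in transcript orientation
#'
#' For an exon at [s,e) inside an intron: the acceptor of the upstream
#' residual intron is the 2 bp immediately 5' of the exon and the donor of
#' the downstream residual intron the 2 bp immediately 3' of it (both in
#' transcript orientation; reverse-complemented on the minus strand).
#' @noRd
flanking_dinucs <- function(seq, s, e, strand) {
  left <- seq_sub(seq, s - 2L, s)    # genome-left of exon start
  right <- seq_sub(seq, e, e + 2L)   # genome-right of exon end
  if (strand == "+") {
    list(acceptor = left, donor = right)
  } else {
    list(acceptor = revcomp(right), donor = revcomp(left))
  }
}

#' Refine cassette-exon boundaries to an allowed splice-site pair
#'
#' Each boundary is shifted independently by at most `splice_window` bp so
#' that the residual host-intron donor/acceptor dinucleotides match an
#' allowed pair. Pairs are tried in the configured order, canonical first;
#' non-canonical pairs are only examined when no canonical pair exists in
#' the window. At each boundary the smallest absolute shift wins, ties going
#' to the lower-coordinate (negative) shift. Shifts that would move a
#' boundary outside the host intron are never considered. When no allowed
#' pair exists in the window the splice-site criterion fails and
#' `splice_class` is `"none"`; when a pair is found the candidate interval
#' is updated and the length criterion re-evaluated on it.
#'
#' @param candidate A cassette `NovelExonCandidate`.
#' @param genome A `SequenceSet`.
#' @param config A `DiscoveryConfig`.
#' @return The candidate with updated interval, `boundary_shifts`,
#'   `splice_class`, `splice_canonical` and `filter_flags["splice_site"]`.
#' @export
refine_splice_sites <- function(candidate, genome, config) {
  if (candidate$type != "cassette") {
    stop_fmt("refine_splice_sites: candidate %s is not a cassette exon",
             candidate$id %||% "<unnamed>")
  }
  seq <- genome[[candidate$chrom]]
  w <- config$splice_window
  s0 <- candidate$start; e0 <- candidate$end
  is <- candidate$host_intron[1]; ie <- candidate$host_intron[2]
  shifts <- order(abs(-w:w), -w:w)  # 0, -1, 1, -2, 2, ...
  shifts <- (-w:w)[shifts]

  try_pair <- function(pair) {
    d <- strsplit(pair, "-", fixed = TRUE)[[1]]
    donor <- d[1]; acceptor <- d[2]
    dl <- NA_integer_; dr <- NA_integer_
    for (sh in shifts) {
      s <- s0 + sh
      if (s <= is || s >= e0) next
      di <- flanking_dinucs(seq, s, e0, candidate$strand)
      tgt <- if (candidate$strand == "+") di$acceptor else di$donor
      need <- if (candidate$strand == "+") acceptor else donor
      if (tgt == need) { dl <- sh; break }
    }
    if (is.na(dl)) return(NULL)
    for (sh in shifts) {
      e <- e0 + sh
      if (e >= ie || e <= s0 + dl) next
      di <- flanking_dinucs(seq, s0 + dl, e, candidate$strand)
      tgt <- if (candidate$strand == "+") di$donor else di$acceptor
      need <- if (candidate$strand == "+") donor else acceptor
      if (tgt == need) { dr <- sh; break }
    }
    if (is.na(dr)) return(NULL)
    list(dl = dl, dr = dr)
  }

  found <- NULL; found_pair <- NA_character_; canonical <- NA
  for (pair in config$canonical_sites) {
    found <- try_pair(pair)
    if (!is.null(found)) { found_pair <- pair; canonical <- TRUE; break }
  }
  if (is.null(found) && config$allow_noncanonical) {
    for (pair in config$noncanonical_sites) {
      found <- try_pair(pair)
      if (!is.null(found)) { found_pair <- pair; canonical <- FALSE; break }
    }
  }

  if (is.null(found)) {
    candidate$splice_class <- "none"
    candidate$splice_canonical <- NA
    candidate$filter_flags["splice_site"] <- FALSE
    return(candidate)
  }
  new_s <- s0 + found$dl; new_e <- e0 + found$dr
  candidate$start <- new_s
  candidate$end <- new_e
  # the length criterion is re-evaluated on the refined interval: shifting
  # may move a candidate across the minimum-length bound in either direction
  candidate$filter_flags["length"] <- (new_e - new_s) > config$min_exon_len
  candidate$boundary_shifts <- c(found$dl, found$dr)
  candidate$splice_class <- found_pair
  candidate$splice_canonical <- canonical
  candidate$filter_flags["splice_site"] <- TRUE
  candidate
}

#' Check the reading-frame criterion for a CDS candidate
#'
#' The inserted length (exon length for cassettes, intron length for retained
#' introns) must be a multiple of 3, and the reconstructed CDS — the
#' annotated CDS with the candidate sequence spliced in at its genomic
#' position, strand-aware — must translate without a stop codon before the
#' annotated one. Re-translating the entire reconstructed CDS catches stops
#' spanning the new junctions.
#'
#' @param candidate A `NovelExonCandidate` classified as CDS.
#' @param transcript Its host `TranscriptModel` (must be coding).
#' @param genome A `SequenceSet`.
#' @return List with elements `frame_ok`, `stop_ok` (NA when the frame check
#'   fails) and `pass`.
#' @export
check_cds_frame <- function(candidate, transcript, genome) {
  if (!transcript$coding) {
    stop_fmt("check_cds_frame: transcript %s has no CDS", transcript$id)
  }
  ins_len <- candidate$end - candidate$start
  frame_ok <- (ins_len %% 3L) == 0L
  if (!frame_ok) {
    return(list(frame_ok = FALSE, stop_ok = NA, pass = FALSE))
  }
  segs <- rbind(transcript$cds,
                data.frame(start = candidate$start, end = candidate$end))
  segs <- segs[order(segs$start), , drop = FALSE]
  cds_seq <- spliced_sequence(genome, candidate$chrom, segs,
                              transcript$strand)
  aa <- translate_in_frame(cds_seq, 0L)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  stops <- stops[stops > 0L]
  n_aa <- nchar(aa)
  premature <- any(stops < n_aa)
  list(frame_ok = TRUE, stop_ok = !premature, pass = !premature)
}

#' Partition candidates into novel and known
#'
#' A candidate is *known* when its interval overlaps, by at least 1 bp, any
#' aligned block of a target-species EST or any annotated exon of any
#' transcript; otherwise it is novel. Both partitions are returned so
#' same-species-supported events can be retained on request.
#'
#' @param candidates List of `NovelExonCandidate` objects.
#' @param target_ests List of `PslRecord` target-species alignments (may be
#'   empty).
#' @param annotation A `GenomeAnnotation`.
#' @return List with elements `novel` and `known`; each candidate's
#'   `filter_flags["novelty"]` is set.
#' @export
novelty_filter <- function(candidates, target_ests, annotation) {
  if (length(target_ests) > 0L) {
    tb <- do.call(rbind, lapply(target_ests, function(r) {
      data.frame(chrom = r$tName, start = r$tStarts,
                 end = r$tStarts + r$blockSizes, stringsAsFactors = FALSE)
    }))
  } else {
    tb <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  }
  etab <- annotation$exon_tbl
  novel <- list(); known <- list()
  for (cand in candidates) {
    hit_est <- nrow(tb) > 0L && any(tb$chrom == cand$chrom &
                                    overlaps(cand$start, cand$end,
                                             tb$start, tb$end))
    hit_exon <- nrow(etab) > 0L && any(etab$chrom == cand$chrom &
                                       overlaps(cand$start, cand$end,
                                                etab$start, etab$end))
    is_novel <- !(hit_est || hit_exon)
    cand$filter_flags["novelty"] <- is_novel
    if (is_novel) novel[[length(novel) + 1L]] <- cand
    else known[[length(known) + 1L]] <- cand
  }
  list(novel = novel, known = known)
}

#' Assemble novel ASVs from accepted candidates
#'
#' One ASV per (source EST, host transcript) pair, grouping all of that EST's
#' accepted novel exons in the transcript; the flanking segments are the
#' EST's blocks intersected with the transcript's annotated exons. A novel
#' exon supported by several ESTs with differently-bounded flanks therefore
#' yields several ASVs.
#'
#' @param candidates Accepted `NovelExonCandidate` objects (ids assigned).
#' @param ests Named list mapping EST id to its best-hit `PslRecord`.
#' @param est_species Named character vector mapping EST id to species.
#' @return List of `NovelASV` objects, deterministically ordered.
#' @export
assemble_asvs <- function(candidates, ests, est_species = NULL) {
  if (length(candidates) == 0L) return(list())
  links <- do.call(rbind, lapply(candidates, function(cc) {
    data.frame(est = cc$supporting_ests$est,
               species = cc$supporting_ests$species,
               transcript = cc$host_transcript, exon = cc$id,
               chrom = cc$chrom, strand = cc$strand,
               stringsAsFactors = FALSE)
  }))
  keys <- paste(links$est, links$transcript, sep = "\r")
  out <- list()
  for (key in sort(unique(keys))) {
    grp <- links[keys == key, , drop = FALSE]
    est_id <- grp$est[1]; tx_id <- grp$transcript[1]
    rec <- ests[[est_id]]
    if (is.null(rec)) next
    # flanking segments: the EST's blocks that are not the novel exons
    ex_iv <- do.call(rbind, lapply(candidates, function(cc) {
      if (cc$id %in% grp$exon) data.frame(start = cc$start, end = cc$end)
      else NULL
    }))
    segs <- data.frame(start = rec$tStarts,
                       end = rec$tStarts + rec$blockSizes)
    if (!is.null(ex_iv) && nrow(ex_iv) > 0L) {
      segs <- interval_subtract(segs, ex_iv)
    }
    asv <- structure(list(
      id = NA_character_, source_est = est_id,
      species = unname(grp$species[1]),
      host_transcript = tx_id, chrom = grp$chrom[1], strand = grp$strand[1],
      exon_ids = sort(unique(grp$exon)),
      flank_segments = segs), class = "NovelASV")
    out[[length(out) + 1L]] <- asv
  }
  key2 <- vapply(out, function(a) paste(a$chrom, a$host_transcript,
                                        a$source_est), character(1))
  out <- out[order(key2, method = "radix")]
  for (k in seq_along(out)) out[[k]]$id <- sprintf("ASV%05d", k)
  out
}

#' Run the full discovery pipeline
#'
#' Orchestrates best-hit selection, candidate detection, splice-site
#' refinement (after which the length criterion is re-evaluated on the
#' refined interval), region classification, frame checking, the novelty
#' filter and
#' ASV assembly. Every criterion is evaluated for every candidate (no
#' short-circuiting), so each rejected candidate carries the full set of
#' flags and the attrition report is exact.
#'
#' @param config A `DiscoveryConfig`.
#' @param genome A `SequenceSet`.
#' @param annotation A `GenomeAnnotation`.
#' @param subject_psls Named list (species -> list of `PslRecord`) of subject
#'   EST alignments, or a flat list for a single unnamed species.
#' @param target_psl List of target-species `PslRecord`s (or `NULL`).
#' @param keep_same_species Keep candidates that fail only the novelty
#'   criterion in the returned `known` slot? They are always excluded from
#'   the accepted set. Default `TRUE` (they are reported).
#' @return List with `candidates` (accepted, ids assigned, sorted),
#'   `rejected` (flagged failures), `asvs`, and `report` (per-criterion
#'   attrition data.frame).
#' @export
run_discovery <- function(config, genome, annotation, subject_psls,
                          target_psl = NULL, keep_same_species = TRUE) {
  if (length(subject_psls) > 0L && inherits(subject_psls[[1]], "PslRecord")) {
    subject_psls <- list(subject = subject_psls)
  }
  if (is.null(names(subject_psls))) {
    names(subject_psls) <- paste0("subject", seq_along(subject_psls))
  }

  ## best hit per EST, per species
  best <- list(); est_species <- character(0)
  for (sp in names(subject_psls)) {
    recs <- subject_psls[[sp]]
    if (length(recs) == 0L) next
    qn <- vapply(recs, `[[`, character(1), "qName")
    for (q in unique(qn)) {
      b <- best_hit(recs[qn == q])
      best[[q]] <- b
      est_species[q] <- sp
    }
  }

  ## detect, per EST
  cands <- list()
  for (q in names(best)) {
    cands <- c(cands, detect_candidates(best[[q]], annotation, genome,
                                        config, species = est_species[q]))
  }

  ## merge duplicates across ESTs: key = (chrom, interval, type, transcript)
  if (length(cands) > 0L) {
    keys <- vapply(cands, function(cc) {
      paste(cc$chrom, cc$start, cc$end, cc$type, cc$host_transcript)
    }, character(1))
    merged <- list()
    for (key in unique(keys)) {
      grp <- cands[keys == key]
      m <- grp[[1]]
      if (length(grp) > 1L) {
        sup <- do.call(rbind, lapply(grp, `[[`, "supporting_ests"))
        sup <- sup[!duplicated(sup$est), , drop = FALSE]
        sup <- sup[order(sup$est), , drop = FALSE]
        rownames(sup) <- NULL
        m$supporting_ests <- sup
        m$flank_overlaps <- c(
          max(vapply(grp, function(g) g$flank_overlaps[1], integer(1))),
          max(vapply(grp, function(g) g$flank_overlaps[2], integer(1))))
        m$filter_flags["flank_overlap"] <-
          m$flank_overlaps[1] >= config$min_flank_overlap &&
          m$flank_overlaps[2] >= config$min_flank_overlap
      }
      merged[[length(merged) + 1L]] <- m
    }
    cands <- merged
  }

  ## splice refinement (cassettes), region, frame, novelty
  for (k in seq_along(cands)) {
    if (cands[[k]]$type == "cassette") {
      cands[[k]] <- refine_splice_sites(cands[[k]], genome, config)
      if (isTRUE(cands[[k]]$splice_canonical == FALSE) &&
          !config$allow_noncanonical) {
        cands[[k]]$filter_flags["splice_site"] <- FALSE
      }
    }
    tx <- annotation$transcripts[[cands[[k]]$host_transcript]]
    cands[[k]]$region <- classify_region(
      c(cands[[k]]$start, cands[[k]]$end), tx)
    if (cands[[k]]$region == "CDS" && tx$coding) {
      fr <- check_cds_frame(cands[[k]], tx, genome)
      cands[[k]]$filter_flags["frame"] <- fr$frame_ok
      cands[[k]]$filter_flags["premature_stop"] <- fr$stop_ok
    }
  }
  nv <- novelty_filter(cands, target_psl %||% list(), annotation)
  cands <- c(nv$novel, nv$known)

  accepted_mask <- vapply(cands, function(cc) {
    all(cc$filter_flags[!is.na(cc$filter_flags)])
  }, logical(1))
  accepted <- cands[accepted_mask]
  rejected <- cands[!accepted_mask]

  accepted <- accepted[order_candidates(accepted)]
  for (k in seq_along(accepted)) accepted[[k]]$id <- sprintf("NE%05d", k)
  rejected <- rejected[order_candidates(rejected)]
  for (k in seq_along(rejected)) rejected[[k]]$id <- sprintf("RX%05d", k)

  asvs <- assemble_asvs(accepted, best, est_species)

  flag_names <- c("length", "flank_overlap", "splice_site", "frame",
                  "premature_stop", "novelty")
  fail_counts <- vapply(flag_names, function(fn) {
    sum(vapply(cands, function(cc) isFALSE(cc$filter_flags[[fn]]),
               logical(1)))
  }, integer(1))
  report <- data.frame(
    criterion = c("detected", flag_names, "accepted"),
    count = c(length(cands), unname(fail_counts), length(accepted)),
    stringsAsFactors = FALSE)

  list(candidates = accepted, rejected = rejected, asvs = asvs,
       report = report)
}

#' Independently re-validate an accepted candidate
#'
#' Re-reads genome and annotation and re-checks every criterion from the
#' candidate's recorded interval, without reusing any state computed during
#' discovery. Used as a soundness check on pipeline output.
#'
#' @param candidate An accepted `NovelExonCandidate`.
#' @param genome,annotation,config As for [run_discovery()].
#' @param target_psl Target-species alignments used for the novelty check.
#' @return `TRUE` when every criterion holds, otherwise a character vector
#'   naming the violated criteria.
#' @export
revalidate_candidate <- function(candidate, genome, annotation, config,
                                 target_psl = NULL) {
  tx <- annotation$transcripts[[candidate$host_transcript]]
  bad <- character(0)
  s <- candidate$start; e <- candidate$end
  if (candidate$type == "cassette") {
    if ((e - s) <= config$min_exon_len) bad <- c(bad, "length")
    di <- flanking_dinucs(genome[[candidate$chrom]], s, e, tx$strand)
    pair <- paste(di$donor, di$acceptor, sep = "-")
    allowed <- c(config$canonical_sites,
                 if (config$allow_noncanonical) config$noncanonical_sites)
    if (!(pair %in% allowed) || grepl("N", pair)) bad <- c(bad, "splice_site")
    if (!(candidate$host_intron[1] < s && e < candidate$host_intron[2])) {
      bad <- c(bad, "inside_intron")
    }
  } else {
    if (!(s == candidate$host_intron[1] && e == candidate$host_intron[2])) {
      bad <- c(bad, "interval_is_intron")
    }
  }
  if (any(candidate$flank_overlaps < config$min_flank_overlap)) {
    bad <- c(bad, "flank_overlap")
  }
  region <- classify_region(c(s, e), tx)
  if (region == "CDS" && tx$coding) {
    fr <- check_cds_frame(candidate, tx, genome)
    if (!fr$pass) bad <- c(bad, "frame")
  }
  nv <- novelty_filter(list(candidate), target_psl %||% list(), annotation)
  if (length(nv$novel) == 0L) bad <- c(bad, "novelty")
  if (length(bad) == 0L) TRUE else bad
}
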