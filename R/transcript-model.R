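## Queryable transcript structures: exon/intron layout, CDS/UTR partition,
## and classification of intronic intervals against them. All coordinates
## 0-based half-open on the forward genome strand.

#' Construct a TranscriptModel
#'
#' @param id Transcript id.
#' @param gene_id Parent gene id.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   any order; sorted internally in ascending genome order.
#' @param cds Optional data.frame of CDS segments (`start`, `end`); `NULL`
#'   for non-coding transcripts.
#' @return An object of class `TranscriptModel` with derived `introns`,
#'   `cds_span` and `coding` fields.
#' @export
transcript_model <- function(id, gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop_fmt("transcript %s: overlapping exons", id)
  }
  tx <- structure(list(
    id = id, gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, cds = NULL, cds_span = NULL, coding = FALSE),
    class = "TranscriptModel")
  if (!is.null(cds) && nrow(cds) > 0L) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    rownames(cds) <- NULL
    tx$cds <- cds
    tx$cds_span <- c(min(cds$start), max(cds$end))
    tx$coding <- TRUE
    if (sum(cds$end - cds$start) %% 3L != 0L) {
      stop_fmt("transcript %s: exonic CDS length not a multiple of 3", id)
    }
  }
  tx$introns <- derive_introns(tx)
  tx
}

#' Derive introns as the gaps between consecutive exons
#'
#' @param transcript A `TranscriptModel`.
#' @return A data.frame of `start`, `end` intervals in ascending genome
#'   order; zero rows for single-exon transcripts. Abutting exons (a
#'   zero-length gap) are rejected as malformed annotation.
#' @export
derive_introns <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  if (n <= 1L) return(data.frame(start = integer(0), end = integer(0)))
  s <- ex$end[-n]
  e <- ex$start[-1]
  if (any(e <= s)) {
    stop_fmt("transcript %s: abutting exons imply a zero-length intron (malformed annotation)",
             transcript$id)
  }
  data.frame(start = s, end = e)
}

#' Assemble a GenomeAnnotation from TranscriptModels
#'
#' Builds per-chromosome exon and intron lookup tables used by the discovery
#' stage for interval classification.
#'
#' @param transcripts Named or unnamed list of `TranscriptModel` objects.
#' @return An object of class `GenomeAnnotation` with fields `transcripts`
#'   (named list), `genes` (gene id -> transcript ids), `exon_tbl` and
#'   `intron_tbl` (flat data.frames with chrom/start/end/transcript/gene/
#'   strand, plus intron index).
#' @export
build_annotation <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_fmt("duplicate transcript id: %s",
                                   ids[duplicated(ids)][1])
  names(transcripts) <- ids
  genes <- split(ids, vapply(transcripts, `[[`, character(1), "gene_id"))
  etab <- do.call(rbind, lapply(transcripts, function(tx) {
    if (nrow(tx$exons) == 0L) return(NULL)
    data.frame(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end,
               transcript = tx$id, gene = tx$gene_id, strand = tx$strand,
               stringsAsFactors = FALSE)
  }))
  itab <- do.call(rbind, lapply(transcripts, function(tx) {
    if (nrow(tx$introns) == 0L) return(NULL)
    data.frame(chrom = tx$chrom, start = tx$introns$start,
               end = tx$introns$end, transcript = tx$id, gene = tx$gene_id,
               strand = tx$strand, index = seq_len(nrow(tx$introns)),
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), transcript = character(0),
                      gene = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(etab)) etab <- empty
  if (is.null(itab)) itab <- cbind(empty, data.frame(index = integer(0)))
  rownames(etab) <- rownames(itab) <- NULL
  structure(list(transcripts = transcripts, genes = genes,
                 exon_tbl = etab, intron_tbl = itab),
            class = "GenomeAnnotation")
}

#' Classify an intronic interval into 5'UTR / CDS / 3'UTR
#'
#' Strand-aware: the 5' UTR lies upstream of the CDS span on the transcript's
#' strand. Intervals that overlap the CDS span at all are classified `CDS`
#' (the stricter frame filter then applies). Non-coding transcripts yield
#' `"noncoding"` and are excluded from CDS-dependent filters.
#'
#' @param interval Numeric/integer length-2 vector `c(start, end)` (0-based
#'   half-open).
#' @param transcript A `TranscriptModel`.
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"noncoding"`.
#' @export
classify_region <- function(interval, transcript) {
  s <- interval[1]; e <- interval[2]
  span_s <- transcript$exons$start[1]
  span_e <- transcript$exons$end[nrow(transcript$exons)]
  if (s < span_s || e > span_e) {
    stop_fmt("interval [%d,%d) outside transcript %s span", s, e,
             transcript$id)
  }
  if (!transcript$coding) return("noncoding")
  cs <- transcript$cds_span[1]; ce <- transcript$cds_span[2]
  if (overlaps(s, e, cs, ce)) return("CDS")
  upstream_in_genome <- e <= cs
  if (transcript$strand == "+") {
    if (upstream_in_genome) "FIVE_UTR" else "THREE_UTR"
  } else {
    if (upstream_in_genome) "THREE_UTR" else "FIVE_UTR"
  }
}

#' Identify pure (constitutive) introns
#'
#' A pure intron is an annotated intron that (a) does not overlap any
#' alternative exon — either one supplied in `alt_exons` (e.g. accepted
#' novel-exon candidates) or an annotated exon that is absent from at least
#' one isoform of its gene — and (b) is flanked by two exons annotated
#' identically in every isoform of the gene (constitutive flanks).
#'
#' @param annotation A `GenomeAnnotation`.
#' @param alt_exons data.frame with columns chrom/start/end of alternative
#'   exon intervals (may have zero rows).
#' @return data.frame chrom/start/end/gene of pure introns, deduplicated and
#'   sorted by (chrom, start, end).
#' @export
pure_introns <- function(annotation,
                         alt_exons = data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0))) {
  ann_alt <- alternative_annotated_exons(annotation)
  alt <- rbind(alt_exons[, c("chrom", "start", "end"), drop = FALSE],
               ann_alt[, c("chrom", "start", "end"), drop = FALSE])
  out <- list()
  for (gene in names(annotation$genes)) {
    tids <- annotation$genes[[gene]]
    txs <- annotation$transcripts[tids]
    # exon intervals present (identically) in every isoform of this gene
    keys_per_tx <- lapply(txs, function(tx)
      paste(tx$chrom, tx$exons$start, tx$exons$end))
    constitutive <- Reduce(intersect, keys_per_tx)
    for (tx in txs) {
      itr <- tx$introns
      if (nrow(itr) == 0L) next
      for (j in seq_len(nrow(itr))) {
        f5 <- paste(tx$chrom, tx$exons$start[j], tx$exons$end[j])
        f3 <- paste(tx$chrom, tx$exons$start[j + 1L], tx$exons$end[j + 1L])
        if (!(f5 %in% constitutive) || !(f3 %in% constitutive)) next
        hit <- nrow(alt) > 0L && any(alt$chrom == tx$chrom &
                                     overlaps(itr$start[j], itr$end[j],
                                              alt$start, alt$end))
        if (hit) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = tx$chrom, start = itr$start[j], end = itr$end[j],
          gene = gene, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$chrom, res$start, res$end)), , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotated exons absent from at least one isoform of their gene
#' @noRd
alternative_annotated_exons <- function(annotation) {
  out <- list()
  for (gene in names(annotation$genes)) {
    tids <- annotation$genes[[gene]]
    if (length(tids) < 2L) next
    txs <- annotation$transcripts[tids]
    keys_per_tx <- lapply(txs, function(tx)
      paste(tx$chrom, tx$exons$start, tx$exons$end))
    constitutive <- Reduce(intersect, keys_per_tx)
    for (tx in txs) {
      keys <- paste(tx$chrom, tx$exons$start, tx$exons$end)
      sel <- !(keys %in% constitutive)
      if (any(sel)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = tx$chrom, start = tx$exons$start[sel],
          end = tx$exons$end[sel], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$chrom, res$start, res$end)), , drop = FALSE]
}

#' Translate a nucleotide string in a given frame
#'
#' Standard nuclear genetic code; only complete codons are translated and a
#' trailing partial codon is ignored. Codons containing `N` translate to
#' `"X"`; stop codons to `"*"`.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param frame_offset 0, 1 or 2 bases to skip before the first codon.
#' @return Amino-acid string.
#' @export
translate_in_frame <- function(sequence, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  check_alphabet(sequence)
  s <- substr(sequence, frame_offset + 1L, nchar(sequence))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the spliced sequence of genomic segments
#'
#' Concatenates the forward-strand sequence of `segments` (ascending genome
#' order) and reverse-complements the result for minus-strand transcripts,
#' yielding the 5'->3' transcript-orientation sequence.
#' @noRd
spliced_sequence <- function(genome, chrom, segments, strand) {
  seq <- genome[[chrom]]
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    seq_sub(seq, segments$start[i], segments$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}
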