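## Readers/writers for the external formats the pipeline touches: FASTA
## (genome, EST sequences), GFF3 (annotation in, novel exons out) and PSL
## (BLAT spliced alignments). Coordinate conventions are converted here and
## nowhere else.

#' Read a FASTA file into a SequenceSet
#'
#' Loads every record, uppercases the sequence and takes the id as the first
#' whitespace-delimited token of the header. The alphabet is restricted to
#' A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `SequenceSet` (id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">")) {
    stop_fmt("malformed FASTA header at line 1 of %s", path)
  }
  dss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(dss), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_fmt("duplicated FASTA id: %s", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(dss))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop_fmt("empty sequence for FASTA record '%s'",
             ids[nchar(seqs) == 0L][1])
  }
  check_alphabet(seqs, "FASTA sequence")
  structure(seqs, class = "SequenceSet")
}

#' Write a SequenceSet (or named character vector) as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(unclass(seqs))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

## ---- PSL ------------------------------------------------------------------

.psl_int_cols <- c("matches", "misMatches", "repMatches", "nCount",
                   "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert")

#' Construct a PSL record (spliced EST-to-genome alignment)
#'
#' Target coordinates follow the PSL standard: 0-based half-open, always on
#' the forward target strand. `strand` is the query strand only; translated
#' two-character PSL strands are rejected at parse time.
#'
#' @param qName,qSize,qStart,qEnd Query (EST) id and coordinates.
#' @param tName,tSize,tStart,tEnd Target (chromosome) id and coordinates.
#' @param strand `"+"` or `"-"` (query strand).
#' @param blockSizes,qStarts,tStarts Integer vectors, one entry per aligned
#'   block, `tStarts` ascending.
#' @param matches,misMatches Match/mismatch base counts.
#' @param ... Remaining PSL columns (default 0).
#' @return An object of class `PslRecord`.
#' @export
psl_record <- function(qName, qSize, qStart, qEnd, tName, tSize, tStart, tEnd,
                       strand, blockSizes, qStarts, tStarts,
                       matches = sum(blockSizes), misMatches = 0L, ...) {
  extra <- list(...)
  rec <- list(
    matches = as.integer(matches), misMatches = as.integer(misMatches),
    repMatches = as.integer(extra$repMatches %||% 0L),
    nCount = as.integer(extra$nCount %||% 0L),
    qNumInsert = as.integer(extra$qNumInsert %||% 0L),
    qBaseInsert = as.integer(extra$qBaseInsert %||% 0L),
    tNumInsert = as.integer(extra$tNumInsert %||% 0L),
    tBaseInsert = as.integer(extra$tBaseInsert %||% 0L),
    strand = strand,
    qName = qName, qSize = as.integer(qSize),
    qStart = as.integer(qStart), qEnd = as.integer(qEnd),
    tName = tName, tSize = as.integer(tSize),
    tStart = as.integer(tStart), tEnd = as.integer(tEnd),
    blockCount = length(blockSizes),
    blockSizes = as.integer(blockSizes),
    qStarts = as.integer(qStarts), tStarts = as.integer(tStarts))
  class(rec) <- "PslRecord"
  validate_psl_record(rec)
  rec
}

#' @noRd
validate_psl_record <- function(rec, where = "") {
  ctx <- if (nzchar(where)) paste0(" (", where, ")") else ""
  if (!rec$strand %in% c("+", "-")) {
    stop_fmt("PSL strand '%s' not supported%s: only untranslated single-character query strands '+'/'-'",
             rec$strand, ctx)
  }
  if (rec$tStart >= rec$tEnd) stop_fmt("PSL tStart >= tEnd%s", ctx)
  n <- rec$blockCount
  if (length(rec$blockSizes) != n || length(rec$qStarts) != n ||
      length(rec$tStarts) != n) {
    stop_fmt("PSL blockCount (%d) inconsistent with block list lengths%s", n, ctx)
  }
  if (n > 1L) {
    ends <- rec$tStarts + rec$blockSizes
    if (any(diff(rec$tStarts) <= 0L) || any(rec$tStarts[-1] < ends[-n])) {
      stop_fmt("PSL blocks out of order or overlapping on target%s", ctx)
    }
  }
  if (sum(rec$blockSizes) > rec$qSize) {
    stop_fmt("PSL sum(blockSizes) exceeds qSize%s", ctx)
  }
  if (rec$tStarts[1] < rec$tStart ||
      rec$tStarts[n] + rec$blockSizes[n] > rec$tEnd) {
    stop_fmt("PSL blocks outside [tStart,tEnd)%s", ctx)
  }
  invisible(rec)
}

#' Read a PSL alignment file
#'
#' Accepts the optional 5-line `psLayout` header. Target coordinates are kept
#' in PSL's native 0-based half-open convention (identical to the package's
#' internal convention). Per-record invariants (sorted non-overlapping target
#' blocks, consistent block counts) are enforced.
#'
#' @param path Path to a PSL file.
#' @return A list of `PslRecord` objects.
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop_fmt("PSL file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) > 0L && startsWith(lines[1], "psLayout")) {
    lines <- lines[-seq_len(min(5L, length(lines)))]
  }
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L) {
      stop_fmt("PSL line %d: expected 21 tab-separated fields, got %d",
               i, length(f))
    }
    parse_ints <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
    rec <- list(
      matches = as.integer(f[1]), misMatches = as.integer(f[2]),
      repMatches = as.integer(f[3]), nCount = as.integer(f[4]),
      qNumInsert = as.integer(f[5]), qBaseInsert = as.integer(f[6]),
      tNumInsert = as.integer(f[7]), tBaseInsert = as.integer(f[8]),
      strand = f[9],
      qName = f[10], qSize = as.integer(f[11]),
      qStart = as.integer(f[12]), qEnd = as.integer(f[13]),
      tName = f[14], tSize = as.integer(f[15]),
      tStart = as.integer(f[16]), tEnd = as.integer(f[17]),
      blockCount = as.integer(f[18]),
      blockSizes = parse_ints(f[19]),
      qStarts = parse_ints(f[20]), tStarts = parse_ints(f[21]))
    class(rec) <- "PslRecord"
    validate_psl_record(rec, where = sprintf("line %d", i))
    out[[i]] <- rec
  }
  out
}

#' Write PSL records to a file
#'
#' @param records List of `PslRecord` objects.
#' @param path Output path.
#' @param header Write the 5-line `psLayout` header? Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
write_psl <- function(records, path, header = FALSE) {
  fmt_list <- function(x) paste0(paste(x, collapse = ","), ",")
  lines <- vapply(records, function(r) {
    paste(r$matches, r$misMatches, r$repMatches, r$nCount,
          r$qNumInsert, r$qBaseInsert, r$tNumInsert, r$tBaseInsert,
          r$strand, r$qName, r$qSize, r$qStart, r$qEnd,
          r$tName, r$tSize, r$tStart, r$tEnd, r$blockCount,
          fmt_list(r$blockSizes), fmt_list(r$qStarts), fmt_list(r$tStarts),
          sep = "\t")
  }, character(1))
  if (header) {
    lines <- c("psLayout version 3", "",
               paste("match\tmis-\trep.\tN's\tQ gap\tQ gap\tT gap\tT gap",
                     "strand\tQ\tQ\tQ\tQ\tT\tT\tT\tT\tblock\tblockSizes",
                     "qStarts\ttStarts", sep = "\t"),
               "", paste(rep("-", 30), collapse = ""), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- GFF3 -----------------------------------------------------------------

#' Read a GFF3 gene annotation into a GenomeAnnotation
#'
#' Expects an Ensembl-style gene/mRNA(or transcript)/exon/CDS hierarchy linked
#' by `ID`/`Parent` attributes. All coordinates are converted from GFF3's
#' 1-based inclusive convention to the package's internal 0-based half-open
#' convention; exons are sorted in ascending genome order per transcript and
#' introns derived as the inter-exon gaps.
#'
#' @param path Path to a GFF3 file.
#' @return A `GenomeAnnotation` object (see [build_annotation()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_fmt("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  chrom <- as.character(GenomicRanges::seqnames(gr))
  # GFF3 1-based inclusive -> 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))

  is_gene <- typ == "gene"
  is_tx <- typ %in% c("mRNA", "transcript")
  gene_ids <- ids[is_gene]
  tx_ids <- ids[is_tx]
  if (anyNA(tx_ids)) stop_fmt("GFF3 transcript feature without ID attribute")
  tx_parent <- parents[is_tx]
  orphan <- !is.na(tx_parent) & !(tx_parent %in% gene_ids)
  if (any(orphan)) {
    stop_fmt("GFF3 orphan Parent reference '%s' (transcript %s)",
             tx_parent[orphan][1], tx_ids[orphan][1])
  }

  feats <- data.frame(type = typ, id = ids, parent = parents, chrom = chrom,
                      start = start0, end = end0, strand = strand,
                      stringsAsFactors = FALSE)
  sub_feats <- feats[feats$type %in% c("exon", "CDS"), , drop = FALSE]
  bad <- !is.na(sub_feats$parent) & !(sub_feats$parent %in% tx_ids)
  if (any(bad)) {
    stop_fmt("GFF3 orphan Parent reference '%s' (%s feature)",
             sub_feats$parent[bad][1], sub_feats$type[bad][1])
  }

  tx_list <- vector("list", length(tx_ids))
  names(tx_list) <- tx_ids
  tx_chrom <- chrom[is_tx]; tx_strand <- strand[is_tx]
  for (k in seq_along(tx_ids)) {
    tid <- tx_ids[k]
    ex <- sub_feats[sub_feats$type == "exon" & sub_feats$parent == tid, , drop = FALSE]
    cds <- sub_feats[sub_feats$type == "CDS" & sub_feats$parent == tid, , drop = FALSE]
    if (nrow(ex) == 0L) stop_fmt("GFF3 transcript %s has no exon features", tid)
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_iv <- NULL
    if (nrow(cds) > 0L) {
      cds <- cds[order(cds$start), , drop = FALSE]
      for (j in seq_len(nrow(cds))) {
        inside <- any(contained_in(cds$start[j], cds$end[j], ex$start, ex$end))
        if (!inside) {
          stop_fmt("GFF3 CDS [%d,%d] of transcript %s not contained in any exon",
                   cds$start[j] + 1L, cds$end[j], tid)
        }
      }
      cds_iv <- data.frame(start = cds$start, end = cds$end)
    }
    tx_list[[k]] <- transcript_model(
      id = tid, gene_id = tx_parent[k] %||% NA_character_,
      chrom = tx_chrom[k], strand = tx_strand[k],
      exons = data.frame(start = ex$start, end = ex$end),
      cds = cds_iv)
  }
  build_annotation(tx_list)
}

#' Write novel exon candidates (and their ASVs) as GFF3
#'
#' One feature per novel exon, 1-based inclusive coordinates, with attributes
#' carrying the event type, region class, splice-site class, supporting EST
#' ids and host transcript. Rows are sorted by (chromosome, start, end, id)
#' so output is deterministic. Reading the file back with a GFF3 reader
#' round-trips the coordinates exactly.
#'
#' @param candidates List of accepted `NovelExonCandidate` objects.
#' @param asvs Optional list of `NovelASV` objects; written as `novel_ASV`
#'   features referencing their exons.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_novel_gff3 <- function(candidates, asvs = list(), path) {
  lines <- "##gff-version 3"
  if (length(candidates) > 0L) {
    candidates <- candidates[order_candidates(candidates)]
    feat <- vapply(candidates, function(cc) {
      ests <- paste(cc$supporting_ests$est, collapse = ",")
      attrs <- sprintf(
        "ID=%s;type=%s;region=%s;splice_class=%s;host_transcript=%s;supporting_ests=%s",
        cc$id, cc$type, cc$region, cc$splice_class %||% "none",
        cc$host_transcript, ests)
      paste(cc$chrom, "exonscout", "novel_exon",
            cc$start + 1L, cc$end, ".", cc$strand, ".", attrs, sep = "\t")
    }, character(1))
    lines <- c(lines, feat)
  }
  if (length(asvs) > 0L) {
    feat <- vapply(asvs, function(a) {
      attrs <- sprintf("ID=%s;host_transcript=%s;source_est=%s;species=%s;novel_exons=%s",
                       a$id, a$host_transcript, a$source_est, a$species,
                       paste(a$exon_ids, collapse = ","))
      paste(a$chrom, "exonscout", "novel_ASV",
            min(a$flank_segments$start) + 1L, max(a$flank_segments$end),
            ".", a$strand, ".", attrs, sep = "\t")
    }, character(1))
    lines <- c(lines, feat)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a GenomeAnnotation as GFF3
#'
#' Emits the gene/mRNA/exon/CDS hierarchy with `ID`/`Parent` attributes,
#' converting internal 0-based half-open coordinates back to GFF3's 1-based
#' inclusive convention. [read_gff3()] of the output reconstructs the
#' annotation exactly.
#'
#' @param annotation A `GenomeAnnotation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  lines <- "##gff-version 3"
  for (gene in sort(names(annotation$genes))) {
    tids <- sort(annotation$genes[[gene]])
    txs <- annotation$transcripts[tids]
    gs <- min(vapply(txs, function(tx) tx$exons$start[1], integer(1)))
    ge <- max(vapply(txs, function(tx) tx$exons$end[nrow(tx$exons)],
                     integer(1)))
    chrom <- txs[[1]]$chrom; strand <- txs[[1]]$strand
    lines <- c(lines, paste(chrom, "exonscout", "gene", gs + 1L, ge, ".",
                            strand, ".", sprintf("ID=%s", gene), sep = "\t"))
    for (tx in txs) {
      span <- c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])
      lines <- c(lines, paste(chrom, "exonscout", "mRNA", span[1] + 1L,
                              span[2], ".", strand, ".",
                              sprintf("ID=%s;Parent=%s", tx$id, gene),
                              sep = "\t"))
      for (i in seq_len(nrow(tx$exons))) {
        lines <- c(lines, paste(chrom, "exonscout", "exon",
                                tx$exons$start[i] + 1L, tx$exons$end[i], ".",
                                strand, ".",
                                sprintf("ID=%s.exon%d;Parent=%s", tx$id, i,
                                        tx$id), sep = "\t"))
      }
      if (tx$coding) {
        for (i in seq_len(nrow(tx$cds))) {
          lines <- c(lines, paste(chrom, "exonscout", "CDS",
                                  tx$cds$start[i] + 1L, tx$cds$end[i], ".",
                                  strand, "0",
                                  sprintf("ID=%s.cds%d;Parent=%s", tx$id, i,
                                          tx$id), sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a novel-exon GFF3 written by [write_novel_gff3()]
#'
#' Returns a data frame with internal 0-based half-open coordinates; used for
#' round-trip checks and for feeding the summary module from files.
#'
#' @param path Path to the GFF3 file.
#' @return A data.frame with columns chrom, start, end, strand, id, type,
#'   region, splice_class, host_transcript, supporting_ests.
#' @export
read_novel_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  rows <- rows[vapply(rows, function(f) length(f) == 9L && f[3] == "novel_exon",
                      logical(1))]
  get_attr <- function(attrs, nm) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", nm, "=([^;]*)"), attrs))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  do.call(rbind, c(list(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), id = character(0), type = character(0),
    region = character(0), splice_class = character(0),
    host_transcript = character(0), supporting_ests = character(0),
    stringsAsFactors = FALSE)),
    lapply(rows, function(f) {
      data.frame(
        chrom = f[1], start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
        strand = f[7],
        id = get_attr(f[9], "ID"), type = get_attr(f[9], "type"),
        region = get_attr(f[9], "region"),
        splice_class = get_attr(f[9], "splice_class"),
        host_transcript = get_attr(f[9], "host_transcript"),
        supporting_ests = get_attr(f[9], "supporting_ests"),
        stringsAsFactors = FALSE)
    })))
}
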