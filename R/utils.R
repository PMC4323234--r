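## Internal helpers shared across modules.
## Coordinate convention: 0-based half-open intervals on the forward genome
## strand everywhere inside the package; GFF3 (1-based inclusive) and PSL
## (0-based half-open) are converted only at the I/O boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a subsequence by 0-based half-open coordinates
#' @noRd
seq_sub <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

#' Reverse-complement a nucleotide string (A/C/G/T/N)
#' @noRd
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Overlap length of two 0-based half-open intervals
#' @noRd
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Does [s1,e1) overlap [s2,e2) by >= 1 bp? Vectorised.
#' @noRd
overlaps <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

#' Is [s1,e1) contained in [s2,e2)? Vectorised.
#' @noRd
contained_in <- function(s1, e1, s2, e2) {
  s2 <= s1 & e1 <= e2
}

#' Round half away from zero (arithmetic "half-up" for non-negative input)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Subtract a set of intervals from another (both data.frames start/end)
#' @noRd
interval_subtract <- function(segs, cut) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    pieces <- data.frame(start = segs$start[i], end = segs$end[i])
    for (j in seq_len(nrow(cut))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces$start[k]; e <- pieces$end[k]
        cs <- cut$start[j]; ce <- cut$end[j]
        if (!overlaps(s, e, cs, ce)) {
          nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = e)
        } else {
          if (s < cs) nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = cs)
          if (ce < e) nxt[[length(nxt) + 1L]] <- data.frame(start = ce, end = e)
        }
      }
      pieces <- if (length(nxt)) do.call(rbind, nxt) else
        data.frame(start = integer(0), end = integer(0))
    }
    out[[length(out) + 1L]] <- pieces
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Validate a nucleotide string against the A/C/G/T/N alphabet
#' @noRd
check_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop_fmt("%s contains characters outside A/C/G/T/N", what)
  }
  invisible(TRUE)
}

#' Deterministic candidate ordering: (chrom, start, end, type, transcript)
#' @noRd
order_candidates <- function(cands) {
  if (length(cands) == 0L) return(integer(0))
  key <- vapply(cands, function(cc) {
    sprintf("%s:%012d:%012d:%s:%s", cc$chrom, cc$start, cc$end, cc$type,
            cc$host_transcript)
  }, character(1))
  order(key, method = "radix")
}
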