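## Descriptive statistics of the discovered events: counts by event type and
## genomic region, EST support, length distributions and the pure-intron vs
## host-intron length tests.

#' Count unique novel exons and ASVs by type and region
#'
#' Unique exons are keyed by (chromosome, interval, type) — an exon reported
#' in several host transcripts counts once. An ASV is counted in every
#' (type, region) category its novel exons fall in (almost always one).
#'
#' @param candidates Accepted `NovelExonCandidate` objects.
#' @param asvs `NovelASV` objects from [assemble_asvs()].
#' @return List with `exons` and `asvs`, each a region x type integer matrix
#'   (rows FIVE_UTR/CDS/THREE_UTR/noncoding, columns cassette/
#'   retained_intron) with a `Total` row and column.
#' @export
count_by_type_region <- function(candidates, asvs = list()) {
  regions <- c("FIVE_UTR", "CDS", "THREE_UTR", "noncoding")
  types <- c("cassette", "retained_intron")
  base <- matrix(0L, nrow = length(regions), ncol = length(types),
                 dimnames = list(regions, types))
  ex_mat <- base
  if (length(candidates) > 0L) {
    key <- vapply(candidates, function(cc)
      paste(cc$chrom, cc$start, cc$end, cc$type), character(1))
    uniq <- candidates[!duplicated(key)]
    for (cc in uniq) ex_mat[cc$region, cc$type] <- ex_mat[cc$region, cc$type] + 1L
  }
  asv_mat <- base
  if (length(asvs) > 0L && length(candidates) > 0L) {
    cand_by_id <- candidates
    names(cand_by_id) <- vapply(candidates, `[[`, character(1), "id")
    for (a in asvs) {
      cats <- unique(t(vapply(cand_by_id[a$exon_ids], function(cc)
        c(cc$region, cc$type), character(2))))
      for (r in seq_len(nrow(cats))) {
        asv_mat[cats[r, 1], cats[r, 2]] <- asv_mat[cats[r, 1], cats[r, 2]] + 1L
      }
    }
  }
  add_margins <- function(m) {
    m <- cbind(m, Total = as.integer(rowSums(m)))
    rbind(m, Total = as.integer(colSums(m)))
  }
  list(exons = add_margins(ex_mat), asvs = add_margins(asv_mat))
}

#' EST-support summaries
#'
#' @param candidates Accepted `NovelExonCandidate` objects.
#' @param asvs `NovelASV` objects.
#' @return List with `mean_ests_per_type` (named numeric: mean number of
#'   supporting ESTs for cassette exons and retained introns, keyed on
#'   unique exons) and `multi_species_pct` (percentage of ASVs whose novel
#'   exons draw support from at least two subject species).
#' @export
est_support_stats <- function(candidates, asvs = list()) {
  types <- c("cassette", "retained_intron")
  means <- setNames(rep(NA_real_, 2), types)
  if (length(candidates) > 0L) {
    key <- vapply(candidates, function(cc)
      paste(cc$chrom, cc$start, cc$end, cc$type), character(1))
    uniq <- candidates[!duplicated(key)]
    for (ty in types) {
      n <- vapply(uniq, function(cc) {
        if (cc$type == ty) nrow(cc$supporting_ests) else NA_integer_
      }, integer(1))
      if (any(!is.na(n))) means[ty] <- mean(n, na.rm = TRUE)
    }
  }
  pct <- NA_real_
  if (length(asvs) > 0L && length(candidates) > 0L) {
    cand_by_id <- candidates
    names(cand_by_id) <- vapply(candidates, `[[`, character(1), "id")
    multi <- vapply(asvs, function(a) {
      sp <- unlist(lapply(cand_by_id[a$exon_ids], function(cc)
        cc$supporting_ests$species))
      length(unique(sp)) >= 2L
    }, logical(1))
    pct <- 100 * mean(multi)
  }
  list(mean_ests_per_type = means, multi_species_pct = pct)
}

#' Length statistics and tests: host introns vs pure introns
#'
#' Compares the lengths of the annotated introns that host novel cassette
#' exons with those of pure (constitutive) introns, using the Welch
#' two-sample two-tailed t-test on the means and the two-tailed Wilcoxon
#' rank-sum test on the distributions (exact for small untied samples,
#' normal approximation with tie/continuity correction otherwise).
#'
#' @param host_lengths,pure_lengths Numeric vectors of intron lengths
#'   (each of size >= 2).
#' @return List with `host_mean`, `host_median`, `pure_mean`, `pure_median`,
#'   `t_p` and `wilcoxon_p`. Degenerate all-identical input yields `t_p = NA`
#'   with a warning.
#' @export
intron_length_tests <- function(host_lengths, pure_lengths) {
  stopifnot(length(host_lengths) >= 2L, length(pure_lengths) >= 2L)
  t_p <- tryCatch(
    stats::t.test(host_lengths, pure_lengths)$p.value,
    error = function(e) {
      warning("t-test undefined for (near-)constant samples; reporting NA",
              call. = FALSE)
      NA_real_
    })
  w_p <- wilcoxon_ranksum(host_lengths, pure_lengths)
  list(host_mean = mean(host_lengths), host_median = stats::median(host_lengths),
       pure_mean = mean(pure_lengths), pure_median = stats::median(pure_lengths),
       t_p = t_p, wilcoxon_p = w_p)
}

#' Two-tailed Wilcoxon rank-sum p-value
#'
#' Exact when both samples have at most 25 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @return Two-tailed p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 25L && length(y) <= 25L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Build the full summary report
#'
#' @param candidates Accepted candidates from [run_discovery()].
#' @param asvs ASVs from [run_discovery()].
#' @param annotation A `GenomeAnnotation`.
#' @return List of class `SummaryReport` with `counts`, `est_support`,
#'   `length_stats` (mean/median per class) and `length_test`.
#' @export
summarize_discovery <- function(candidates, asvs, annotation) {
  counts <- count_by_type_region(candidates, asvs)
  support <- est_support_stats(candidates, asvs)

  is_cassette <- vapply(candidates, function(cc) cc$type == "cassette",
                        logical(1))
  cass <- candidates[is_cassette]
  ri <- candidates[!is_cassette]
  lens <- function(cs) vapply(cs, function(cc) cc$end - cc$start, integer(1))
  host_introns <- unique(do.call(rbind, lapply(cass, function(cc) {
    data.frame(chrom = cc$chrom, start = cc$host_intron[1],
               end = cc$host_intron[2], stringsAsFactors = FALSE)
  })))
  alt <- if (length(candidates) > 0L) {
    do.call(rbind, lapply(candidates, function(cc)
      data.frame(chrom = cc$chrom, start = cc$start, end = cc$end,
                 stringsAsFactors = FALSE)))
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  pure <- pure_introns(annotation, alt)

  stat_pair <- function(v) {
    if (length(v) == 0L) c(mean = NA_real_, median = NA_real_)
    else c(mean = mean(v), median = stats::median(v))
  }
  host_len <- if (is.null(host_introns)) integer(0)
              else host_introns$end - host_introns$start
  pure_len <- pure$end - pure$start
  length_stats <- rbind(
    cassette = stat_pair(lens(cass)),
    retained_intron = stat_pair(lens(ri)),
    host_intron = stat_pair(host_len),
    pure_intron = stat_pair(pure_len))
  length_test <- if (length(host_len) >= 2L && length(pure_len) >= 2L) {
    intron_length_tests(host_len, pure_len)
  } else NULL

  structure(list(counts = counts, est_support = support,
                 length_stats = length_stats, length_test = length_test),
            class = "SummaryReport")
}

#' Write a SummaryReport as a deterministic TSV
#'
#' @param report A `SummaryReport`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(report, path) {
  lines <- c("section\tkey\tvalue")
  emit <- function(section, key, value) {
    lines <<- c(lines, sprintf("%s\t%s\t%s", section, key,
                               format(value, digits = 10)))
  }
  for (what in c("exons", "asvs")) {
    m <- report$counts[[what]]
    for (r in rownames(m)) for (cl in colnames(m)) {
      emit(paste0("counts_", what), paste(r, cl, sep = "."), m[r, cl])
    }
  }
  for (ty in names(report$est_support$mean_ests_per_type)) {
    emit("est_support", paste0("mean_ests.", ty),
         report$est_support$mean_ests_per_type[[ty]])
  }
  emit("est_support", "multi_species_pct", report$est_support$multi_species_pct)
  for (r in rownames(report$length_stats)) {
    emit("length", paste0(r, ".mean"), report$length_stats[r, "mean"])
    emit("length", paste0(r, ".median"), report$length_stats[r, "median"])
  }
  if (!is.null(report$length_test)) {
    emit("length_test", "t_p", report$length_test$t_p)
    emit("length_test", "wilcoxon_p", report$length_test$wilcoxon_p)
  }
  writeLines(lines, path)
  invisible(path)
}
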