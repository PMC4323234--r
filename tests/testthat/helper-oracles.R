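# Independent oracles used to cross-check the package implementations.
# These deliberately use their own algorithms (vectorised mutant scans,
# recursive pathway enumeration, log-binomial hypergeometric probabilities,
# explicit permutation counting) rather than calling package internals.

GC_TABLE <- Biostrings::GENETIC_CODE

# NG86 site counts of one codon: scan all 9 single-nucleotide mutants.
oracle_codon_sites <- function(codon) {
  if (GC_TABLE[[codon]] == "*") return(c(N = NA_real_, S = NA_real_))
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), chars[pos]), function(b) {
      m <- chars; m[pos] <- b; paste(m, collapse = "")
    }, character(1))
    aas <- GC_TABLE[muts]
    syn <- syn + sum(aas != "*" & aas == GC_TABLE[[codon]]) / 3
  }
  c(N = 3 - syn, S = syn)
}

# NG86 pathway-averaged differences between two codons: recursive DFS over
# orderings of the differing positions.
oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(Nd = 0, Sd = 0))
  paths <- list()
  recurse <- function(cur, remaining, nd, sd, blocked) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(nd, sd, blocked)
      return(invisible())
    }
    for (k in remaining) {
      nxt <- cur
      substr(nxt, k, k) <- substr(c2, k, k)
      step_stop <- GC_TABLE[[cur]] == "*" || GC_TABLE[[nxt]] == "*"
      syn <- !step_stop && GC_TABLE[[cur]] == GC_TABLE[[nxt]]
      recurse(nxt, setdiff(remaining, k),
              nd + ifelse(syn, 0, 1), sd + ifelse(syn, 1, 0),
              blocked || step_stop)
    }
  }
  recurse(c1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(Nd = mean(m[ok, 1]), Sd = mean(m[ok, 2]))
}

# Two-sided exact hypergeometric p for a 2x2 table via log-binomials.
oracle_fisher_2x2 <- function(a, b, c2, d2) {
  m <- a + b; n <- c2 + d2; k <- a + c2
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p via full enumeration of group
# assignments (Mann-Whitney U, R's two-sided doubling rule).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  if (u_obs > n1 * n2 / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Small handcrafted coding transcript on an all-controllable chromosome.
# Layout: exon1 = [100,160) all CDS starting ATG, intron = [160,460),
# exon2 = [460,520) all CDS ending TAA; background "C" everywhere else.
toy_coding_locus <- function(intron_filler = NULL) {
  set.seed(404)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  cds <- paste0("ATG", paste(sample(sense, 38, replace = TRUE), collapse = ""),
                "TAA")  # 120 bases
  intron <- if (is.null(intron_filler)) {
    paste0("GT", strrep("C", 296), "AG")
  } else intron_filler
  chrom <- paste0(strrep("C", 100), substr(cds, 1, 60), intron,
                  substr(cds, 61, 120), strrep("C", 100))
  genome <- structure(c(chr1 = chrom), class = "SequenceSet")
  tx <- transcript_model("txA", "geneA", "chr1", "+",
                         exons = data.frame(start = c(100L, 460L),
                                            end = c(160L, 520L)),
                         cds = data.frame(start = c(100L, 460L),
                                          end = c(160L, 520L)))
  list(genome = genome, tx = tx,
       annotation = build_annotation(list(tx)))
}

# Standard event mix used by the recovery tests: one of each violation mode.
mixed_event_list <- function() {
  list(
    event_spec("cassette", "CDS", "VALID", n_supporting_ests = 2,
               species = c("wheat", "barley")),
    event_spec("cassette", "FIVE_UTR", "VALID"),
    event_spec("cassette", "THREE_UTR", "VALID", shifts = c(3L, -2L)),
    event_spec("retained_intron", "CDS", "VALID"),
    event_spec("retained_intron", "FIVE_UTR", "VALID"),
    event_spec("cassette", "CDS", "VIOLATES_LENGTH"),
    event_spec("cassette", "CDS", "VIOLATES_FLANK_OVERLAP"),
    event_spec("cassette", "CDS", "VIOLATES_SPLICE"),
    event_spec("cassette", "CDS", "VIOLATES_FRAME"),
    event_spec("cassette", "CDS", "VIOLATES_STOP"),
    event_spec("cassette", "CDS", "VIOLATES_NOVELTY"),
    event_spec("retained_intron", "THREE_UTR", "VIOLATES_FLANK_OVERLAP"))
}

# Flatten a fixture's subject PSL lists into (records by qName, species map).
est_index <- function(fx) {
  ests <- list(); species <- character(0)
  for (sp in names(fx$subject_psl)) {
    for (r in fx$subject_psl[[sp]]) {
      ests[[r$qName]] <- r
      species[r$qName] <- sp
    }
  }
  list(ests = ests, species = species)
}

# Match accepted candidates against a fixture truth table; returns list with
# sensitivity and flag precision.
score_against_truth <- function(res, truth) {
  acc_key <- vapply(res$candidates, function(cc)
    paste(cc$chrom, cc$start, cc$end, cc$type), character(1))
  valid <- truth[truth$validity == "VALID", , drop = FALSE]
  truth_key <- paste(valid$chrom, valid$start, valid$end, valid$type)
  sensitivity <- mean(truth_key %in% acc_key)

  bad <- truth[truth$validity != "VALID", , drop = FALSE]
  rej_by_key <- res$rejected
  names(rej_by_key) <- vapply(res$rejected, function(cc)
    paste(cc$chrom, cc$type), character(1))
  ok <- vapply(seq_len(nrow(bad)), function(i) {
    hits <- Filter(function(cc) {
      cc$chrom == bad$chrom[i] && cc$type == bad$type[i] &&
        cc$host_intron[1] <= bad$start[i] && bad$end[i] <= cc$host_intron[2]
    }, res$rejected)
    if (length(hits) != 1L) return(FALSE)
    ff <- hits[[1]]$filter_flags
    failed <- names(ff)[!is.na(ff) & !ff]
    identical(failed, bad$expected_flag[i])
  }, logical(1))
  list(sensitivity = sensitivity, flag_precision = mean(ok),
       n_accepted = length(res$candidates))
}
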