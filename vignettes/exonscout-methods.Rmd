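---
title: "Methods: novel exon discovery and evolutionary-rate contrasts"
author: "exonscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novel exon discovery and evolutionary-rate contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonscout)
```

## The problem and the model

Gene annotations built largely from computational prediction both miss real
exons and assert isoforms that no transcript has ever evidenced. When the
species of interest has a shallow EST/cDNA library, its own transcripts
cannot fill the gap — but the libraries of *related* species can: expressed
sequence that aligns, spliced, inside an annotated intron of the target
genome and is bounded by the annotated exons is strong evidence for an
unannotated exon conserved across the species pair.

`exonscout` consumes spliced EST-to-genome alignments (PSL, the BLAT output
format; computing the alignments is out of scope) and recognises two event
shapes inside annotated introns:

* **cassette exon** — an internal aligned block strictly inside one intron
  of a host transcript, whose neighbouring blocks align to exons of the
  same transcript;
* **retained intron** — one contiguous block covering an entire intron and
  reaching into both flanking exons.

Internally every feature lives on a single coordinate convention — 0-based,
half-open, forward genome strand. GFF3 (1-based inclusive) and PSL (0-based
half-open) are converted only at the I/O boundary; this is the cheapest way
to make off-by-one errors structurally impossible, and the round-trip tests
hold the converters to exactness.

## Filtering criteria and their tunables

Candidates pass four filters, each exposed in `discovery_config()` and each
recorded per candidate as an independent flag (no short-circuiting), so an
attrition report is exact and a rejected candidate names the criterion that
killed it.

| parameter | default | meaning |
|---|---|---|
| `min_exon_len` | 50 bp | cassette exon must be *strictly longer* (an exclusive bound) |
| `min_flank_overlap` | 50 bp | each flanking EST segment must overlap an annotated exon of the host transcript by at least this much (inclusive) |
| `splice_window` | ±10 bp | boundary shift searched per side, independently |
| `canonical_sites` | GT-AG, GC-AG, AT-AC | searched first, in order |
| `noncanonical_sites` | AT-AA, AT-AG, AT-AT, GT-AT, GT-GG | searched only when no canonical pair exists in the window |
| `allow_noncanonical` | `TRUE` | non-canonical events are kept but marked, so downstream analyses can restrict to canonical ones |

Decisions made where the design was genuinely open:

* **Window semantics.** "A 10-bp window" could mean ±10 per boundary or 10
  in total; we adopt ±10 per boundary, shifted independently, both
  configurable. Within a boundary the smallest absolute shift wins and ties
  go to the lower-coordinate (negative) shift — the minimal-edit choice,
  and a deterministic one.
* **Order of operations.** Splice-site refinement runs before the frame
  check, and the length criterion is *re-evaluated on the refined
  interval*: shifting may move a candidate across the minimum-length bound
  in either direction, and length is that criterion's job. This also keeps
  the flags orthogonal — a 48-bp candidate with perfect planted splice
  sites fails length and nothing else.
* **Flank overlap target.** The flanking EST segments are required to
  overlap annotated *exons* of the host transcript (maximum single-exon
  overlap), the stricter of the readings and the one matching the event
  schematics.
* **Frame check scope.** The reading-frame criterion re-translates the
  whole reconstructed CDS (annotated CDS with the candidate spliced in at
  its genomic position, strand-aware) rather than the insert alone, so a
  stop codon spanning a new junction is caught. The premature-stop flag is
  only evaluated when the mod-3 check passes: a frameshifted translation
  would almost always contain spurious downstream stops and would
  double-flag candidates whose only defect is length mod 3.
* **Region tie-break.** A candidate straddling the CDS/UTR boundary is
  classified CDS, so the stricter filter applies. Candidates in non-coding
  host transcripts are classified `noncoding` and skip the frame criterion.
* **Best hit.** BLAT's "best" is unspecified; we use max(matches −
  misMatches) with a deterministic (tName, tStart) tie-break.
* **Novelty.** Overlap with target-species evidence is disqualifying at
  ≥ 1 bp, the literal reading of "should not overlap"; both partitions are
  returned so same-species-supported events can be retained on request.
* **Multi-transcript introns.** Each (interval, transcript) pair is
  evaluated independently and reported once per passing host transcript;
  the unique-exon count deduplicates on (chromosome, interval, type).

## Evolutionary-rate contrast

For a CDS novel exon, the two flanking exons' CDS portions are concatenated
in transcript order — in the annotated isoform they are adjacent in the
CDS, so the concatenation is frame-continuous, with the frame offset taken
from the annotation. The novel exon and the concatenation are each aligned
codon-by-codon to the best supporting subject EST (most aligned bases over
the regions; ties by matches, then id), with columns containing a gap,
an `N`, or a stop codon dropped.

Rates use **Nei–Gojobori (1986) counting**: each codon position contributes
the fraction of its three single-nucleotide changes that are synonymous to
*S* (mutations to stops count as nonsynonymous), so *N* + *S* = 3·L
exactly; differences are partitioned by averaging over all shortest
mutational pathways with equal weights, excluding pathways through stop
codons (if every pathway is blocked, all are used with stop-involving steps
counted nonsynonymous). Proportions *p* = d/sites are corrected with the
Jukes–Cantor formula *d* = −¾ ln(1 − 4*p*/3); *p* ≥ ¾ is reported as
saturated (`NA`). NG86-with-JC was chosen over a maximum-likelihood codon
model deliberately: it is fully specified by closed formulas, desk-
verifiable by enumeration (the test suite checks all 61×61 sense-codon
pairs against an independent pathway-enumeration oracle), and supplies
exactly the integer-like counts the exact tests below consume. The cost is
known: no transition/transversion or codon-frequency weighting, so
absolute rates are biased relative to ML estimators, though the
novel-versus-flank *contrast* — the quantity of interest — is computed
identically for both exon sets.

Significance of the *dn* difference uses a 2×2 table — rows (novel exon,
concatenated flanks), columns (changed, unchanged nonsynonymous sites) —
tested with a two-tailed exact hypergeometric test; analogously for *ds*,
and a neutrality test on [[Nd, N−Nd], [Sd, S−Sd]]. Fractional NG86 counts
are rounded half-up by default (`half_even` available); the exact test sums
hypergeometric probabilities ≤ the observed one with the conventional 1e−7
relative tie tolerance. No multiple-testing correction is applied by
default (raw *p* < 0.05 is the conventional read-out here); p-values are
returned so the caller can apply `p.adjust` if desired.

## The synthetic-data generator

`generate_fixture()` is first-class, tested code: it emits a multi-gene
genome (FASTA), an Ensembl-style annotation (GFF3), subject-species EST
sequences with *exact* PSL alignments derived from construction (no aligner
in the loop, isolating discovery logic from aligner behaviour), optional
target-species ESTs, and a truth table. Its defaults define the study
conditions the validation reproduces:

* five-exon genes (UTR exon | UTR+CDS | CDS | CDS+UTR | UTR exon) on
  alternating strands, CDS segment lengths multiples of 3 so planted CDS
  events sit at codon phase 0 and frame/stop properties are exact by
  construction; UTR exons 120–200 bp, ordinary introns 250–400 bp, GC
  fraction 0.44 — unremarkable values for a compact plant genome;
* valid cassette exons default to 72–108 bp (multiples of 3), matching the
  ~100 bp scale typical of conserved cassette exons; cassette-hosting
  introns are generated long relative to ordinary introns (the tendency
  real surveys report), which the pure-intron length comparison measures;
* each violation mode breaks exactly one criterion: length violators use
  48 bp (≤ 50 *and* a multiple of 3, so frame still passes), splice
  violators have their boundary windows scrubbed of every allowed
  dinucleotide pair, frame violators insert length ≢ 0 (mod 3) built from
  C/T-only codons (which can never form a stop in any frame), stop
  violators plant one in-frame TAA, novelty violators receive a
  target-species EST block over the candidate;
* planted substitution divergence (`divergence` in `event_spec()`) mutates
  the subject EST copy with per-site synonymous/nonsynonymous rates, at
  most one substitution per codon, so realized counts are unambiguous and
  `count_differences` must recover them exactly.

What the generator does **not** emulate: sequencing error and EST
truncation, paralogous mis-alignment, alternative donor/acceptor shifts,
terminal exons, real codon usage and intron composition, or aligner
artefacts. Passing the planted-event tests therefore demonstrates that the
*logic* is sound under clean evidence, not that real-data precision would
be 100%; on real alignments the filters are exactly the guards against
those artefacts.

## Numerical and procedural choices

* All outputs are deterministically ordered (candidates by chromosome,
  start, end, type, transcript); reruns are byte-identical.
* The exact hypergeometric test is validated against a log-binomial
  enumeration oracle for every 2×2 table with grand total ≤ 60 (tolerance
  1e−12) and against `stats::fisher.test` spot checks.
* The Wilcoxon rank-sum test (host-intron vs pure-intron lengths) is exact
  for untied samples of ≤ 25 per group, otherwise the normal approximation
  with tie/continuity correction; the exact branch is validated against
  full permutation enumeration for all n₁+n₂ ≤ 12. The mean comparison
  uses Welch's t-test; identical-constant samples yield `NA` with a
  warning rather than a fabricated p-value.
* Validation problem sizes: the standard recovery fixture uses 50 genes
  with 44 planted events; parameter recovery uses 200 replicates of
  500-codon sequences at synonymous/nonsynonymous rates 0.05/0.01; the
  direction property (Δ*dn* > 0, Δ*ds* < 0, novel mutated 0.02/0.03 and
  flanks 0.06/0.005) is evaluated per replicate as the *mean* contrast over
  one 8-event fixture — the mean-difference form in which that property is
  stated — across 40 seeded fixtures.

## Known limitations

* Only internal exons are discoverable; events at transcript termini and
  alternative donor/acceptor usage are out of scope by design.
* Non-coding RNA exons that fail the frame criterion are rejected even
  though some may be real; the per-criterion flags make them easy to
  recover from the rejected set if wanted.
* Rate contrasts need a subject EST covering both the novel exon and its
  flanks with enough gapless codons; sparse coverage yields saturated or
  undefined estimates, which are flagged rather than guessed.
* NG86/JC absolute rates are biased for biased codon usage or high
  transition/transversion ratios (see above); interpret *contrasts*, not
  absolute values.
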