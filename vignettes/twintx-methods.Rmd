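---
title: "Comparing twin de novo transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing twin de novo transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twintx)
```

## The problem

When two closely related species are sequenced and assembled *de novo*
(classically from 454 pyrosequencing of normalized cDNA libraries), the
natural questions are: how complete are the two assemblies, how divergent
are the orthologous transcripts, which transcripts are private to one
species, and do the private sets carry a distinctive functional signature?
`twintx` implements that comparison as a pipeline of small, testable
stages: read cleaning, homopolymer QC, local-alignment search, best-hit
filtering, Ortholog-Hit-Ratio (OHR) completeness, CDS completeness
classes, reciprocal-best-hit (RBH) ortholog calling with identity
statistics, species-specific (PDEG) set extraction and Fisher-exact GO
enrichment.

Because the real datasets behind such studies (hundreds of thousands of
reads, external databases) are not suitable for routine testing, the
package ships a first-class simulator that generates *twin* transcript
sets from common ancestors with controlled divergence, planted
species-specific transcripts, planted coverage fractions, and raw reads
with the full adapter/barcode library structure. Every analysis stage is
validated against that planted truth.

## The simulator: what it emulates, and what it does not

`generate_twin_transcriptomes()` draws random ancestor sequences
(uniform base composition) and derives one descendant copy per species.

* **Divergence model.** `divergence` (default 0.02) is the *expected
  pairwise per-site substitution divergence* between the two copies. Each
  copy is mutated independently at the per-copy rate `h` solving
  `(1 - h)^2 + h^2/3 = 1 - d`, i.e. `h = (3 - sqrt(9 - 12 d)) / 4`; the
  quadratic term accounts for coincident mutations to the same base, so
  the expected pairwise identity is exactly `1 - d`. Substitutions pick
  uniformly among the three alternative bases; indels are single-base,
  insertion and deletion equally likely, at per-copy rate
  `indel_rate / 2`. The paper-scale default `d = 0.02` emulates a sibling
  species pair with ~98% mean transcript identity. The simplest symmetric
  model is used deliberately: no transition/transversion bias, no rate
  heterogeneity, no codon structure.
* **Realized identity.** The truth table records, per ortholog pair, the
  identity of one optimal *global* alignment computed at generation time
  (matches over alignment columns). With indels, alternative optima can
  differ slightly; downstream checks therefore allow 0.5 percentage
  points of slack between planted and re-measured identity.
* **Fragmentation.** Each descendant is truncated to a coverage fraction
  drawn from `fragment_fractions`, from a uniformly chosen end (5' or 3',
  creating both N- and C-terminal incompleteness). The *realized*
  fraction `round(f * L) / L` is recorded, so OHR can be checked for
  exact equality at zero divergence.
* **Reads.** `generate_reads()` emits
  `adapter A + 6 bp barcode + inner 5' adapter + insert + inner 3'
  adapter + adapter B`, using the 454 adapter sequences and the two
  species barcodes (`ATCAGC`, `CACACG`) of the library design it
  emulates. With probability `homopolymer_error_rate` one existing run
  (>= 2 bp) inside the insert is lengthened by 1-3 bp — the dominant 454
  error mode. Not emulated: flowgram noise, quality values, expression
  levels (the emulated libraries were normalized), chimeras.

Consequently, passing tests demonstrate correctness of the *analysis*
under a clean generative model; they do not certify behaviour on real 454
data with correlated errors, uneven coverage or assembly artifacts.

## Read cleaning

`demultiplex_and_trim()` anchors adapter A at position 0 with at most
`max_adapter_mismatches` (default 2) mismatches, reads the following 6 bp
barcode, and strips the inner 5' adapter, then adapter B and the inner 3'
adapter from the 3' end (anchored suffix match within the same budget, or
an exact partial overlap of >= 8 bp for adapters running off the read).
Unrecognized structure goes to an `unassigned` bin; every read ends in
exactly one bin, and the report counts are conserved by construction.
`filter_reads()` removes reads shorter than `min_length` (default 100 bp,
matching the usual minimum contig length for 454 assemblies) and reads
with more than `max_n_fraction` (default 2%) undetermined bases — both
thresholds are conventions, stated here because the upstream tools this
stage emulates do not document theirs. The rRNA screen removes reads with
a local alignment of >= 90% identity over >= 100 bp to a user-supplied
reference; these defaults are likewise declared, not inherited.

## Homopolymer QC

`longest_runs()` reports, per base, the longest maximal run (1 =
isolated, 0 = absent; N breaks runs because an undetermined base cannot
certify identity of its neighbours). `homopolymer_profile()` histograms
only runs >= 2 bp — a homopolymer proper — and averages over the
sequences that contribute such a run; averaging over all sequences
instead would shift means down by a few hundredths and is not what the
run-length figures this stage reproduces show.

## The alignment engine

The search is nucleotide-only, local, affine-gap (+1/-2, open -5, extend
-2; a gap of length L costs 5 + 2L). The dynamic programming core is
delegated to `Biostrings::pairwiseAlignment()`; the package adds k-mer
seeding, strand handling, hit construction and statistics. Candidate
pairs must share at least `min_seed_hits = 2` distinct 11-mers on a
strand; each candidate pair yields at most one hit (the single
best-scoring local alignment — no HSP tiling, matching the best-hit-only
downstream analysis). Tests quantify seeding recall at >= 99% for
divergence <= 0.05.

Bit scores use the Karlin-Altschul form `(lambda S - ln k)/ln 2` with
`lambda` solved exactly from the ungapped score equation under uniform
composition (1.3327 for the default scores) and `k = 0.35`, a constant
fixed once for the default scheme; with these gap penalties the gapped
correction is small, and only the *threshold* behaviour of e-values
(1e-5 for annotation, 1e-10 for RBH) matters downstream. E-values are
`q_len * db_residues * 2^-bit`, computed in log space.

## Best-hit filtering, OHR and CDS classes

Hits are ranked into four categories by query overlap
(`100 * aln_length / q_len`, >= 70%) and identity (>= 50%); per query only
the best category present is retained. The overlap denominator is the
query (transcript) length — a declared choice; the filtering is
transcript-centric.

The OHR of a transcript is the *ungapped* alignment length divided by the
full length of the hit sequence, keeping the best value over its hits; 1.0
means the transcript covers the entire reference. All gap columns are
subtracted (both sequences); for imported 12-column hits the exact gap
column count is unknown and `gap_opens` is used as the estimate
(single-base gaps assumed) — exact for the internal engine's own hits,
logged as an approximation for imports.

`classify_cds()` is a deliberately simple longest-ORF classifier, a
stand-in for trained CDS predictors: stop-to-stop segments in all six
frames, entered at the first ATG where present; candidates without an ATG
are admitted only when their segment runs off the 5' end (a truncation
explains the missing start). Classes: `complete`, `n_fragment` (amino
end truncated), `c_fragment` (carboxyl end truncated), `both_fragment`,
`none`; the five classes partition any input set. `min_orf_bp = 300`
(100 codons) is a convention. Ties in length prefer the more complete
class, then frame order, making the classification invariant under
reverse complement. N-terminal is taken to mean the amino end, i.e. the
5' side of the sense frame.

The matching truth generator, `generate_cds_transcripts()`, plants each
class by construction (an in-frame stop directly upstream of the ATG for
`complete`, truncations for the fragment classes) using sense codons
that are neither stop nor ATG, and resamples a transcript until its
planted open segment is strictly longer than the longest stop-free
segment of every other reading frame — a structural check on stop
positions only, independent of the classifier. Without that guarantee a
random filler occasionally presents a longer open segment in another
frame, which a longest-ORF rule must, by definition, prefer.

## RBH, divergence and PDEG sets

Reciprocal best hits use e-value <= 1e-10 and alignment overlap >= 90%,
enforced on the query side in each direction, so both partners end up
covered — the conservative reading of an "overlap" threshold with no
stated denominator. Ties at equal bit score break by higher identity,
then subject id, for determinism. The pair's identity is reported from
the a-to-b direction; the b-to-a value is compared and a warning raised
if they disagree by more than one point. The divergence report summarizes
identities and lists pairs below 97% for downstream annotation.

PDEGs — transcripts with no qualifying hit in the sibling set — use the
annotation threshold 1e-5 rather than the stringent RBH threshold:
specificity is a statement about the general search, not the conservative
ortholog pass. With nested thresholds the PDEG and RBH sets are provably
disjoint.

## GO enrichment

Each term annotated in the reference set is tested with a two-sided
Fisher exact test on the 2x2 table (test set vs reference *minus* test
set — disjoint columns, so the independence assumption holds), p-values
corrected by Benjamini-Hochberg (Bonferroni available). The odds ratio
reported is the sample `ad/bc`. No GO-graph propagation is performed;
terms are tested as annotated, which is a declared limitation. Under the
simulator's null the raw rejection rate at 0.05 sits near 0.04 —
hypergeometric discreteness makes the test conservative — and a term
planted at 50x odds in one species' specific transcripts is recovered as
the top-ranked significant term.

## Numerical and scale choices

Test and acceptance runs use problem sizes chosen to exercise each
property at meaningful power on a single CPU: 200 ortholog pairs
(~130,000 aligned sites, so the binomial 99% interval on mean identity is
about +/- 0.1 point) for parameter recovery; 40 transcripts across four
coverage fractions for OHR; 20 simulation seeds x 50 terms for enrichment
calibration; 500 random pairs (<= 60 bp) against a full-matrix affine DP
oracle and 1,000 random instances per closed-form oracle
(homopolymers, N50, category filtering, Fisher p-values). Degenerate
inputs are defined, not special-cased: empty hit lists yield a
"no hit" record, empty sets error, zero-mutation simulations give exact
recovery, and all tie-breaks are documented lexicographic/score orders so
identical configuration and seed reproduce artifacts byte for byte.

## Known limitations

* The aligner is heuristic (seeded): hits without two shared 11-mers are
  missed; at the divergences this package targets (<= 5%) the measured
  recall is >= 99%, but deeply diverged homologs require an external
  aligner, whose tabular output can be imported instead.
* E-value constants are calibrated for the default scoring only; custom
  schemes change thresholds in ways the package does not re-estimate.
* The ORF classifier knows nothing about codon usage; very short or
  GC-extreme transcripts can present a longer spurious open segment in a
  non-coding frame than the true CDS remnant.
* The simulator's uniform-composition, i.i.d.-site model understates the
  difficulty of real data (repeats, low-complexity regions, chimeric
  assemblies).
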