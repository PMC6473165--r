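---
title: "Methods: annotation, typing, phylogenetics and prevalence analysis of avian papillomaviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, typing, phylogenetics and prevalence analysis of avian papillomaviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avianpv)
```

# Scope

`avianpv` implements the computational workflow used to characterize novel
avian papillomaviruses (APVs) from wild-bird surveillance: annotating
circular genomes with the avian gene layout, cataloguing the degenerate
sequence motifs that diagnose papillomavirus proteins and control regions,
assigning taxonomy ranks from L1 nucleotide identity, building distance
phylogenies with clade queries, and testing prevalence differences with
binomial GLMs.  A synthetic-data module generates all three kinds of input
(genomes, alignments, cohorts) with known ground truth, and is the substrate
for most of the test suite.

# Genome model and annotation

Papillomavirus genomes are circular dsDNA of roughly 5.7–8.6 kb; the avian
viruses handled here run 7.3–8.1 kb and carry all ORFs on one strand in the
order E6–E7–E1(E9 nested)–E2–NCR–L2–L1–LCR.  Coordinates are 1-based and
inclusive (the GenBank convention used in the source data's primer tables);
intervals may wrap the origin, and every circular-coordinate operation is
defined as the corresponding linear operation on the doubled sequence
restricted to spans shorter than the genome — a property the tests exercise
directly.

ORF discovery scans the forward strand only (the reverse strand of an APV
contains no annotated genes, so the annotator never consults it; genome
orientation is the caller's responsibility).  For each stop codon the
maximal start-to-stop frame is kept.  Gene names are assigned positionally,
without homology search:

* **E1** is the longest core ORF (core threshold 300 aa);
* **E2** is the next core ORF downstream, **L2** the next after that;
* **L1** is chosen among the remaining candidates by the overlap rule: its
  start codon must share at least one nucleotide with the L2 stop codon and
  lie within 10 nt downstream of a splice-acceptor candidate.  ATG starts
  are preferred; a GTG start is admitted only when no overlapping ATG
  exists, mirroring the puffin virus, where all sequenced strains show a
  GTG at the expected L1 start.  If nothing overlaps, the longest
  downstream candidate is taken and flagged.
* **E6/E7** are the accessory ORFs (threshold 60 aa, low enough for the
  81–99 aa avian E6) between the L1 stop and the E1 start, in genome order;
  a single candidate is taken as E7, matching the one known APV that lacks
  E6.
* **E9**, the avian-specific protein, is an accessory ORF nested inside E1
  in a different reading frame.

The LCR is the gap between L1 and the first early ORF; the NCR is the gap
between E2 and L2 when it is at least 2 nt (the described range is
2–50 nt; longer gaps are reported but flagged atypical).  The splice
acceptor stand-in scores every AG dinucleotide by the pyrimidine fraction
of the 12 nt upstream — a deliberately simple heuristic standing where a
neural-network predictor was used in the original analysis; only the
relative placement of acceptors matters to the L1 rule, not calibrated
scores.

Annotations are reported in the input genome's own coordinate frame, with
the rotation offset to the canonical E6-first frame recorded in the
annotation (`rotation_to_canonical`); `rotate_genome()` applies it.
Keeping the input frame makes every reported coordinate directly checkable
against the submitted sequence, which we judged more useful than silently
renumbering; the canonical presentation is one call away.

# Motif catalogue

Fifteen degenerate consensi are built in: the typical (`ACCNNNNNNGGT`) and
atypical (`ACCNNNNGGT`) E2-binding sites, the TATA box (`TATAWAW`), the
late polyadenylation signal (`AATAAA`/`ATTAAA`), the E6/E7 zinc domain (two
`CXXC` pairs separated by 39–42 residues), the pRb-binding `LXCXE`, the
Walker A/B/C helicase motifs and the avian-conserved Walker A form, the E2
DNA-binding domain, and the L2 furin, transmembrane `GXXXG`, SNX17- and
syntaxin-18-binding motifs.  Patterns compile to ordered position classes
with optional variable spacers; scanning reports every match, including
overlapping ones and, on circular sequences, origin-spanning ones, with one
row per distinct (start, spacer length).  The hydrophobic class Φ is not
defined in the source material; we fixed it to the Kyte–Doolittle-positive
set `{A,V,L,I,M,F,W,Y,C}` and made it overridable.  An `N` in a scanned
sequence matches nothing, so ambiguity never creates hits.  E2-binding
sites are counted by distinct start within the LCR (the typical and
atypical patterns cannot claim the same start because their spacers
differ); a genome-wide count is available behind a switch because the
described copy numbers do not state the restriction explicitly.

# Typing and demarcation

Pairwise identity is `100 × (1 − p)` with the p-distance computed over
comparable columns only (pairwise deletion of gap/ambiguous columns, the
default of the software used for the original identity tables).  Group
means follow the "inverse of the mean p-distance between groups"
convention.  The demarcation cascade uses strict thresholds — same subtype
above 99%, type above 90%, species above 70%, genus above 60% — because the
classification rules are phrased as ">99%"/">90%"; at exactly 90 a pair is
therefore same-species, not same-type.  Clustering is single linkage
applied level by level within the parent cluster (a sequence joins a type
if it is close enough to *any* member, the natural reading of the pairwise
rule; complete linkage is available by flag), implemented as connected
components so the strict boundary is exact.  Cluster labels are numbered by
first member in input order, making output deterministic and
order-invariant.

Synonymous/non-synonymous classification compares codon pairs after
pairwise gap deletion: a substitution is synonymous iff its codon pair
translates identically; when a codon is hit more than once and the
translations differ, all its substitutions count as non-synonymous.  This
codon-level attribution matches the whole-ORF tallies reported for the duck
and gull virus subtype pairs.  Gaps are assumed codon-aligned; the bundled
global aligner (match +1, mismatch −1, gap −2, via Biostrings) is a
convenience for self-contained examples, not a Clustal replacement.

# Distance phylogenetics

The original trees were maximum-likelihood trees; this package deliberately
replaces ML with neighbor joining over the same named distance models,
because every conclusion drawn from those trees is a clade-composition
statement (monophyly of host-family and host-order virus groups), not a
branch-length comparison.  K2P and TN93 distances follow their standard
closed forms; the gamma correction replaces each logarithmic term `−log w`
by `a (w^{−1/a} − 1)` (the convention of the software the study used, which
our implementation matches to 10 decimal places in cross-checks against
`ape::dist.dna`), and an invariant-site fraction, supplied externally
rather than estimated, rescales mismatch proportions by `1/(1 − p_inv)`
and the distance by `(1 − p_inv)`.  Saturated comparisons return `Inf`
with a warning, never a silent `NaN`.

NJ ties in the Q criterion are broken by the smallest index pair, and
negative branch estimates are clamped to zero with the deficit moved to the
adjacent branch, so output is deterministic and non-negative.  Bootstrap
resampling draws all column indices from one seeded generator in replicate
order; support is the percentage of replicate trees containing each
bipartition of the point tree.  Monophyly of a leaf set means some edge of
the unrooted tree induces exactly that bipartition.

# Prevalence and GLM tests

Prevalence is the percentage of virus-positive *individuals* (repeated
samples of one bird collapse to one row, positive if any sample was
positive), printed half-up to one decimal — 13/16 is 81.3%, which R's
default round-half-even would print as 81.2.  The Wilson 95% interval is
reported because it behaves at the boundaries (`k = 0` gives a lower bound
of exactly 0); the original tables print no interval, so this is additive
output.  Group comparisons use a logit-link binomial GLM with one
categorical predictor; the test statistic is the deviance drop
(likelihood-ratio χ²), which algebraically equals the G statistic
`2 Σ o log(o/e)` on the level-by-status table.  Recomputing the published
statistics from the printed counts reproduces 24.2, 9.79 and 1.43 exactly,
which identifies the deviance test (rather than Pearson's χ²) as the method
used.  Two published statistics cannot be reconstructed from any count table
consistent with the totals (the duck age χ² = 15.41 and the duck species
χ² = 1.70); unknown-age/unlabelled individuals were likely excluded at
source, and these comparisons are not asserted anywhere.  The seasonality
test is implemented unadjusted: although described as accounting for age,
the printed value equals the unadjusted 2×2 statistic.

# Synthetic data: what it emulates and what it does not

`generate_genome()` assembles the full avian layout with planted ground
truth: protein motifs in their host ORFs, regulatory sites in the LCR, a
2–50 nt NCR, the L2-stop/L1-start single-nucleotide overlap (TAA∧ATG or,
for the GTG configuration, TAG∧GTG), a pyrimidine-rich acceptor context at
the L2 3′ end, and an E9 window woven into E1 in frame +1 with a guard stop
just upstream so the E9 call is exact.  Random filler is then repaired in
place until no non-planted reading frame at or above the accessory
threshold survives and no unplanned regulatory motif remains in the
LCR/NCR; repairs touch only non-planted positions and change coding
positions only synonymously, so the planted truth is invariant under
repair.  The repair criterion compares `find_orfs()` output against the
construction's own interval list — not against the annotator's decisions —
so annotation-recovery tests remain a real check.  Default copy numbers
(8 atypical E2-binding sites, no typical site, TATA and polyA present)
reflect the described duck-virus configuration; `random_genome_spec()`
draws ORF and region lengths within the reported ranges so genomes land in
7.3–8.1 kb.

`evolve_alignment()` evolves a root coding sequence down a balanced
genus/species/type/subtype design with transition-biased (κ:1) single-site
events, calibrating per-level branch event counts so the realized mean
identity of leaf pairs joined at each level hits its target within ±1
percentage point (multiplicative adjustment of cumulative budgets, at most
10 rounds).  Default targets — 99.5% within subtype, 95% within type, 80%
within species, 65% within genus, 50% between genera — straddle the
demarcation thresholds the way the published identity tables do.  The
`synonymous_only` constraint restricts proposals to codon-preserving
changes and fails loudly when a target exceeds the synonymous capacity of
the root.  No indels, no recombination and no codon-usage realism are
simulated: passing tests show the inference machinery is correct on clean,
gap-free, tree-like data, not that it is robust to alignment error or
recombinant histories.

`generate_cohort()` draws independent Bernoulli statuses per individual at
level-specific prevalences.  Under the published seasonal effect size
(56.1% vs 12.5% at n = 41/72) the deviance test rejects in ≥95% of
replicates, and under equal prevalences its size stays within 0.05 ± 0.02 —
both checked in the suite at the problem sizes stated there (200 and 1000
replicates, chosen to keep the default run inside a few minutes).

# Numerical and design notes

* All generators are pure functions of spec + seed; the RNG state of the
  caller is saved and restored.
* Genome repair and the E9 weave are bounded searches; if a draw cannot be
  repaired the generator re-derives a substream seed (at most 6 attempts)
  and a genuinely infeasible spec errors immediately.
* The E6 zinc spacer is inclusive [39, 42]; multiple spacer lengths at one
  start are reported as separate hits but counted once per start where
  counts matter.
* `lr_test()` accepts either individual-level cohorts or aggregated `k/n`
  tables and gives identical answers; boundary levels (0% or 100%
  positive) keep their observed fitted proportions and are flagged.
* Known limitations: no reverse-strand or homology-based gene naming, no
  E4/E5/E8 calling, no ML/Bayesian inference or model selection, no
  codon-aware alignment, no dN/dS estimation, and no replication of the
  neural-network splice scores.
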