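---
title: "mirheat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirheat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirheat` analyses replicate-free small RNA sequencing studies that compare
a heat-tolerant (HT) and a heat-sensitive (HS) genotype over a short stress
time course (0, 6, 12 h). This vignette explains the statistical models and
algorithms, the parameters a user may want to move, the scope of the
synthetic-data generator, and the choices we made where the design was
genuinely open.

## 1. Read cleaning and tag collapsing

Raw reads are insert + 3' adapter, truncated at the instrument read length.
`clean_reads()` applies discard rules in a fixed order: no detectable 3'
adapter, empty insert, poly-A artifact, optional 5'-primer contaminant,
then the insert length bounds (15-30 nt inclusive by default). Survivors
collapse to unique tags with per-library counts, and the stats ledger
always balances (`total_raw = total_clean + sum(discarded)`).

Choices made where the underlying procedure is usually left unstated:

* Reads without an adapter are **discarded**, not kept untrimmed, because
  an undetected adapter means the insert boundary is unknown. Setting
  `require_adapter = FALSE` keeps them whole, which also makes cleaning
  idempotent on already-clean inserts.
* The discard order only affects the reason ledger, never which reads
  survive; we fixed it as listed.
* A poly-A artifact is an insert that is at least 90 % A over its full
  length (`polya_min_fraction = 0.9`); the class is standard, the numeric
  definition is ours.
* Adapter matching is a semi-global suffix-prefix comparison: full adapter
  inside the read, or a read suffix against an adapter prefix of at least
  `min_adapter_overlap = 6` nt, at up to `adapter_error_rate = 0.1`
  mismatches per overlap base. Best match = fewest mismatches, ties to the
  leftmost position.
* No base-quality filtering by default; a mean-quality floor exists but is
  off, since pooled-library sRNA studies commonly rely on the adapter and
  length gates alone.

## 2. Classification

Tags are mapped ungapped to the reference on both strands
(`align_tags()`; exact matching uses Biostrings preprocessed dictionaries,
mismatch-tolerant matching a per-tag scan, and both are certified against a
brute-force sliding-window oracle in the test suite). Each tag receives one
of eleven categories. Where hits overlap several features the most specific
annotation wins, with priority

`Mature > Precursor > rRNA > tRNA > snRNA > snoRNA > other sncRNA > Exon >
Intron > Intergenic`,

so reads from a mature miRNA embedded in its precursor (which may itself
sit in a gene) count as `Mature`. Unmapped tags form their own class.
Category tables are read-weighted; percentages are kept at full precision
internally and rendered as `count(percent%)` with two decimals and trailing
zeros trimmed.

ncRNA-class tags are tabulated first and *then* excluded from the miRNA
pools: the classification table describes the whole library, while
known/novel matching operates on the remainder.

Known miRNAs are same-length Hamming matches to the catalog within 3
mismatches (`match_known()`); the best (fewest-mismatch) entry wins, ties
break lexicographically by catalog id. Tags beyond distance 3 from every
entry are the novel-candidate pool. Counts of all tags matching one catalog
entry are summed for quantification.

## 3. MFE folding

`fold_mfe()` is a Zuker-style dynamic program over a deliberately compact
nearest-neighbor model:

* stacking energies for the sixteen Watson-Crick stacks (Turner-like
  values) plus a single mild value (-0.50 kcal/mol) for every stack
  involving a G:U pair;
* length-indexed hairpin, bulge and internal-loop initiation penalties with
  a Jacobson-Stockmayer logarithmic extension, defined at 0.01 kcal/mol
  resolution;
* affine multiloops (3.4 init + 0.4 per branch);
* no dangles, no coaxial stacking, 37 °C only; minimum hairpin loop 3 nt;
  interior loops limited to 30 unpaired bases.

The full parameter table is plain text
(`inst/extdata/rna_energy_params.tsv`) so the model is auditable, and the
parameter list returned by `rna_energy_params()` can be edited to run
reduced models. Two independent oracles certify the implementation: for
sequences up to 18 nt the DP energy equals exhaustive enumeration over all
nested structures, and with zeroed loop penalties and a uniform -1 per
pair the DP reduces exactly to Nussinov base-pair maximization. We claim
qualitative agreement with full-parameter folders (hairpin topology, MFE
sign and magnitude range), not their exact energies.

Numerical choices: energies are integer hundredths of a kcal/mol inside the
DP; ties in energy break toward the structure with more pairs (the pair
count is folded into the integer objective at a scale that cannot disturb
the energy ordering), and the traceback has a fixed scan order, so folding
is fully deterministic.

`mfei()` uses the standard plant-literature definition
`(|MFE|/length*100) / GC%`. The default acceptance threshold MFEI >= 0.85
is configurable; 0.85 is the conventional cut separating pre-miRNA hairpins
from coding/other transcripts.

## 4. Novel miRNA discovery

For each unexplained, expressed (`min_reads >= 5` across libraries) tag:

1. **Unique placement.** A tag must map to one locus. Hits confined to a
   single precursor-sized window (<= 250 nt) count as one locus, because a
   near-perfect hairpin maps its mature to both of its own arms; genuinely
   dispersed multi-mappers are dropped.
2. **Inverted-repeat prefilter.** A hairpin requires an approximate reverse
   complement of the mature within precursor range; tags without one (edit
   distance <= 5 within +/- 200 nt) can never satisfy the duplex criteria
   and skip folding. This is purely an efficiency device; the gate itself
   is unchanged.
3. **Excision ladder.** Candidate windows are cut under both arm
   hypotheses, with tight and generous outer flanks (5 and 20 nt) and
   loop-side extents of 35-180 nt, short to long, spanning typical plant
   pre-miRNA lengths (~60-250 nt). The first passing window — the tightest
   hairpin containing the duplex — is kept; otherwise the best-MFEI window
   is reported with its failure reasons.
4. **Duplex statistics.** The miRNA\* interval is derived from the pairing
   partners of the mature with the canonical 2-nt 3' overhang. Walking the
   duplex, symmetric unpaired stretches count one mismatch per position;
   asymmetric stretches count as a single bulge whose size is the larger
   strand's run (a G:U wobble is a pair, not a mismatch). Frayed mature
   ends count as mismatches.
5. **Meyers gate.** Pass requires a single stem-loop, at most one bulge of
   at most 2 nt, fewer than three mismatches, MFE < 0 and MFEI at or above
   the threshold; the verdict lists every failed criterion.

The star sequence being observed among the tags is reported
(`star_observed`) but not required by default; `strict_star = TRUE`
enables the stringent mode. We default to lenient because requiring a
sequenced star at desk-scale depths would gate discovery on sampling depth
rather than on hairpin quality.

## 5. Differential expression

The replicate-free two-library comparison uses the Audic-Claverie exact
test. With counts `x`, `y` and clean-library totals `N1`, `N2`
(`r = N2/N1`), the conditional law of `y` given `x` is negative binomial
(size `x+1`, success probability `1/(1+r)`); `ac_pvalue()` evaluates the
point mass with log-gamma arithmetic, sums the *smaller* tail directly by
the pmf ratio recurrence (full relative precision even at p ~ 1e-300), and
closes the larger tail through `C + D = 1 + p(y|x)`. The two-sided p-value
is `min(1, 2 min(C, D))`; the tails are printed separately in the outputs
because the test conditions on `x` and is not exactly exchangeable in
`(x, y)`.

Around the test sit: TPM normalization against each library's total clean
reads (a switch to miRNA-mapped totals exists, since published tables are
sometimes computed against restricted denominators); the 0 -> 0.01 TPM
floor applied to exact zeros only, so appear/disappear miRNAs keep finite
log fold-changes; the low-expression filter dropping miRNAs below 1 TPM in
*all* libraries; `log2(N2/N1)` fold-changes from floored TPM while
p-values use raw counts (the floor is meaningful only for ratios);
Benjamini-Hochberg FDR within each contrast; and direction calls requiring
both `FDR <= 0.01` and `|log2FC| >= 1` (both configurable; these defaults
are consistent with the significance pattern of published tables of this
design, whose listed entries all satisfy them).

Membership labels aggregate contrasts: a miRNA significant in at least one
HT contrast and no HS contrast is `HT-only`, symmetrically `HS-only`,
`both` when significant in each genotype, `none` otherwise; a miRNA
significant at both timepoints still counts once.

## 6. Targets, enrichment, qPCR

Target scoring uses the Allen penalty scheme (mismatch 1, G:U 0.5, gap 2,
doubled at miRNA positions 2-13), chosen because the commonly used plant
target predictors descend from it. Scorer A is the penalty cutoff
(<= 4.0); scorer B additionally requires the site's duplex stacking energy
to reach 70 % of the perfect-complement duplex under the package's own
stacking table — an energy-ratio criterion in the spirit of
hybridization-based predictors. Only sites found by both scorers (>= 50 %
overlap) survive, mirroring the two-tool consensus practice. The bulk scan
is a banded dynamic program in C++; the R scorer `score_target()` is the
reference implementation and the two are asserted equal in the tests.

Enrichment is the upper-tail hypergeometric test per term, BH-corrected,
with the universe defaulting to all genes in the supplied term map (the
background set is configurable because published analyses rarely state
theirs). qPCR quantification is textbook 2^-ddCt against a U6 reference
with amplification efficiency assumed exactly 2; concordance with
sequencing is the Pearson r² over per-miRNA log2 fold-changes.

## 7. The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is
designed around: six libraries (HT/HS x 0/6/12 h) of 1e5 reads on a 100 kb
single-chromosome genome hosting 24 known and 12 novel miRNA precursors,
rRNA/tRNA/snRNA/snoRNA/other contamination at 0.6/2/0.1/0.03/0.03 % of
reads (within the ranges such studies report), poly-A/no-insert/oversized
artifacts at 2 % each, a modal tag length of 21 nt, and miRNA tags at 18 %
of reads with rank-skewed abundances. Mature counts are negative binomial
with dispersion 0.01 — mild technical overdispersion appropriate for
pooled libraries without biological replicates — and the planted
differential effects are +/- 2 log2 units at both heat timepoints of the
affected genotype, plus appear-from-zero and silenced-to-zero miRNAs that
exercise the TPM floor. The DE plan assigns HT-only, HS-only and both
memberships to known and novel miRNAs in fixed template roles.

Designed hairpins are built by explicit reverse-complement arm
construction, not by sampling-until-folds, so discovery has an exact
answer key: loops, outer flanks and bulge inserts are drawn from a
non-self-pairing A/C alphabet, bulge bases are chosen not to pair with the
mature bases facing the insertion point, and designed mismatches and
bulges sit in opposite halves of the arm. These constraints make the
designed stem the unique low-energy topology; without them the energy
model occasionally re-renders a designed defect as a different (equally
physical) loop and the key would be approximate. Class-fraction reads are
drawn against the nominal non-miRNA budget so every class's expected count
is depth x fraction in every library, independent of the planted DE
effects.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and quality variation,
5' adapters and UMIs, true biological replicate variance (the pooled-library
design pools replicates before sequencing), miRNA families and sequence
conservation, isomiR length heterogeneity of a single locus, and
genome-scale repeat structure. Recovery rates on the simulator certify the
implementation, not expected performance on real libraries.

## 8. Problem sizes and runtime choices

The shipped tests fold all sequences up to 18 nt against exhaustive
enumeration (500 random sequences), check the exact test against the
negative-binomial identity on a 200-point grid, simulate 10,000 null count
pairs (Poisson mean 100 — large enough that the discrete test's size is
near its nominal level) for calibration, and run the full pipeline on the
default 6 x 1e5-read study for planted-truth recovery. The acceptance
script repeats the end-to-end run at the same sizes.

## 9. Known limitations

* The energy model is intentionally compact; absolute MFE values differ
  from full Turner-parameter folders, so MFEI thresholds tuned against
  other software should be re-examined before porting.
* The exact test inherits the Audic-Claverie assumptions: a single count
  pair per miRNA, totals treated as fixed, no biological replicate
  variance. With replicates available, a negative-binomial GLM framework
  is the better tool; this package deliberately targets the pooled design.
* Target scoring limits gaps to 2 per strand and does not model target
  accessibility or multiple-site cooperativity.
* Known-miRNA matching is same-length Hamming (no isomiR shifts or
  indels), mirroring the "mismatched nucleotides" convention of catalog
  comparison.
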