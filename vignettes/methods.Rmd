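---
title: "Methods: spectral-count quantification, differential expression, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count quantification, differential expression, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceprot)
```

## The quantification model

Label-free spectral counting treats the number of MS/MS spectra matched to
a protein's peptides in one run (SpC) as a proxy for its abundance. Two
systematic effects make raw SpC incomparable: longer proteins produce more
tryptic peptides, and each run samples only a fraction of the peptide
mixture, so total counts and detected-protein sets vary run to run
("analytical incompleteness"). The normalized spectral abundance factor
(NSAF) addresses both by length-correcting and closing each sample to a
unit total:

$$\mathrm{NSpC}_k \;=\; \frac{(\mathrm{SpC}/L)_k}{\sum_{i=1}^{n}(\mathrm{SpC}/L)_i}$$

with $L$ the residue length and the denominator summed over the $n$
retained proteins within that sample. `nsaf_normalize()` computes this per
sample column; conservation (each column sums to 1) is asserted to
$10^{-9}$ in the tests.

Three preprocessing rules matter and interact:

* **Replicate filter** (`apply_replicate_filter()`, `min_spc = 2`): a
  protein enters the comparative analysis only if, in at least one
  (variety, condition) group, *every* replicate has SpC ≥ 2. Requiring the
  filter in *all* groups would contradict the on/off expression patterns
  such data show — a protein convincingly present in cold but absent in
  control is exactly the kind of responder the analysis is after — so the
  default scope is `any-group`, with `per-comparison` and `all-groups`
  available and the choice recorded in the run summary.
* **Pseudocount** (`add_pseudocount()`, `epsilon = 0.1`): after filtering,
  remaining zeros become 0.1 *on the SpC scale, before length division*.
  This makes the ln transform defined everywhere and turns on/off proteins
  into large finite ratios rather than infinities.
* **Order**: filter, then pseudocount, then normalize over the retained
  set. The NSAF denominator is therefore a property of the filtered set,
  and adding or removing an unretained protein does not perturb anyone's
  NSpC.

## The differential test

Per variety, `differential_expression()` compares cold vs control with a
two-sided two-sample t-test on $\ln(\mathrm{NSpC})$. The default is the
pooled-variance Student's t ($df = 4$ at $3+3$ replicates), the classical
choice for tiny balanced groups; Welch is available via
`var_equal = FALSE`. Lognormal-ish multiplicative noise is the standard
working assumption for relative abundance data, and on the ln scale the
t-test is approximately calibrated — the acceptance suite verifies a null
false-positive rate near $\alpha = 0.05$ on simulated data with no planted
effects.

Zero-variance degeneracies (possible after pseudocounting, when a protein
has identical values in both groups or constant unequal values) resolve
deterministically — $p = 1$ if the group means agree, $p = 0$ (flagged
`degenerate`) if not — so batch runs never abort.

The effect-size measure is the ratio of arithmetic group means of NSpC,
cold/control. A protein is called `up` when $p < \alpha$ and ratio ≥ 2,
`down` when $p < \alpha$ and ratio ≤ 1/2; the 2-fold boundary is inclusive
(a ratio of exactly 2.0 is a call). No multiple-testing correction is
applied by default — the procedure mirrors classical per-protein testing
at raw α — but `adjust = "BH"` is available, and the choice is recorded in
the run summary. Cross-variety categorization
(`categorize_responses()`) is pure set algebra over the two DE sets, with
overlap proteins flagged when their direction disagrees between varieties
(discordant responses do occur, and the generator plants independent folds
per variety so they arise in simulation too).

## GO enrichment

`go_enrichment()` performs singular enrichment: for each term with at
least `min_term_size = 2` annotated background proteins, the hypergeometric
upper tail $P(X \ge k)$ with $n$ the annotated input proteins and $N$ the
annotated background, followed by Benjamini–Hochberg across all tested
terms (Benjamini–Yekutieli behind a flag). Conventions follow flat-file
singular enrichment practice: the universe is restricted per namespace to
proteins carrying at least one annotation there; annotations are used as
given, with no GO-DAG ancestor propagation (DAG-aware analysis would need
the ontology graph, which is out of scope); and annotations for proteins
outside the experiment stay in the genome background, because background
term counts are annotation-wide, not experiment-wide.

The tail probability is summed in log space (log-binomials with
log-sum-exp), and the tests require agreement with direct enumeration to
$10^{-12}$ on every valid instance with $N \le 30$.

## Molecular weight and isoelectric point

`compute_mw()` sums average residue masses plus one water (18.0153 Da).
`net_charge()` is the Henderson–Hasselbalch sum over N-terminus,
C-terminus, and the side chains of K, R, H, D, E, C, Y, with the EMBOSS
pepstats default pKa table (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5,
D 3.9, E 4.1, C 8.5, Y 10.1); the table is a function argument, so an
alternative set is a one-line change. `compute_pi()` finds the zero
crossing by bisection on [0, 14] to $10^{-4}$ pH units — every term is
strictly decreasing in pH, so the crossing is unique. Ambiguity codes
contribute mass (X the mean residue mass, B the D/N mean, Z the E/Q mean,
U the cysteine mass) but no charge; disulfides are ignored (all cysteines
treated as free). Reported pI values are conventionally rounded to one
decimal; published pI/MW extremes from other pKa tables can differ in the
second decimal, so comparisons should be made at printed rounding.

## What the generator emulates — and what it does not

`simulate_study()` produces the study design the analysis targets:
2 varieties × 2 conditions × 3 biological replicates. Its defaults are the
package's fixed "study conditions":

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 2000 | desk-scale stand-in for a few-thousand-protein embryo proteome |
| `length_law` | lognormal, median 320 aa, sdlog 0.5 | typical plant proteome length spread |
| `abundance_law` | lognormal sdlog 2, winsorized at the 99.5 % quantile | 3–4 orders of magnitude of relative abundance; the cap makes the top of the proteome a handful of comparably abundant proteins (storage/housekeeping), not one runaway species |
| `spectra_budget` | 50 000 | fixed per-run MS/MS sampling depth; counts are multinomial conditioned on this total, which enforces the compositional structure NSAF assumes |
| `replicate_noise` | 0.2 (lognormal sdlog) | biological + preparation noise per (protein, run); calibrated so within-group replicate NSpC R² falls in the 0.78–0.95 reproducibility band |
| `dropout_tau` | 1 | detection probability $1 - e^{-\mu/\tau}$ for expected count $\mu$; with the abundance spread this yields per-run detection of roughly 60–70 % of the proteome and a filtered, "globally normalized" set near 60 % — the run-to-run incompleteness the filter and pseudocount exist for |
| `de_fraction` | 0.05 per variety | a minority of the proteome responds to cold |
| `fold_law` | log-uniform on [2, 64], both directions | spans calls at the threshold through near on/off responses |
| `overlap_fraction` | 0.1 | a small shared response between varieties, with independent fold draws so discordant overlaps occur |

Fold-ups saturate at the abundance cap (a protein cannot take more than
the ceiling share of sampled spectra); the realized fold is what the truth
table records, so parameter-recovery tests compare against the generative
truth. All draws flow from the single `seed` (the experiment and GO-map
streams use fixed offsets of it), making fixtures byte-stable; the
packaged fixture under `inst/extdata/fixture/` is regenerated
byte-identically by `export_fixture(simulate_study(fixture_config(),
sequences = TRUE), ..., fixture_config())`.

Not emulated: peptide-level identity (counts are drawn at the protein
level), retention-time or ionization physics, shared-peptide ambiguity
between homologous proteins, and identification FDR. Passing tests
therefore show the *statistical* pipeline behaves correctly under the
assumed count model — not that any particular real dataset satisfies that
model.

## Numerical and design choices

* Sizes were chosen to keep the default test run fast at desk scale:
  1000 random matrices for conservation, the full $N \le 30$ instance
  sweep for the hypergeometric oracle, 1000 3-vs-3 draws for the t-test
  oracle, one 2000-protein simulation each for null calibration, recovery,
  and the R² band.
* Ties and boundaries: ratio exactly 2.0 is a DE call; BH output is capped
  at 1; bisection returns the bracket midpoint; the (unreachable for valid
  sequences) no-ionizable-group case returns pH 7.0 with a warning.
* Degenerate inputs error early with the offending protein/sample named:
  negative or fractional counts, duplicate ids, unknown design labels,
  missing lengths, malformed GO ids.
* `run_pipeline()` stages communicate through files so any stage can be
  re-run in isolation; the run summary embeds the parameter snapshot and
  stage tallies, and tallies are cross-checked against the written tables
  before the summary is finalized.

## Known limitations

* **Down-regulation magnitudes saturate at the detection floor.** When a
  strongly down-regulated protein's cold-side counts fall to zero, the 0.1
  pseudocount sets the measurable floor, and the estimated ratio
  overstates the true magnitude. The acceptance suite makes this visible:
  median ln-ratio recovery error is within ln(1.3) over all quantifiable
  planted effects, but the strict subset of |fold| ≥ 8 effects exceeds
  that tolerance, driven by large down-folds. At realistic sampling depth
  this is intrinsic to pseudocounted spectral counting, not a tuning
  artifact: a 64-fold decrease can only be bounded, not estimated, unless
  the control side carries hundreds of spectra. Extreme reported ratios
  from such pipelines should be read as "off in one condition".
* **NSAF is compositional.** A large induced protein consumes spectra
  budget and deflates everyone else's NSpC in that condition, shifting all
  ratios by a shared factor. With a small DE fraction the shift is modest,
  but it is a real bias of the method: unchanged proteins in a condition
  with large induced responders show ratios slightly below 1.
* Raw-scale Pearson R² as a reproducibility score is dominated by the most
  abundant proteins; it is reported because it is the field's conventional
  QC number, not because it summarizes the bulk of the matrix.
* The t-test at n = 3 per group has limited power for folds near the
  2-fold threshold; sensitivity claims in the tests are therefore made for
  strong (≥ 8-fold), well-sampled (mean SpC ≥ 10) effects.
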