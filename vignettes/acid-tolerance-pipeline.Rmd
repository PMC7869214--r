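---
title: "Linking polyproline translation to acetic-acid tolerance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking polyproline translation to acetic-acid tolerance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidtol)
```

## The scientific problem

The translation factor eIF5A is required to resolve ribosome stalling at
runs of consecutive proline codons: proteins carrying polyproline motifs
depend on eIF5A activity for efficient synthesis, and the more or longer
the motifs, the stronger the dependence. In *Saccharomyces cerevisiae*,
elevated eIF5A activity improves growth under acetic-acid stress, which
suggests that some acid-tolerance effectors are polyproline proteins whose
synthesis is eIF5A-limited. `acidtol` implements the computational side of
that argument as a reusable pipeline:

1. **motif scanning** — find and classify maximal polyproline runs across a
   proteome;
2. **gene-set integration** — merge acid-sensitivity deletion screens into
   a non-redundant tolerance candidate set, intersect it with the
   polyproline genes, and keep the high-dependence class;
3. **regulon analysis** — call "direct" transcription-factor targets by
   scanning promoters for a consensus element (the URS1 site bound by
   Ume6p) and overlap them with the tolerance set;
4. **quantitative arithmetic** — calibrator-normalised mRNA levels
   (delta-delta-Cq), GFP protein abundance (RFU), translation efficiency,
   and percent differences;
5. **phenotype extraction** — growth lag, maximum specific growth rate and
   growth efficiency from OD600 curves; CFU survival percentages;
6. **synthetic data** — generators for all of the above with recorded
   ground truth, so every stage is testable without any download.

## Motif model

A polyproline motif is a **maximal** run of at least `min_run_len = 3`
consecutive prolines. Maximality matters: a six-proline stretch is one run
of length six, not four overlapping PPP windows, and only under that
reading are the two dependence classes coherent — *multiple* separate runs
versus a *single long* run. A protein is classed as highly eIF5A-dependent
when it has at least `min_multi_runs = 2` separate runs or a run of length
at least `min_long_run = 4`. Matching is case-insensitive; any non-proline
letter, including the ambiguity code `X` and the stop `*`, breaks a run —
the conservative choice, since an ambiguous residue is not evidence of
proline.

Pattern labels are canonical strings (counts per run length, ascending,
e.g. `2x3P+1x4P`), so a census of a proteome is a deterministic
tabulation. Run coordinates are stored and reported 1-based inclusive, the
convention used in R and read naturally by biologists. Exact census bin
edges for long runs are report configuration, not analysis: the census
exposes raw labels and leaves any binning to the caller.

## Gene-set integration

Deletion screens and sequence databases mix standard gene names and
systematic ORF names, so all set arithmetic happens in the systematic
namespace through a required alias map; identifiers missing from the map
are kept verbatim and logged, never dropped, because silently losing genes
corrupts the candidate-funnel counts. The "consistency analysis" of
overlapping screens is an alias-resolved deduplicating union — the only
reading under which three screens can combine to fewer genes than their
size sum — and the union report records per-source sizes and all pairwise
overlaps so the inclusion–exclusion identity can be audited. Functional
categorisation uses a flat gene-to-category slim: a gene with *k*
categories counts once in each (member lists are emitted so single-count
views remain derivable), and unannotated genes appear under
`unknown function`. Enrichment statistics are deliberately out of scope.

## Consensus scanning

Direct transcription-factor targets are called by scanning promoters for
an IUPAC consensus. The default pattern is `TCGGCGGCT`, the canonical URS1
core bound by Ume6p; this is a configurable choice, not a fact derived
from data in the package, and any IUPAC-degenerate pattern may be
substituted. Both strands are scanned by default because URS1 function is
orientation-independent; promoters are taken 5'→3' on the coding strand
and trimmed to the `promoter_window = 1000` bp nearest the start codon.
All overlapping matches are reported — downstream logic needs only
presence or absence — and a literal `N` in a promoter never matches, even
against a degenerate pattern code, so uncertain sequence cannot create a
"direct" call. Matching is delegated to `Biostrings::matchPattern()`; the
test suite holds it against an independent brute-force all-offsets matcher.

## Expression arithmetic

Relative transcription uses the classic delta-delta-Cq model with
replicate Cq values averaged per (sample, gene) before the differencing —
matching the one-level-per-condition presentation typical of qPCR figures
— and an amplification efficiency fixed at 2 by default (configurable in
(1, 2]; no standard curves are modelled). Instrument-side Cq calling is
upstream of this package: Cq tables are inputs. The calibrator sample has
level exactly 1 by construction, and adding any constant to all Cq of a
run leaves every level unchanged.

Protein abundance of GFP-tagged proteins is fluorescence intensity divided
by OD600 (RFU), normalised to a calibrator; background subtraction with an
untagged-strain blank is possible upstream but not applied by default.
Translation efficiency is relative protein over relative mRNA for the same
gene and calibrator, so re-expressing everything against a different
calibrator multiplies all values by one constant and changes no ratio.
Percent differences are reported to the nearest integer in tables.

The packaged worked example combines a 67 % baseline translation-efficiency
advantage of an eIF5A-overexpressing reporter strain (ratio 1.67) with
acid-stress inductions of mRNA (1.6× control, 2.7× overexpressor) and
protein (2.4×, 4.1×): the stress-condition TE ratio is
1.67 × (4.1/2.7)/(2.4/1.6) ≈ 1.69, a 69 % advantage. The printed baseline
protein fold of 1.6 and the 67 % TE statement disagree at printed
precision (1.6 vs 1.67); the package treats the TE ratio 1.67 as the
baseline and keeps the discrepancy visible here rather than resolving it
silently. The significance test behind figure asterisks is not named in
the source material; `two_group_test()` uses the two-sided
unequal-variance (Welch) t-test, the safe default for small replicate
groups, with stars at 0.05/0.01. Two constant groups are handled
explicitly (p = 1 if equal, 0 otherwise) since the t statistic is
undefined there.

## Growth variables

`growth_variables()` implements the classical graphical reading of a
growth curve: fit least-squares lines to natural-log OD over every
contiguous window of `window_size` points; the maximum slope is the
maximum specific growth rate (earliest window on ties, for determinism);
the lag is where that tangent crosses the initial-density level; growth
efficiency is the total linear-scale OD change from initial density to the
maximum. The log-scale fit is the standard reading of "slope of the
exponential phase" as a specific growth rate; a linear-scale alternative
is available via `log_scale = FALSE`. The initial density is the mean of
the first `max(2, window_size/2)` readings rather than the single first
point, which buys robustness to read noise at the cost of a small upward
lag bias (fractions of a sampling interval) on curves with no flat phase
at all. Negative lags are clipped to zero and flagged; readings at or
below `od_floor = 1e-4` are clipped and flagged; slopes within rounding of
zero are reported as no growth with an undefined lag.

**Choosing the window.** The default `window_size = 4` suits sparse
(hourly) sampling and noise-free curves. For dense plate-reader data
(15-minute cadence) with realistic multiplicative noise, a 4-point window
makes the max-slope estimator an order statistic over many noisy slopes
and biases the rate badly upward; the package's tests use a 12-point
window there — spanning roughly one mass-doubling time at typical yeast
rates — which in a 500-curve simulation at 5 % noise keeps the median
absolute relative error of both rate and lag under 5 %. The residual
*downward* bias of any windowed estimate on a logistic curve is about
`rate × od/capacity` averaged over the window; at the default inoculum
(OD 0.05) and capacity (OD 2.0) this stays within 0.01 /h for rates up to
about 0.35 /h.

Survival is plain arithmetic: CFU at time *t* as a percentage of the
starting count, exactly 100 % at time zero and invariant to any dilution
factor.

## The synthetic-data generators

Every generator takes an explicit seed (restored afterwards; no global
state leaks) and returns its ground truth beside the data; the same seed
reproduces outputs byte-identically.

* `simulate_proteome()` plants requested pattern labels into background
  sequence drawn from the 19 non-proline amino acids, with at least one
  non-proline residue between planted runs, so the planted census is
  exact. A realistic mode adds background proline at a chosen frequency,
  in which case truth is recomputed from the generated sequences.
* `simulate_screens()` plants all seven Venn regions of three gene sets
  exactly. The defaults used in the bundled study emulation are screens of
  216, 650 and 409 genes whose union is 1031.
* `simulate_regulon()` plants one consensus site per direct target
  (random position, random orientation when both strands are scanned) and
  rejection-samples non-direct promoters to contain zero matches on either
  strand.
* `simulate_growth()` uses a transparent three-phase model — flat at the
  inoculation density until the lag, then a logistic rise at the stated
  maximum specific rate toward the carrying capacity — with multiplicative
  log-normal noise, mimicking an OD reader. The three-phase form was
  chosen over Baranyi-type models precisely because its ground truth is
  unambiguous.
* `simulate_expression()` and `simulate_fluorescence()` invert the
  delta-delta-Cq and RFU arithmetic with Gaussian cycle noise and
  multiplicative intensity noise respectively.
* `simulate_funnel_bundle()` wires all of the above into one coherent
  synthetic study — by default at the full scale of the emulated one:
  6000 genes, 558 polyproline proteins of which 85 fall in the 1031-gene
  screen union and 17 are high-dependence, and a 1481-target regulon with
  170 direct targets, 176 targets and 24 direct targets inside the
  tolerance union — and `write_funnel_bundle()` serialises it in exactly
  the plain-text formats the pipeline reads (screen lists deliberately
  written under aliases where they exist, so alias resolution is always
  exercised).

What the generators do **not** emulate: real yeast amino-acid or
nucleotide composition, codon structure, correlated screen noise, plate
spatial effects, or amplification-efficiency drift. Passing the round-trip
tests therefore demonstrates that the pipeline's arithmetic and
bookkeeping are correct, not that the biological counts of any particular
database snapshot will be reproduced — those depend on the proteome
version, the screens' supplementary lists and the regulon database used.

## Orchestration

`funnel_config()` collects all paths and parameters in one flat
configuration (readable from YAML via `read_run_config()`); its defaults
are exactly the thresholds above, asserted by a test. `run_funnel()`
executes scan → union → intersect → high-dependence filter → categorise →
regulon overlap, writes one tidy TSV per stage plus a stage-by-stage
report of input/output sizes (count drift being the main failure mode of
gene-list plumbing), aborts naming the failed stage, and leaves a `FAILED`
marker beside partial outputs. `run_quant_report()` produces the
expression, abundance, growth, survival and translation-efficiency
tables. These functions, with the configuration file, are the package's
command-line surface; `scripts/acceptance.R` shows the pattern of driving
a full run from `Rscript`.

## Problem sizes and budgets

The test suite generates everything it needs at run time: the full-scale
bundle above, 1000 random sequences × six minimum-run-length settings
against the brute-force run scanner, 250 + 200 random promoters against
the brute-force IUPAC matcher, 500 noisy growth curves, and 500 two-group
test simulations. The complete suite runs in well under two minutes on a
single core.

## Known limitations

* The URS1 consensus default is a literature choice; regulon "direct"
  counts depend entirely on it and on the promoter window.
* The max-slope growth estimator is intentionally non-parametric; curves
  with diauxic shifts or death phases report the steepest phase only.
* Single-reference-gene qPCR normalisation only; no multi-reference
  schemes, no amplification-curve or melt-curve QC.
* Alias resolution is exact-match against a provided table; there is no
  fuzzy matching and no ontology traversal behind the flat category slim.
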