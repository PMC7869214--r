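# acidtol

Polyproline motif scanning and acetic-acid tolerance analysis in yeast.

The translation factor eIF5A relieves ribosome stalling at consecutive
proline codons, so proteins with polyproline motifs depend on eIF5A
activity for efficient synthesis. In *Saccharomyces cerevisiae*, elevated
eIF5A activity improves acetic-acid tolerance — a trait that matters for
lignocellulosic fermentation, where acetic acid is the main inhibitor in
the hydrolysate. `acidtol` is for researchers who want to run, or stress-
test, the computational chain that connects those two facts:

* **Motif scanning** — maximal runs of ≥3 prolines (`PPP`/3P) per protein,
  canonical pattern labels (`2x3P+1x4P`), and a proteome census. A protein
  is *highly eIF5A-dependent* when it has ≥2 separate runs or one run of
  ≥4 prolines.
* **Candidate funnel** — alias-resolved deduplicating union of
  acid-sensitivity deletion screens, intersection with polyproline genes,
  high-dependence filtering, functional categorisation.
* **Regulon analysis** — direct transcription-factor targets called by an
  IUPAC consensus scan of promoters (default: the URS1 core `TCGGCGGCT`
  bound by Ume6p, both strands), overlapped with the tolerance set.
* **Quantitative arithmetic** — ΔΔCq relative expression
  (level = E^−ΔΔCq, reference gene ACT1, calibrator ≡ 1), GFP abundance as
  RFU = FI/OD600, translation efficiency TE = protein level / mRNA level,
  percent differences, Welch tests.
* **Growth and survival** — lag, maximum specific growth rate (max slope
  of ln OD over a sliding window) and growth efficiency (ΔOD600) from
  growth curves; CFU survival percentages.
* **Synthetic data** — generators for every input with recorded ground
  truth (planted motif censuses, Venn-exact screens, planted promoter
  sites, three-phase growth curves, Cq tables), so the whole pipeline is
  testable offline.

## Worked example

The package's headline number is a pure computation from five measured
values: an eIF5A-overexpressing reporter strain starts with a 67 %
translation-efficiency advantage for *UME6* mRNA (ratio 1.67); under
acetic-acid stress, mRNA is induced 1.6× (control) and 2.7×
(overexpressor), protein 2.4× and 4.1×:

```r
library(acidtol)
te_stress_gain(baseline_ratio = 1.67,
               protein_fold_ctrl = 2.4, mrna_fold_ctrl = 1.6,
               protein_fold_over = 4.1, mrna_fold_over = 2.7)
#> $te_induction_ctrl
#> [1] 1.5
#> $te_induction_over
#> [1] 1.518519
#> $stress_ratio
#> [1] 1.690617
#> $percent_gain
#> [1] 69
```

Stress raises the control strain's translation efficiency 1.5-fold and the
overexpressor's 1.52-fold; combined with the 1.67 baseline, the
overexpressor translates *UME6* 69 % more efficiently under acid stress.

The full candidate funnel runs from files; here on a synthetic study
bundle whose truth is planted at the scale of the emulated one:

```r
b <- simulate_funnel_bundle(seed = 1)
paths <- write_funnel_bundle(b, "bundle")
cfg <- funnel_config(
  proteome_fasta = paths[["proteome"]],
  screen_files = unname(paths[c("screen1", "screen2", "screen3")]),
  alias_file = paths[["aliases"]], annotation_file = paths[["annotations"]],
  regulon_file = paths[["regulon"]], promoter_fasta = paths[["promoters"]],
  out_dir = "bundle/out")
run_funnel(cfg)
#>             stage n_in n_out                  file
#> 1            scan 6000   558          profiles.tsv
#> 2           union 1275  1031            funnel.tsv
#> 3       intersect 1031    85            funnel.tsv
#> 4 high_dependence   85    17            funnel.tsv
#> 5      categorize   85    10        categories.tsv
#> 6  regulon_direct 1481   170 regulon_annotated.tsv
#> 7 regulon_overlap  176    24           overlap.tsv
```

Reading the report: 558 of 6000 proteins carry polyproline runs; the three
screens (216 + 650 + 409 = 1275 hits) union to 1031 tolerance candidates;
85 of those encode polyproline proteins, 17 of them in the
high-dependence class; of 1481 regulon targets, 170 carry the consensus in
their promoter (direct), 176 targets fall in the tolerance set, 24 of
those are direct. Every number equals the generator's planted truth.

Growth phenotyping of a noisy stressed culture (planted: 32 h lag,
0.15 /h):

```r
g <- simulate_growth(lag = 32, rate = 0.15, noise_sd = 0.05, seed = 4)
growth_variables(g$data$time, g$data$od, window_size = 12)
#> growth variables: lag 32.95 h, rate 0.1732 /h, efficiency 2.039
```

See the methods vignette (`vignettes/acid-tolerance-pipeline.Rmd`) for the
models, parameter choices and limitations.

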