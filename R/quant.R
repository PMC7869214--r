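# Calibrator-normalised expression arithmetic: delta-delta-Cq relative
# transcription, GFP relative fluorescence units, relative protein
# abundance, translation efficiency and percent differences.

#' Relative expression by the delta-delta-Cq method
#'
#' For each sample, replicate Cq values are averaged per (sample, gene),
#' then
#' \deqn{level = E^{-[(Cq_{target} - Cq_{ref})_{sample} -
#'                   (Cq_{target} - Cq_{ref})_{calibrator}]}}
#' with amplification efficiency E (default 2, the classic 2^-ddCq). The
#' calibrator sample has level exactly 1. Adding a constant to every Cq of a
#' run leaves all levels unchanged.
#'
#' @param cq Data frame with columns `sample`, `gene`, `replicate`, `cq`
#'   (cycles, positive).
#' @param target_genes Character vector of target gene ids.
#' @param reference_gene Housekeeping reference gene present in every
#'   sample (e.g. `"ACT1"`).
#' @param calibrator_sample Sample whose level is defined as 1.
#' @param efficiency Amplification efficiency, in (1, 2].
#' @return Data frame with columns `sample`, `gene`, `level`, `kind`
#'   (`"mRNA"`) and `calibrator`.
#' @export
relative_expression <- function(cq, target_genes, reference_gene = "ACT1",
                                calibrator_sample, efficiency = 2) {
  stopifnot(is.data.frame(cq),
            all(c("sample", "gene", "replicate", "cq") %in% names(cq)))
  if (!is.numeric(efficiency) || efficiency <= 1 || efficiency > 2) {
    stop("efficiency must be in (1, 2]")
  }
  if (any(cq$cq <= 0)) stop("Cq values must be positive")
  mean_cq <- stats::aggregate(cq ~ sample + gene, data = cq, FUN = mean)
  key <- function(s, g) paste(s, g, sep = "\r")
  lut <- stats::setNames(mean_cq$cq, key(mean_cq$sample, mean_cq$gene))
  samples <- unique(cq$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  ref_missing <- samples[!key(samples, reference_gene) %in% names(lut)]
  if (length(ref_missing)) {
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(ref_missing, collapse = ", "))
  }
  rows <- list()
  for (g in target_genes) {
    have <- samples[key(samples, g) %in% names(lut)]
    if (!calibrator_sample %in% have) {
      stop("calibrator sample lacks Cq for target gene ", g)
    }
    dcq <- lut[key(have, g)] - lut[key(have, reference_gene)]
    ddcq <- dcq - dcq[have == calibrator_sample]
    rows[[g]] <- data.frame(sample = have, gene = g,
                            level = efficiency^(-ddcq),
                            kind = "mRNA", calibrator = calibrator_sample,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Relative fluorescence unit (RFU)
#'
#' Fluorescence intensity divided by OD600: a per-cell-mass proxy for the
#' abundance of a GFP-tagged protein.
#'
#' @param fi Fluorescence intensity (arbitrary units; ex 488 / em 509 nm).
#' @param od600 Optical density at 600 nm (must be positive).
#' @return `fi / od600`, vectorised.
#' @examples
#' rfu(800, 0.8)  # 1000
#' @export
rfu <- function(fi, od600) {
  if (any(od600 <= 0)) stop("od600 must be positive to compute RFU")
  fi / od600
}

#' Calibrator-normalised protein abundance from RFU values
#'
#' @param rfus Named numeric vector of RFU per sample.
#' @param calibrator_sample Sample whose abundance is defined as 1.
#' @return Data frame with columns `sample`, `level`, `kind` (`"protein"`),
#'   `calibrator`.
#' @export
relative_abundance <- function(rfus, calibrator_sample) {
  stopifnot(is.numeric(rfus), !is.null(names(rfus)))
  if (!calibrator_sample %in% names(rfus)) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  cal <- unname(rfus[calibrator_sample])
  if (cal <= 0) stop("calibrator RFU must be positive")
  data.frame(sample = names(rfus), level = unname(rfus) / cal,
             kind = "protein", calibrator = calibrator_sample,
             stringsAsFactors = FALSE)
}

#' Translation efficiency: relative protein over relative mRNA
#'
#' Both inputs must be normalised against the same calibrator; the
#' calibrator's translation efficiency is then exactly 1, and re-expressing
#' against a different calibrator rescales all efficiencies by one constant
#' without changing any ratio between samples.
#'
#' @param protein,mrna Either plain numeric vectors of matching length, or
#'   data frames with columns `sample`, `level`, `calibrator` (as returned
#'   by [relative_abundance()] / [relative_expression()]; data frames are
#'   merged on `sample`).
#' @return For numeric input, a numeric vector `protein / mrna`. For data
#'   frames, a data frame with columns `sample`, `te`.
#' @examples
#' translation_efficiency(2.4, 1.6)  # 1.5
#' @export
translation_efficiency <- function(protein, mrna) {
  if (is.numeric(protein) && is.numeric(mrna)) {
    if (any(mrna <= 0)) stop("mRNA level must be positive")
    return(protein / mrna)
  }
  stopifnot(is.data.frame(protein), is.data.frame(mrna))
  if (!identical(unique(protein$calibrator), unique(mrna$calibrator))) {
    stop("protein and mRNA levels use different calibrators")
  }
  m <- merge(protein[c("sample", "level")], mrna[c("sample", "level")],
             by = "sample", suffixes = c(".protein", ".mrna"))
  if (any(m$level.mrna <= 0)) stop("mRNA level must be positive")
  data.frame(sample = m$sample, te = m$level.protein / m$level.mrna,
             stringsAsFactors = FALSE)
}

#' Percent difference of a relative to b
#'
#' @param a,b Numeric; `b` must be positive.
#' @param digits Rounding for reporting; `NULL` returns the raw value.
#'   Tables report the nearest integer percent.
#' @return `100 * (a - b) / b`, optionally rounded.
#' @export
percent_difference <- function(a, b, digits = NULL) {
  if (any(b <= 0)) stop("baseline b must be positive")
  out <- 100 * (a - b) / b
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Translation-efficiency gain under stress from fold inductions
#'
#' Combines a baseline (unstressed) translation-efficiency ratio between an
#' overexpressor and its control with the fold inductions of protein and
#' mRNA under stress in each strain (every fold relative to that strain's
#' own unstressed state, which cancels the shared calibrator):
#' \deqn{ratio_{stress} = ratio_{baseline} \times
#'   \frac{protein_{over}/mRNA_{over}}{protein_{ctrl}/mRNA_{ctrl}}}
#' and reports the percent by which the overexpressor's translation
#' efficiency exceeds the control's under stress.
#'
#' @param baseline_ratio Unstressed TE ratio overexpressor/control (e.g.
#'   1.67 for a 67 percent baseline advantage).
#' @param protein_fold_ctrl,mrna_fold_ctrl Stress inductions in the control
#'   strain.
#' @param protein_fold_over,mrna_fold_over Stress inductions in the
#'   overexpressing strain.
#' @return List with `te_induction_ctrl`, `te_induction_over`,
#'   `stress_ratio` and `percent_gain` (nearest integer percent).
#' @examples
#' # fold chain: baseline 1.67; control 2.4/1.6; overexpressor 4.1/2.7
#' te_stress_gain(1.67, 2.4, 1.6, 4.1, 2.7)$percent_gain  # 69
#' @export
te_stress_gain <- function(baseline_ratio, protein_fold_ctrl, mrna_fold_ctrl,
                           protein_fold_over, mrna_fold_over) {
  stopifnot(baseline_ratio > 0)
  te_ctrl <- translation_efficiency(protein_fold_ctrl, mrna_fold_ctrl)
  te_over <- translation_efficiency(protein_fold_over, mrna_fold_over)
  ratio <- baseline_ratio * te_over / te_ctrl
  list(te_induction_ctrl = te_ctrl,
       te_induction_over = te_over,
       stress_ratio = ratio,
       percent_gain = percent_difference(ratio, 1, digits = 0))
}

#' Bundled UME6 translation-efficiency example
#'
#' Loads the packaged fixture of relative levels for the Ume6p-GFP reporter
#' system (baseline TE advantage of the eIF5A-overexpressing strain, and
#' acid-stress fold inductions of UME6 mRNA and Ume6p protein in both
#' strains) and evaluates [te_stress_gain()] on it.
#'
#' @return The list returned by [te_stress_gain()], plus element `inputs`.
#' @export
ume6_te_example <- function() {
  path <- system.file("extdata", "ume6_te_example.tsv", package = "acidtol",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$value, tab$quantity)
  out <- te_stress_gain(vals[["baseline_te_ratio"]],
                        vals[["protein_fold_control"]],
                        vals[["mrna_fold_control"]],
                        vals[["protein_fold_overexpressor"]],
                        vals[["mrna_fold_overexpressor"]])
  out$inputs <- as.list(vals)
  out
}

#' Replicate summary: mean, sample standard deviation, n
#'
#' @param values Numeric vector.
#' @return List with `mean`, `sd` (n-1 denominator; 0 for a single value)
#'   and `n`.
#' @export
replicate_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values))
}

#' Two-sided unequal-variance two-sample test
#'
#' Welch's t-test between two replicate groups. Degenerate input in which
#' both groups are constant is handled explicitly: p = 1 when the constants
#' agree, p = 0 when they differ (the test statistic is infinite).
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return List with `p_value`, `stars` (see [significance_stars()]),
#'   `mean_a`, `mean_b`.
#' @export
two_group_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("two_group_test needs at least 2 replicates per group")
  }
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  list(p_value = p, stars = significance_stars(p),
       mean_a = mean(a), mean_b = mean(b))
}

#' Significance stars at the 0.05 / 0.01 thresholds
#'
#' @param p P-value(s).
#' @return `"**"` for p < 0.01, `"*"` for p < 0.05, otherwise `""`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}
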