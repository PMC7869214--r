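# Orchestration: run the whole candidate funnel (scan -> union -> intersect
# -> high-dependence filter -> categorise -> regulon overlap) and the
# quantification reports from one flat configuration.

#' Build a run configuration
#'
#' Flat key-value configuration for [run_funnel()] and
#' [run_quant_report()]. The defaults are the pipeline's scientific
#' thresholds: polyproline runs of at least 3 prolines; high eIF5A
#' dependence for at least 2 separate runs or a single run of at least 4;
#' the URS1 core consensus `TCGGCGGCT` scanned on both strands within a
#' 1000-bp promoter window; reference gene `ACT1` with amplification
#' efficiency 2; growth regression window of 4 points.
#'
#' @param ... Named values overriding the defaults, including input paths
#'   (`proteome_fasta`, `screen_files`, `alias_file`, `annotation_file`,
#'   `regulon_file`, `promoter_fasta`, `cq_file`, `plate_file`,
#'   `growth_file`, `survival_file`), `out_dir`, and analysis parameters.
#' @return A named list of class `run_config`.
#' @export
funnel_config <- function(...) {
  cfg <- list(
    proteome_fasta = NULL, screen_files = NULL, alias_file = NULL,
    annotation_file = NULL, regulon_file = NULL, promoter_fasta = NULL,
    cq_file = NULL, plate_file = NULL, growth_file = NULL,
    survival_file = NULL, out_dir = ".",
    min_run_len = 3L, min_multi_runs = 2L, min_long_run = 4L,
    consensus = "TCGGCGGCT", both_strands = TRUE, promoter_window = 1000L,
    reference_gene = "ACT1", calibrator_sample = NULL, efficiency = 2,
    growth_window = 4L, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of flat key-value pairs; keys as in
#'   [funnel_config()]. Relative input paths are resolved against the YAML
#'   file's directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("proteome_fasta", "alias_file", "annotation_file",
                 "regulon_file", "promoter_fasta", "cq_file", "plate_file",
                 "growth_file", "survival_file", "out_dir")
  for (k in intersect(names(raw), path_keys)) {
    if (!is.null(raw[[k]]) && !grepl("^(/|[A-Za-z]:)", raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  if (!is.null(raw$screen_files)) {
    raw$screen_files <- vapply(raw$screen_files, function(p)
      if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p), "")
  }
  do.call(funnel_config, raw)
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               marker)
    stop(sprintf("funnel stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the candidate-gene funnel
#'
#' Executes, in order: proteome motif scan; deduplicating union of the
#' screen gene lists; intersection of the union with the polyproline gene
#' set; high-dependence filtering; functional categorisation; and (when a
#' regulon and promoters are configured) direct-target calling and overlap
#' with the tolerance union. All outputs are tidy TSV files under
#' `config$out_dir`; the returned report records, per stage, the input and
#' output sizes and the output file. Identical configuration and inputs
#' give byte-identical outputs.
#'
#' @param config A `run_config` from [funnel_config()] /
#'   [read_run_config()].
#' @return Data frame (the funnel report) with columns `stage`, `n_in`,
#'   `n_out`, `file`; also written to `funnel.tsv`. Attribute `results`
#'   carries the in-memory stage objects.
#' @export
run_funnel <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  results <- list()
  add <- function(stage, n_in, n_out, file) {
    # file names are recorded relative to out_dir so identical runs in
    # different directories produce byte-identical reports
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, file = basename(file),
      stringsAsFactors = FALSE)
  }

  # 1. motif scan
  profiles <- .stage("scan", out_dir, {
    seqs <- read_protein_fasta(config$proteome_fasta)
    scan_proteome(seqs, min_len = config$min_run_len,
                  min_multi_runs = config$min_multi_runs,
                  min_long_run = config$min_long_run)
  })
  census <- motif_census(profiles)
  write_motif_tables(profiles, census,
                     file.path(out_dir, "profiles.tsv"),
                     file.path(out_dir, "census.tsv"))
  add("scan", census$n_proteins_scanned, census$n_with_any_run,
      file.path(out_dir, "profiles.tsv"))
  results$profiles <- profiles
  results$census <- census

  # 2. screen union
  alias_map <- if (!is.null(config$alias_file))
    read_alias_map(config$alias_file) else NULL
  screens <- .stage("union", out_dir, {
    lapply(config$screen_files, load_gene_list, alias_map = alias_map)
  })
  tolerance <- consistency_union(screens, name = "tolerance")
  add("union", sum(vapply(screens, length, 1L)), length(tolerance),
      file.path(out_dir, "funnel.tsv"))
  results$screens <- screens
  results$tolerance <- tolerance

  # 3. intersect with polyproline genes
  polypro <- gene_set(profiles$protein_id[profiles$n_runs > 0L],
                      name = "polyproline", provenance = "motif scan")
  common <- gene_intersect(tolerance, polypro, name = "common")
  add("intersect", length(tolerance), length(common),
      file.path(out_dir, "funnel.tsv"))
  results$common <- common

  # 4. high-dependence filter
  highdep <- filter_high_dependence(common, profiles, name = "high_dependence")
  add("high_dependence", length(common), length(highdep),
      file.path(out_dir, "funnel.tsv"))
  results$highdep <- highdep

  # 5. categorisation
  if (!is.null(config$annotation_file)) {
    ann <- .stage("categorize", out_dir,
                  read_annotation_map(config$annotation_file))
    categories <- categorize_genes(common, ann)
    utils::write.table(categories, file.path(out_dir, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add("categorize", length(common), nrow(categories),
        file.path(out_dir, "categories.tsv"))
    results$categories <- categories
  }

  # 6. regulon direct-target calling and tolerance overlap
  if (!is.null(config$regulon_file) && !is.null(config$promoter_fasta)) {
    reg <- .stage("regulon", out_dir, {
      table <- read_regulon_table(config$regulon_file)
      promoters <- read_promoter_fasta(config$promoter_fasta,
                                       window = config$promoter_window)
      pattern <- consensus_pattern(config$consensus,
                                   both_strands = config$both_strands)
      classify_direct_targets(table, promoters, pattern)
    })
    utils::write.table(reg, file.path(out_dir, "regulon_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- overlap_with_tolerance(reg, tolerance)
    ov_df <- data.frame(
      quantity = c("n_targets", "n_direct", "n_targets_in_tolerance",
                   "n_direct_in_tolerance"),
      value = c(ov$n_targets, ov$n_direct, ov$n_targets_in_tolerance,
                ov$n_direct_in_tolerance))
    utils::write.table(ov_df, file.path(out_dir, "overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("regulon_direct", ov$n_targets, ov$n_direct,
        file.path(out_dir, "regulon_annotated.tsv"))
    add("regulon_overlap", ov$n_targets_in_tolerance,
        ov$n_direct_in_tolerance, file.path(out_dir, "overlap.tsv"))
    results$regulon <- reg
    results$overlap <- ov
  }

  report <- do.call(rbind, report)
  utils::write.table(report, file.path(out_dir, "funnel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(report, "results") <- results
  report
}

#' Run the quantification reports
#'
#' Produces one tidy TSV per configured analysis: delta-delta-Cq relative
#' expression (`relative_expression.tsv`), RFU-based relative protein
#' abundance (`abundance.tsv`), growth variables per curve (`growth.tsv`),
#' survival percentages (`survival.tsv`), and the translation-efficiency
#' percent-difference table (`te_percent.tsv`), which always includes the
#' packaged worked-example row evaluated from the bundled fixture (see
#' [ume6_te_example()]).
#'
#' @param config A `run_config`; any of `cq_file` (columns sample, gene,
#'   replicate, cq), `plate_file` (sample, od600, fi), `growth_file`
#'   (label, time, od) and `survival_file` (label, time, cfu) may be set.
#'   `cq_file` requires `calibrator_sample`.
#' @return Named list of the tables written.
#' @export
run_quant_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  if (!is.null(config$cq_file)) {
    cq <- utils::read.csv(config$cq_file, stringsAsFactors = FALSE)
    if (is.null(config$calibrator_sample)) {
      stop("quant stage 'expression' failed: calibrator_sample not configured")
    }
    targets <- setdiff(unique(cq$gene), config$reference_gene)
    expr <- relative_expression(cq, targets,
                                reference_gene = config$reference_gene,
                                calibrator_sample = config$calibrator_sample,
                                efficiency = config$efficiency)
    utils::write.table(expr, file.path(out_dir, "relative_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$expression <- expr
  }

  if (!is.null(config$plate_file)) {
    plate <- utils::read.csv(config$plate_file, stringsAsFactors = FALSE)
    rfus <- stats::setNames(rfu(plate$fi, plate$od600), plate$sample)
    cal <- if (!is.null(config$calibrator_sample) &&
               config$calibrator_sample %in% names(rfus))
      config$calibrator_sample else plate$sample[1L]
    ab <- relative_abundance(rfus, cal)
    utils::write.table(ab, file.path(out_dir, "abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$abundance <- ab
  }

  if (!is.null(config$growth_file)) {
    g <- utils::read.csv(config$growth_file, stringsAsFactors = FALSE)
    rows <- lapply(split(g, g$label), function(d) {
      d <- d[order(d$time), ]
      gv <- growth_variables(d$time, d$od,
                             window_size = config$growth_window)
      data.frame(label = d$label[1L], lag = gv$lag, rate = gv$rate,
                 efficiency = gv$efficiency,
                 flags = paste(gv$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    gt <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.table(gt, file.path(out_dir, "growth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$growth <- gt
  }

  if (!is.null(config$survival_file)) {
    s <- utils::read.csv(config$survival_file, stringsAsFactors = FALSE)
    rows <- lapply(split(s, s$label), function(d) {
      d <- d[order(d$time), ]
      sr <- survival_rate(d$time, d$cfu)
      cbind(label = d$label[1L], sr, stringsAsFactors = FALSE)
    })
    st <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    utils::write.table(st, file.path(out_dir, "survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$survival <- st
  }

  ex <- ume6_te_example()
  te_tab <- data.frame(
    comparison = "UME6 worked example (overexpressor vs control, acid stress)",
    te_control = ex$te_induction_ctrl,
    te_overexpressor = ex$te_induction_over,
    stress_ratio = ex$stress_ratio,
    percent_gain = ex$percent_gain,
    stringsAsFactors = FALSE)
  utils::write.table(te_tab, file.path(out_dir, "te_percent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$te <- te_tab
  out
}
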