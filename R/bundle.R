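# A full synthetic study bundle: proteome + screens + alias map +
# annotations + regulon with promoters, all with recorded truth, sized by
# default to the candidate funnel this pipeline was built around
# (screens 216/650/409 -> union 1031 -> 85 polyproline -> 17 high
# dependence; regulon 1481 targets / 170 direct / 176 and 24 overlaps).

#' Simulate a complete funnel bundle with planted truth
#'
#' Generates, from one master seed, every input the candidate funnel
#' consumes: a proteome in which exactly `n_polyproline` proteins carry
#' polyproline runs (of which `n_common` lie inside the screen union and
#' `n_common_high` of those are high-dependence), three overlapping screen
#' gene lists with a planted union size, an alias map (a subset of genes
#' get standard-style names used in the written screen files), a functional
#' annotation map for the common genes, and a TF regulon whose direct
#' targets and tolerance overlaps are planted exactly.
#'
#' @param seed Master seed; all sub-generators derive their seeds from it.
#' @param universe_size Genes in the synthetic genome.
#' @param screen_regions Seven Venn region sizes (see [simulate_screens()]);
#'   the default plants screens of sizes 216, 650 and 409 with union 1031.
#' @param n_polyproline Proteins with at least one polyproline run.
#' @param n_common Polyproline genes inside the screen union.
#' @param n_common_high High-dependence genes among the common ones.
#' @param n_targets,n_direct Regulon targets and planted direct targets.
#' @param n_targets_in_tol,n_direct_in_tol Planted overlaps between the
#'   regulon (all targets / direct targets) and the screen union.
#' @param promoter_len Promoter length for the regulon (bp).
#' @param pattern Consensus pattern for direct-target planting/calling.
#' @param n_aliases Genes given standard-style alias names.
#' @return List with `proteome`, `screens`, `alias_map`, `annotations`,
#'   `regulon`, `promoters`, and `truth` (all planted counts and
#'   memberships, plus the master seed).
#' @export
simulate_funnel_bundle <- function(seed,
                                   universe_size = 6000L,
                                   screen_regions = c(n1 = 66L, n2 = 496L,
                                                      n3 = 275L, n12 = 60L,
                                                      n13 = 40L, n23 = 44L,
                                                      n123 = 50L),
                                   n_polyproline = 558L,
                                   n_common = 85L,
                                   n_common_high = 17L,
                                   n_targets = 1481L,
                                   n_direct = 170L,
                                   n_targets_in_tol = 176L,
                                   n_direct_in_tol = 24L,
                                   promoter_len = 300L,
                                   pattern = consensus_pattern(),
                                   n_aliases = 200L) {
  stopifnot(n_common <= n_polyproline, n_common_high <= n_common,
            n_direct <= n_targets, n_direct_in_tol <= n_targets_in_tol,
            n_direct_in_tol <= n_direct,
            n_targets_in_tol <= n_targets)
  universe <- sprintf("YSG%04d", seq_len(universe_size))
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 6L))

  screens <- simulate_screens(universe, screen_regions, seed = sub[1L])
  union_ids <- screens$truth$union_ids
  outside <- setdiff(universe, union_ids)
  if (n_polyproline - n_common > length(outside)) {
    stop("universe too small for the requested polyproline census")
  }

  high_labels <- c("2x3P", "1x4P", "3x3P", "1x5P", "2x3P+1x4P", "1x6P")
  labels <- withr::with_seed(sub[2L], {
    common <- sample(union_ids, n_common)
    common_high <- common[seq_len(n_common_high)]
    common_low <- setdiff(common, common_high)
    out_pp <- sample(outside, n_polyproline - n_common)
    n_out_high <- round(length(out_pp) * 0.3)
    lab <- c(
      stats::setNames(sample(high_labels, n_common_high, replace = TRUE),
                      common_high),
      stats::setNames(rep("1x3P", length(common_low)), common_low),
      stats::setNames(sample(high_labels, n_out_high, replace = TRUE),
                      out_pp[seq_len(n_out_high)]),
      stats::setNames(rep("1x3P", length(out_pp) - n_out_high),
                      out_pp[-seq_len(n_out_high)])
    )
    lab
  })
  common_ids <- sort(names(labels)[names(labels) %in% union_ids])
  common_high_ids <- sort(intersect(
    common_ids, names(labels)[labels %in% high_labels]))

  proteome <- simulate_proteome(ids = universe, labels = labels,
                                seed = sub[3L])

  # regulon: planted overlap with the tolerance union
  reg_ids <- withr::with_seed(sub[4L], {
    t_in <- sample(union_ids, n_targets_in_tol)
    t_out <- sample(outside, n_targets - n_targets_in_tol)
    d_in <- t_in[seq_len(n_direct_in_tol)]
    d_out <- t_out[seq_len(n_direct - n_direct_in_tol)]
    list(targets = c(t_in, t_out), direct = c(d_in, d_out))
  })
  regulon <- simulate_regulon(reg_ids$targets, reg_ids$direct,
                              promoter_len = promoter_len, pattern = pattern,
                              seed = sub[5L])

  # alias map and annotations
  categories <- c("chromatin remodeling and transcription", "RNA processing",
                  "protein modification", "trafficking and sorting",
                  "signal transduction", "cytoskeleton and morphogenesis",
                  "cell wall", "metabolism", "mitochondrial function")
  aa <- withr::with_seed(sub[6L], {
    aliased <- sample(universe, n_aliases)
    alias_map <- stats::setNames(aliased, sprintf("STD%03d",
                                                  seq_len(n_aliases)))
    n_unann <- min(3L, length(common_ids))
    annotated <- utils::head(common_ids, length(common_ids) - n_unann)
    ann <- lapply(annotated, function(g)
      sample(categories, sample(1:2, 1L)))
    names(ann) <- annotated
    list(alias_map = alias_map, ann = ann)
  })
  ann_truth <- table(unlist(aa$ann, use.names = FALSE))
  n_unannotated <- length(common_ids) - length(aa$ann)

  truth <- list(
    seed = seed,
    screen_sizes = unname(screens$truth$set_sizes),
    union_size = screens$truth$union_size,
    n_polyproline = n_polyproline,
    n_common = length(common_ids),
    n_common_high = length(common_high_ids),
    common_ids = common_ids,
    common_high_ids = common_high_ids,
    census = proteome$truth$census,
    n_targets = n_targets,
    n_direct = n_direct,
    n_targets_in_tol = n_targets_in_tol,
    n_direct_in_tol = n_direct_in_tol,
    direct_ids = regulon$truth$direct_ids,
    category_counts = stats::setNames(as.integer(ann_truth),
                                      names(ann_truth)),
    n_unannotated = n_unannotated
  )
  list(proteome = proteome$sequences,
       screens = screens$sets,
       alias_map = aa$alias_map,
       annotations = aa$ann,
       regulon = regulon$regulon,
       promoters = regulon$promoters,
       pattern = if (is.character(pattern)) consensus_pattern(pattern)
                 else pattern,
       truth = truth)
}

#' Write a funnel bundle to disk as plain-text pipeline inputs
#'
#' Serialises every component of [simulate_funnel_bundle()] in the formats
#' the pipeline reads: proteome and promoter FASTA, one gene list per
#' screen (identifiers written under their alias where one exists, so the
#' funnel exercises alias resolution), alias and annotation TSV, regulon
#' TSV, and the truth as a JSON sidecar.
#'
#' @param bundle Output of [simulate_funnel_bundle()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths (invisibly).
#' @export
write_funnel_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(dir, "proteome.fa"),
    screen1 = file.path(dir, "screen1.txt"),
    screen2 = file.path(dir, "screen2.txt"),
    screen3 = file.path(dir, "screen3.txt"),
    aliases = file.path(dir, "aliases.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    regulon = file.path(dir, "regulon.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    truth = file.path(dir, "truth.json")
  )
  .write_fasta(bundle$proteome, paths[["proteome"]])
  # reverse map: canonical -> alias; screens written under aliases
  rev_map <- stats::setNames(names(bundle$alias_map),
                             unname(bundle$alias_map))
  for (i in 1:3) {
    ids <- bundle$screens[[i]]$ids
    shown <- ifelse(ids %in% names(rev_map), rev_map[ids], ids)
    writeLines(shown, paths[[paste0("screen", i)]])
  }
  utils::write.table(
    data.frame(alias = names(bundle$alias_map),
               canonical = unname(bundle$alias_map)),
    paths[["aliases"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ann_df <- data.frame(
    gene = rep(names(bundle$annotations),
               lengths(bundle$annotations)),
    category = unlist(bundle$annotations, use.names = FALSE))
  utils::write.table(ann_df, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$regulon, paths[["regulon"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_fasta(bundle$promoters, paths[["promoters"]])
  jsonlite::write_json(
    bundle$truth[c("seed", "screen_sizes", "union_size", "n_polyproline",
                   "n_common", "n_common_high", "n_targets", "n_direct",
                   "n_targets_in_tol", "n_direct_in_tol")],
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# deterministic FASTA writer (60-column wrap)
.write_fasta <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
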