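# Synthetic-data generators with recorded ground truth: stand-ins for the
# proteome database, the three acid-sensitivity deletion screens, the
# TF-target table with promoters, and the plate/qPCR instruments. Every
# generator takes an explicit seed and returns its truth alongside the data.

.aa_background <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1L]]  # 19 aa, no P

#' Simulate a proteome with planted polyproline patterns
#'
#' Generates protein sequences in which polyproline runs appear only where
#' planted, so the pattern census of the output is known exactly. By
#' default the background alphabet excludes proline entirely; with
#' `background_p_freq > 0` proline occurs spontaneously at that frequency
#' ("realistic" mode) and the recorded truth is recomputed from the
#' generated sequences rather than from the planting plan.
#'
#' @param n_proteins Number of proteins (ignored when `ids` given).
#' @param pattern_spec Named integer vector, pattern label to number of
#'   proteins, e.g. `c("2x3P" = 10, "1x4P" = 7)`; labels as in
#'   [make_pattern_label()]. Proteins are assigned labels at random unless
#'   `labels` pins them.
#' @param background_p_freq Background proline frequency (default 0).
#' @param length_range Min/max protein length (residues).
#' @param seed Integer seed; same seed, same output, byte for byte.
#' @param ids Optional protein ids (character); defaults to `YSG0001`-style
#'   synthetic systematic names.
#' @param labels Optional named character vector id -> pattern label,
#'   overriding the random assignment from `pattern_spec`.
#' @return List with `sequences` (named character vector) and `truth`
#'   (list: `profiles` data frame of planted per-protein labels and
#'   high-dependence flags, `census` as from [motif_census()], `seed`).
#' @export
simulate_proteome <- function(n_proteins, pattern_spec = integer(0),
                              background_p_freq = 0,
                              length_range = c(250L, 550L), seed,
                              ids = NULL, labels = NULL) {
  if (is.null(ids)) ids <- sprintf("YSG%04d", seq_len(n_proteins))
  n_proteins <- length(ids)
  if (is.null(labels)) {
    if (sum(pattern_spec) > n_proteins) {
      stop("pattern_spec requests more planted proteins than n_proteins")
    }
  } else {
    stopifnot(all(names(labels) %in% ids))
  }
  withr::with_seed(seed, {
    if (is.null(labels)) {
      labels <- if (length(pattern_spec)) {
        chosen <- sample(ids, sum(pattern_spec))
        stats::setNames(rep(names(pattern_spec), times = pattern_spec),
                        chosen)
      } else {
        stats::setNames(character(0), character(0))
      }
    }
    seqs <- vapply(ids, function(id) {
      len <- sample(seq(length_range[1L], length_range[2L]), 1L)
      lab <- if (id %in% names(labels)) labels[[id]] else ""
      .build_protein(len, parse_pattern_label(lab), background_p_freq)
    }, "")
  })
  planted <- vapply(ids, function(id)
    if (id %in% names(labels)) labels[[id]] else "", "")
  truth_profiles <- if (background_p_freq > 0) {
    scan_proteome(seqs)  # spontaneous runs possible: recompute truth
  } else {
    data.frame(
      protein_id = ids,
      pattern_label = unname(planted),
      n_runs = vapply(planted, function(l) length(parse_pattern_label(l)), 1L),
      max_run_len = vapply(planted, function(l) {
        r <- parse_pattern_label(l); if (length(r)) max(r) else 0L }, 1L),
      high_dependence = vapply(planted, function(l) {
        r <- parse_pattern_label(l)
        length(r) >= 2L || (length(r) >= 1L && max(r) >= 4L) }, TRUE),
      stringsAsFactors = FALSE
    )
  }
  list(sequences = seqs,
       truth = list(profiles = truth_profiles,
                    census = motif_census(truth_profiles),
                    seed = seed))
}

# One protein: background segments interleaved with planted P-runs, every
# pair of runs separated by at least one non-P residue.
.build_protein <- function(len, run_lengths, background_p_freq) {
  alphabet <- .aa_background
  prob <- NULL
  if (background_p_freq > 0) {
    alphabet <- c(alphabet, "P")
    prob <- c(rep((1 - background_p_freq) / 19, 19), background_p_freq)
  }
  k <- length(run_lengths)
  total_p <- sum(run_lengths)
  n_bg <- len - total_p
  if (k > 0L && n_bg < k - 1L) {
    stop("planted motifs longer than protein allows")
  }
  if (k == 0L) {
    return(paste(sample(alphabet, len, replace = TRUE, prob = prob),
                 collapse = ""))
  }
  # shuffle planted run order (indexing form avoids the sample() scalar trap)
  run_lengths <- run_lengths[sample.int(length(run_lengths))]
  # one guaranteed background residue between consecutive runs; the
  # remaining background is split at random into k+1 segments
  extra <- n_bg - (k - 1L)
  cuts <- sort(sample(0:extra, k, replace = TRUE))
  seg <- diff(c(0L, cuts, extra))             # k+1 segments summing to extra
  seg_len <- seg + c(0L, rep(1L, k - 1L), 0L) # interior get the guard residue
  pieces <- character(2L * k + 1L)
  for (i in seq_len(k + 1L)) {
    pieces[2L * i - 1L] <- paste(
      sample(alphabet, seg_len[i], replace = TRUE, prob = prob),
      collapse = "")
  }
  for (i in seq_len(k)) {
    pieces[2L * i] <- strrep("P", run_lengths[i])
  }
  paste(pieces, collapse = "")
}

#' Simulate three overlapping deletion-screen gene lists
#'
#' Draws three gene sets from a universe with every one of the seven Venn
#' regions planted at a requested size, so set sizes, all pairwise overlaps
#' and the union size are known exactly.
#'
#' @param universe Either an integer (universe size; synthetic ids are
#'   generated) or a character vector of gene ids.
#' @param regions Named integer vector with the seven Venn region sizes:
#'   `n1`, `n2`, `n3` (exclusive regions), `n12`, `n13`, `n23` (pairwise
#'   only) and `n123` (triple overlap).
#' @param seed Integer seed.
#' @param names Names for the three screens.
#' @return List with `sets` (list of three [gene_set()]s) and `truth`
#'   (list: `set_sizes`, `pairwise` overlaps, `union_size`, `union_ids`,
#'   `seed`).
#' @export
simulate_screens <- function(universe, regions, seed,
                             names = c("screen1", "screen2", "screen3")) {
  need <- c("n1", "n2", "n3", "n12", "n13", "n23", "n123")
  if (!all(need %in% base::names(regions))) {
    stop("regions must name all seven Venn regions: ",
         paste(need, collapse = ", "))
  }
  regions <- regions[need]
  if (any(regions < 0)) stop("region sizes must be non-negative")
  if (is.numeric(universe) && length(universe) == 1L) {
    universe <- sprintf("YSG%04d", seq_len(universe))
  }
  total <- sum(regions)
  if (total > length(universe)) {
    stop("Venn regions exceed universe size (", total, " > ",
         length(universe), ")")
  }
  withr::with_seed(seed, {
    picked <- sample(universe, total)
  })
  idx <- cumsum(regions)
  part <- mapply(function(from, to) picked[seq(from, length.out = to)],
                 c(1L, utils::head(idx, -1L) + 1L), regions,
                 SIMPLIFY = FALSE)
  base::names(part) <- need
  s1 <- c(part$n1, part$n12, part$n13, part$n123)
  s2 <- c(part$n2, part$n12, part$n23, part$n123)
  s3 <- c(part$n3, part$n13, part$n23, part$n123)
  sets <- mapply(gene_set, list(s1, s2, s3), names,
                 MoreArgs = list(provenance = "synthetic screen"),
                 SIMPLIFY = FALSE)
  truth <- list(
    set_sizes = stats::setNames(c(length(s1), length(s2), length(s3)), names),
    pairwise = c(s12 = length(part$n12) + length(part$n123),
                 s13 = length(part$n13) + length(part$n123),
                 s23 = length(part$n23) + length(part$n123)),
    union_size = total,
    union_ids = sort(picked),
    seed = seed
  )
  list(sets = sets, truth = truth)
}

#' Simulate a TF regulon with promoters and planted consensus sites
#'
#' Non-direct targets receive promoters rejection-sampled to contain zero
#' consensus matches on either scanned strand; direct targets get one
#' planted site at a random position, in a random orientation when both
#' strands are scanned.
#'
#' @param target_ids Character vector of target gene ids.
#' @param direct_ids Subset of `target_ids` to plant as direct targets.
#' @param promoter_len Promoter length in bp (default 300).
#' @param pattern A [consensus_pattern()] or IUPAC string.
#' @param tf TF identifier for the table.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling attempts per promoter before
#'   giving up with an error advising longer promoters.
#' @return List with `regulon` (data frame `tf`, `target`, `evidence` all
#'   `"documented"`), `promoters` (named character vector) and `truth`
#'   (list: `direct_ids`, `sites` data frame of planted positions/strands,
#'   `seed`).
#' @export
simulate_regulon <- function(target_ids, direct_ids, promoter_len = 300L,
                             pattern = consensus_pattern(), tf = "UME6",
                             seed, max_attempts = 100L) {
  if (is.character(pattern)) pattern <- consensus_pattern(pattern)
  stopifnot(all(direct_ids %in% target_ids))
  plen <- nchar(pattern$iupac)
  if (plen > promoter_len) stop("pattern does not fit in promoter")
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::IUPAC_CODE_MAP
  withr::with_seed(seed, {
    clean_promoter <- function() {
      for (i in seq_len(max_attempts)) {
        s <- paste(sample(bases, promoter_len, replace = TRUE), collapse = "")
        if (nrow(scan_consensus(s, pattern)) == 0L) return(s)
      }
      stop("could not sample a match-free promoter after ", max_attempts,
           " attempts; use longer promoters or a more specific pattern")
    }
    instantiate <- function() {
      chars <- strsplit(pattern$iupac, "", fixed = TRUE)[[1L]]
      paste(vapply(chars, function(ch) {
        opts <- strsplit(code[[ch]], "")[[1L]]
        sample(opts, 1L)
      }, ""), collapse = "")
    }
    promoters <- character(length(target_ids))
    names(promoters) <- target_ids
    sites <- data.frame(target = character(0), position = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    for (g in target_ids) {
      p <- clean_promoter()
      if (g %in% direct_ids) {
        pos <- sample(promoter_len - plen + 1L, 1L)
        site <- instantiate()
        strand <- "+"
        if (pattern$both_strands && sample(c(TRUE, FALSE), 1L)) {
          site <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(site)))
          strand <- "-"
        }
        substring(p, pos, pos + plen - 1L) <- site
        sites <- rbind(sites, data.frame(target = g, position = pos,
                                         strand = strand,
                                         stringsAsFactors = FALSE))
      }
      promoters[[g]] <- p
    }
  })
  regulon <- data.frame(tf = tf, target = target_ids, evidence = "documented",
                        stringsAsFactors = FALSE)
  list(regulon = regulon, promoters = promoters,
       truth = list(direct_ids = sort(direct_ids), sites = sites, seed = seed))
}

#' Simulate a three-phase growth curve
#'
#' Flat at `od0` until `lag`, then a logistic rise toward `capacity` with
#' maximum specific growth rate `rate`; multiplicative log-normal noise
#' mimics plate-reader error.
#'
#' @param lag Lag time in hours.
#' @param rate Maximum specific growth rate per hour.
#' @param od0 Inoculation density (default 0.05, a typical liquid-assay
#'   starting OD600).
#' @param capacity Carrying capacity (default 2.0 OD600).
#' @param noise_sd Standard deviation of log-scale multiplicative noise
#'   (0 = noiseless).
#' @param sampling_dt Sampling interval in hours (default 0.25, a
#'   plate-reader cadence).
#' @param horizon Total duration in hours; defaults to lag plus the time
#'   for the logistic to reach 99 percent of capacity.
#' @param seed Integer seed.
#' @return List with `data` (data frame `time`, `od`) and `truth` (list of
#'   the generating parameters plus `seed`).
#' @export
simulate_growth <- function(lag, rate, od0 = 0.05, capacity = 2,
                            noise_sd = 0, sampling_dt = 0.25, horizon = NULL,
                            seed = 1L) {
  stopifnot(lag >= 0, rate >= 0, od0 > 0, capacity > od0, sampling_dt > 0)
  if (is.null(horizon)) {
    horizon <- if (rate > 0) {
      lag + (log(99) + log(capacity / od0 - 1)) / rate + 2
    } else 24
  }
  times <- seq(0, horizon, by = sampling_dt)
  od_true <- ifelse(
    times < lag | rate == 0,
    od0,
    capacity * od0 / (od0 + (capacity - od0) * exp(-rate * (times - lag)))
  )
  od <- od_true
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      od <- od_true * exp(stats::rnorm(length(times), 0, noise_sd))
    })
  }
  list(data = data.frame(time = times, od = od),
       truth = list(lag = lag, rate = rate, od0 = od0, capacity = capacity,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate an exponential-death CFU survival series
#'
#' @param death_rate Death rate per hour (log-linear decline).
#' @param cfu0 Starting CFU per mL.
#' @param times Sampling times in hours (first must be 0).
#' @param noise_sd Log-scale multiplicative noise sd (0 = noiseless; the
#'   time-zero count is left noise-free so percentages stay anchored).
#' @param seed Integer seed.
#' @return List with `data` (data frame `time`, `cfu`) and `truth`.
#' @export
simulate_survival <- function(death_rate, cfu0 = 1e7,
                              times = seq(0, 6, by = 1), noise_sd = 0,
                              seed = 1L) {
  stopifnot(death_rate >= 0, cfu0 > 0, times[1L] == 0)
  cfu <- cfu0 * exp(-death_rate * times)
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      mult <- exp(stats::rnorm(length(times), 0, noise_sd))
      mult[1L] <- 1
      cfu <- cfu * mult
    })
  }
  list(data = data.frame(time = times, cfu = cfu),
       truth = list(death_rate = death_rate, cfu0 = cfu0, seed = seed))
}

#' Simulate qPCR Cq tables from planted expression folds
#'
#' For each (sample, gene) with planted fold f relative to the calibrator,
#' the target Cq is `cq_target_base - log(f)/log(efficiency)` plus Gaussian
#' cycle noise per replicate; the reference gene sits at a constant base Cq
#' in every sample, so the recovered delta-delta-Cq level estimates f.
#'
#' @param folds Data frame with columns `sample`, `gene`, `fold`
#'   (calibrator rows must have fold 1).
#' @param calibrator_sample Calibrator sample id.
#' @param reference_gene Reference gene id added to every sample.
#' @param cq_target_base,cq_ref_base Base Cq of targets and reference.
#' @param noise_sd Per-measurement Cq noise sd in cycles (default 0.1).
#' @param n_replicates Technical replicates per (sample, gene) (default 3).
#' @param efficiency Amplification efficiency (default 2).
#' @param seed Integer seed.
#' @return List with `cq` (data frame `sample`, `gene`, `replicate`, `cq`)
#'   and `truth` (the folds plus the generator settings).
#' @export
simulate_expression <- function(folds, calibrator_sample,
                                reference_gene = "ACT1",
                                cq_target_base = 22, cq_ref_base = 16,
                                noise_sd = 0.1, n_replicates = 3L,
                                efficiency = 2, seed = 1L) {
  stopifnot(is.data.frame(folds),
            all(c("sample", "gene", "fold") %in% names(folds)),
            all(folds$fold > 0))
  cal <- folds[folds$sample == calibrator_sample, ]
  if (nrow(cal) == 0L) stop("calibrator sample absent from folds")
  if (any(abs(cal$fold - 1) > 1e-12)) {
    stop("calibrator rows must have fold exactly 1")
  }
  samples <- unique(folds$sample)
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(folds))) {
      true_cq <- cq_target_base - log(folds$fold[i]) / log(efficiency)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = folds$sample[i], gene = folds$gene[i],
        replicate = seq_len(n_replicates),
        cq = true_cq + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
    for (s in samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = reference_gene, replicate = seq_len(n_replicates),
        cq = cq_ref_base + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  })
  cq <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(cq = cq,
       truth = list(folds = folds, calibrator = calibrator_sample,
                    reference_gene = reference_gene, noise_sd = noise_sd,
                    n_replicates = n_replicates, efficiency = efficiency,
                    seed = seed))
}

#' Simulate plate fluorescence readings from planted protein abundances
#'
#' FI = abundance x OD600 x fi_per_unit x multiplicative noise, so
#' RFU = FI/OD600 recovers abundance x fi_per_unit.
#'
#' @param abundance Named numeric vector, sample -> true relative abundance.
#' @param od600 Named numeric vector of OD600 per sample (same names), or a
#'   single value recycled.
#' @param fi_per_unit Instrument gain (FI per abundance unit per OD).
#' @param noise_sd Log-scale multiplicative noise sd.
#' @param seed Integer seed.
#' @return List with `plate` (data frame `sample`, `od600`, `fi`) and
#'   `truth`.
#' @export
simulate_fluorescence <- function(abundance, od600 = 0.8, fi_per_unit = 1000,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(is.numeric(abundance), !is.null(names(abundance)),
            all(abundance > 0))
  if (length(od600) == 1L) {
    od600 <- stats::setNames(rep(od600, length(abundance)), names(abundance))
  }
  fi <- abundance * od600[names(abundance)] * fi_per_unit
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      fi <- fi * exp(stats::rnorm(length(fi), 0, noise_sd))
    })
  }
  list(plate = data.frame(sample = names(abundance),
                          od600 = unname(od600[names(abundance)]),
                          fi = unname(fi), stringsAsFactors = FALSE),
       truth = list(abundance = abundance, fi_per_unit = fi_per_unit,
                    noise_sd = noise_sd, seed = seed))
}
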