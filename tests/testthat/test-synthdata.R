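test_that("planted proteome censuses are recovered exactly", {
  spec <- c("2x3P" = 10L, "1x4P" = 7L, "1x3P" = 20L)
  sim <- simulate_proteome(300, pattern_spec = spec, seed = 42)
  cen <- motif_census(scan_proteome(sim$sequences))
  got <- stats::setNames(cen$counts$count, cen$counts$pattern_label)
  expect_equal(got[names(spec)], spec, ignore_attr = TRUE)
  expect_equal(cen$n_with_any_run, sum(spec))
  expect_equal(cen$n_high_dependence, 17L)
  expect_equal(cen$n_proteins_scanned, 300L)
  # truth sidecar agrees with the scan
  expect_equal(cen$n_with_any_run, sim$truth$census$n_with_any_run)
  none <- simulate_proteome(50, seed = 1)
  expect_equal(motif_census(scan_proteome(none$sequences))$n_with_any_run, 0L)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_proteome(40, pattern_spec = c("2x3P" = 5L), seed = 9)
  b <- simulate_proteome(40, pattern_spec = c("2x3P" = 5L), seed = 9)
  expect_identical(a, b)
  c <- simulate_proteome(40, pattern_spec = c("2x3P" = 5L), seed = 10)
  expect_false(identical(a$sequences, c$sequences))
  r1 <- simulate_regulon(sprintf("G%02d", 1:20), sprintf("G%02d", 1:4),
                         seed = 3)
  r2 <- simulate_regulon(sprintf("G%02d", 1:20), sprintf("G%02d", 1:4),
                         seed = 3)
  expect_identical(r1, r2)
  g1 <- simulate_growth(lag = 5, rate = 0.3, noise_sd = 0.05, seed = 8)
  g2 <- simulate_growth(lag = 5, rate = 0.3, noise_sd = 0.05, seed = 8)
  expect_identical(g1, g2)
})

test_that("infeasible planting requests fail loudly", {
  expect_error(simulate_proteome(5, pattern_spec = c("1x3P" = 9L), seed = 1),
               "more planted")
  expect_error(simulate_proteome(1, pattern_spec = c("1x300P" = 1L),
                                 length_range = c(10L, 12L), seed = 1),
               "longer than protein")
})

test_that("screen generator plants exact Venn structure", {
  regions <- c(n1 = 66L, n2 = 496L, n3 = 275L, n12 = 60L, n13 = 40L,
               n23 = 44L, n123 = 50L)
  sim <- simulate_screens(3000, regions, seed = 12)
  sizes <- vapply(sim$sets, length, 1L)
  expect_equal(unname(sizes), c(216L, 650L, 409L))
  u <- consistency_union(sim$sets)
  expect_equal(length(u), 1031L)
  expect_equal(sim$truth$union_size, 1031L)
  # pairwise truths match direct intersection
  expect_equal(length(gene_intersect(sim$sets[[1]], sim$sets[[2]])),
               unname(sim$truth$pairwise["s12"]))
  # disjoint and identical degenerate specs
  disjoint <- simulate_screens(100, c(n1 = 10L, n2 = 20L, n3 = 5L, n12 = 0L,
                                      n13 = 0L, n23 = 0L, n123 = 0L),
                               seed = 2)
  expect_equal(length(consistency_union(disjoint$sets)), 35L)
  same <- simulate_screens(100, c(n1 = 0L, n2 = 0L, n3 = 0L, n12 = 0L,
                                  n13 = 0L, n23 = 0L, n123 = 12L), seed = 2)
  expect_equal(length(consistency_union(same$sets)), 12L)
  expect_error(simulate_screens(10, c(n1 = 5L, n2 = 5L, n3 = 5L, n12 = 0L,
                                      n13 = 0L, n23 = 0L, n123 = 0L),
                                seed = 1), "exceed")
})

test_that("regulon generator round-trips through direct-target calling", {
  ids <- sprintf("G%03d", 1:100)
  sim <- simulate_regulon(ids, ids[1:17], seed = 99)
  out <- classify_direct_targets(sim$regulon, sim$promoters,
                                 consensus_pattern())
  called <- sort(out$target[out$evidence == "direct_by_consensus"])
  expect_equal(called, sim$truth$direct_ids)
  expect_equal(attr(out, "report")$n_direct, 17L)
  # planted sites are found at their planted positions
  for (i in seq_len(nrow(sim$truth$sites))) {
    site <- sim$truth$sites[i, ]
    hits <- scan_consensus(sim$promoters[[site$target]], consensus_pattern())
    expect_true(any(hits$position == site$position &
                      hits$strand == site$strand))
  }
  # minus-strand plants need both-strand scanning to be found
  minus <- sim$truth$sites[sim$truth$sites$strand == "-", ]
  expect_gt(nrow(minus), 0L)
  one <- minus$target[1]
  expect_equal(nrow(scan_consensus(
    sim$promoters[[one]],
    consensus_pattern(both_strands = FALSE))), 0L)
  # no planted direct targets -> no direct calls
  none <- simulate_regulon(ids[1:10], character(0), seed = 7)
  out0 <- classify_direct_targets(none$regulon, none$promoters,
                                  consensus_pattern())
  expect_equal(attr(out0, "report")$n_direct, 0L)
})

test_that("planted qPCR folds are recovered by delta-delta-Cq", {
  folds <- data.frame(sample = c("cal", "s1", "s2", "s3"),
                      gene = "BUD21", fold = c(1, 3.5, 4.8, 0.5))
  sim <- simulate_expression(folds, "cal", noise_sd = 0, seed = 4)
  out <- relative_expression(sim$cq, "BUD21", "ACT1", "cal")
  expect_equal(out$level[match(folds$sample, out$sample)], folds$fold,
               tolerance = 1e-9)
  # planted fold 1 everywhere -> all levels 1 (noiseless)
  ones <- data.frame(sample = c("cal", "a", "b"), gene = "G", fold = 1)
  sim1 <- simulate_expression(ones, "cal", noise_sd = 0, seed = 4)
  expect_equal(relative_expression(sim1$cq, "G", "ACT1", "cal")$level,
               rep(1, 3))
  expect_error(simulate_expression(
    data.frame(sample = "cal", gene = "G", fold = 2), "cal"), "fold exactly 1")
})

test_that("planted fluorescence abundances survive the RFU chain", {
  ab <- c(ctrl = 1, over = 1.6)
  sim <- simulate_fluorescence(ab, od600 = c(ctrl = 0.8, over = 1.1),
                               noise_sd = 0)
  rfus <- stats::setNames(rfu(sim$plate$fi, sim$plate$od600),
                          sim$plate$sample)
  rel <- relative_abundance(rfus, "ctrl")
  expect_equal(rel$level[rel$sample == "over"], 1.6, tolerance = 1e-9)
})

test_that("the full funnel bundle is internally consistent", {
  b <- simulate_funnel_bundle(seed = 11, universe_size = 800L,
                              screen_regions = c(n1 = 20L, n2 = 60L,
                                                 n3 = 30L, n12 = 8L,
                                                 n13 = 6L, n23 = 5L,
                                                 n123 = 4L),
                              n_polyproline = 60L, n_common = 20L,
                              n_common_high = 6L, n_targets = 50L,
                              n_direct = 10L, n_targets_in_tol = 12L,
                              n_direct_in_tol = 4L, n_aliases = 40L)
  expect_equal(b$truth$union_size, 133L)
  expect_equal(b$truth$n_common, 20L)
  expect_equal(b$truth$n_common_high, 6L)
  expect_length(b$proteome, 800L)
  expect_length(b$promoters, 50L)
  # written twice with the same seed -> byte-identical files
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  p1 <- write_funnel_bundle(b, d1)
  p2 <- write_funnel_bundle(simulate_funnel_bundle(
    seed = 11, universe_size = 800L,
    screen_regions = c(n1 = 20L, n2 = 60L, n3 = 30L, n12 = 8L, n13 = 6L,
                       n23 = 5L, n123 = 4L),
    n_polyproline = 60L, n_common = 20L, n_common_high = 6L,
    n_targets = 50L, n_direct = 10L, n_targets_in_tol = 12L,
    n_direct_in_tol = 4L, n_aliases = 40L), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})
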