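test_that("FASTA parsing concatenates wrapped lines and strips terminators", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A first protein", "PP", "PA", ">B", "MKPPP*"), fa)
  seqs <- read_protein_fasta(fa)
  expect_equal(names(seqs), c("A", "B"))
  expect_equal(unname(seqs[["A"]]), "PPPA")
  expect_equal(unname(seqs[["B"]]), "MKPPP")
  expect_equal(attr(seqs, "terminator"), c(FALSE, TRUE))
  expect_equal(attr(seqs, "description"), c("first protein", ""))
})

test_that("FASTA parsing rejects duplicates and empty records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "MK", ">A", "ML"), fa)
  expect_error(read_protein_fasta(fa), "duplicate")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "MK", ">B", "", ">C", "ML"), fa2)
  expect_error(read_protein_fasta(fa2), "record 2")
  fa3 <- withr::local_tempfile(fileext = ".fa")
  file.create(fa3)
  expect_length(read_protein_fasta(fa3), 0)
})

test_that("FASTA parsing agrees with an independent line-by-line parser", {
  naive_fasta <- function(path) {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
    bounds <- c(idx, length(lines) + 1L)
    seqs <- vapply(seq_along(idx), function(i) {
      toupper(paste(lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)],
                    collapse = ""))
    }, "")
    stats::setNames(sub("\\*$", "", seqs), ids)
  }
  set.seed(101)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    ids <- sprintf("R%02d_%d", seq_len(n), i)
    seqs <- vapply(seq_len(n), function(j) random_protein(sample(5:120, 1)), "")
    fa <- tempfile(fileext = ".fa")
    wrapped <- unlist(lapply(seq_len(n), function(j) {
      s <- seqs[j]
      w <- sample(10:70, 1)
      starts <- seq(1L, nchar(s), by = w)
      c(paste0(">", ids[j]), substring(s, starts, pmin(starts + w - 1L,
                                                       nchar(s))))
    }))
    writeLines(wrapped, fa)
    got <- read_protein_fasta(fa)
    want <- naive_fasta(fa)
    expect_equal(stats::setNames(as.vector(got), names(got)), want)
    unlink(fa)
  }
})

test_that("find_proline_runs returns maximal runs only", {
  expect_equal(find_proline_runs("APPPA"),
               data.frame(start = 2L, length = 3L))
  expect_equal(find_proline_runs("PPPPPP"),
               data.frame(start = 1L, length = 6L))
  expect_equal(find_proline_runs("PPAPPXPPP"),
               data.frame(start = 7L, length = 3L))
  expect_equal(nrow(find_proline_runs("")), 0L)
  expect_equal(nrow(find_proline_runs("MKWW")), 0L)
  expect_error(find_proline_runs("PPP", min_len = 0), "min_len")
})

test_that("run finding matches the brute-force oracle", {
  set.seed(202)
  for (i in 1:300) {
    s <- random_protein(sample(0:80, 1), p_freq = runif(1, 0.05, 0.6))
    for (ml in 1:6) {
      expect_identical(find_proline_runs(s, ml), brute_force_runs(s, ml),
                       info = sprintf("seq %s min_len %d", s, ml))
    }
  }
})

test_that("runs obey concatenation and min_len monotonicity properties", {
  set.seed(303)
  for (i in 1:100) {
    s1 <- random_protein(sample(0:40, 1), p_freq = 0.4)
    s2 <- random_protein(sample(0:40, 1), p_freq = 0.4)
    joined <- find_proline_runs(paste0(s1, "A", s2))
    r1 <- find_proline_runs(s1)
    r2 <- find_proline_runs(s2)
    r2$start <- r2$start + nchar(s1) + 1L
    expect_equal(joined, rbind(r1, r2), ignore_attr = TRUE)
    n_by_minlen <- vapply(1:6, function(ml)
      nrow(find_proline_runs(s1, ml)), 1L)
    expect_true(all(diff(n_by_minlen) <= 0))
  }
})

test_that("high-dependence classification follows the 2-run / 4-long rule", {
  two_runs <- profile_protein("a", "PPPAPPP")
  expect_true(two_runs$high_dependence)
  expect_equal(two_runs$pattern_label, "2x3P")
  one_run <- profile_protein("b", "APPPA")
  expect_false(one_run$high_dependence)
  long_run <- profile_protein("c", "APPPPA")
  expect_true(long_run$high_dependence)
  expect_equal(long_run$pattern_label, "1x4P")
  none <- profile_protein("d", "MKLV")
  expect_false(none$high_dependence)
  expect_equal(none$pattern_label, "")
  expect_equal(none$max_run_len, 0L)
})

test_that("pattern labels are canonical and round-trip", {
  expect_equal(make_pattern_label(c(4, 3, 3)), "2x3P+1x4P")
  expect_equal(make_pattern_label(integer(0)), "")
  expect_equal(parse_pattern_label("2x3P+1x4P"), c(3L, 3L, 4L))
  expect_equal(parse_pattern_label(""), integer(0))
  set.seed(9)
  for (i in 1:50) {
    lens <- sample(3:8, sample(1:5, 1), replace = TRUE)
    expect_equal(parse_pattern_label(make_pattern_label(lens)), sort(lens))
  }
})

test_that("census counts patterns and conserves totals", {
  profs <- rbind(profile_protein("a", "APPPA"),
                 profile_protein("b", "CPPPC"),
                 profile_protein("c", "PPPAPPP"),
                 profile_protein("d", "MKLV"))
  cen <- motif_census(profs)
  expect_equal(cen$counts$count[cen$counts$pattern_label == "1x3P"], 2L)
  expect_equal(cen$counts$count[cen$counts$pattern_label == "2x3P"], 1L)
  expect_equal(cen$n_proteins_scanned, 4L)
  expect_equal(cen$n_with_any_run, 3L)
  expect_equal(cen$n_high_dependence, 1L)
  expect_equal(sum(cen$counts$count), cen$n_with_any_run)
  empty <- motif_census(profs[0, ])
  expect_equal(empty$n_proteins_scanned, 0L)
  expect_equal(empty$n_with_any_run, 0L)
  expect_equal(empty$n_high_dependence, 0L)
})
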