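# Polyproline motif detection and proteome-wide pattern census.

#' Read a protein FASTA file
#'
#' Reads protein sequences, taking the first whitespace-delimited token of
#' each header as the record identifier (systematic name) and the remainder
#' as a free-text description. Sequences are uppercased, wrapped lines are
#' concatenated, and a single trailing stop character (`*`) is stripped and
#' flagged.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of residue strings. Attributes:
#'   `description` (character, per record) and `terminator` (logical, `TRUE`
#'   where a trailing `*` was stripped).
#' @details Records with empty sequences raise an error naming the record
#'   index; duplicated identifiers are an error, since downstream set
#'   arithmetic keys proteins by systematic name.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">YSG0001 some protein", "MKPPP*"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    res <- character(0)
    attr(res, "description") <- character(0)
    attr(res, "terminator") <- logical(0)
    return(res)
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("malformed FASTA header (empty id) at record ",
         which(ids == "")[1L])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in FASTA: ",
         ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(aa))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence at record ", which(empty)[1L], " (", ids[empty][1L], ")")
  }
  term <- grepl("\\*$", seqs)
  seqs[term] <- sub("\\*$", "", seqs[term])
  still_empty <- !nzchar(seqs)
  if (any(still_empty)) {
    stop("empty sequence (terminator only) at record ", which(still_empty)[1L])
  }
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  attr(seqs, "terminator") <- term
  seqs
}

#' Find maximal runs of consecutive prolines
#'
#' Scans one residue string for maximal runs of the letter `P` of length at
#' least `min_len`. A run of length L is reported once, never as overlapping
#' shorter windows, because the downstream dependence classes (two separate
#' 3P motifs versus a single run of four or more prolines) are only coherent
#' under maximal-run semantics. Matching is case-insensitive; any non-P
#' letter, including `X` and `*`, breaks a run.
#'
#' @param residues Amino-acid string (may be empty).
#' @param min_len Minimum run length to report (default 3, the classic
#'   polyproline/3P threshold).
#' @return A data frame with columns `start` (1-based) and `length`, sorted
#'   by start. Zero rows when there is no qualifying run.
#' @examples
#' find_proline_runs("APPPA")          # one run: start 2, length 3
#' find_proline_runs("PPPPPP")         # one maximal run of length 6
#' find_proline_runs("PPAPPXPPP")      # only the trailing PPP qualifies
#' @export
find_proline_runs <- function(residues, min_len = 3L) {
  stopifnot(length(residues) == 1L, is.character(residues))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) {
    stop("min_len must be an integer >= 1")
  }
  if (nchar(residues) == 0L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  r <- rle(chars == "P")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = as.integer(starts[keep]),
             length = as.integer(r$lengths[keep]))
}

#' Canonical pattern label from run lengths
#'
#' Builds the canonical label used for census tabulation: counts of each
#' distinct run length, lengths ascending, joined by `+`, e.g. `"2x3P+1x4P"`
#' for two runs of three prolines and one of four. The empty string denotes
#' a protein with no qualifying run.
#'
#' @param lengths Integer vector of maximal run lengths (possibly empty).
#' @return A single string.
#' @export
make_pattern_label <- function(lengths) {
  if (length(lengths) == 0L) return("")
  tab <- table(factor(sort(as.integer(lengths))))
  paste(sprintf("%dx%sP", as.integer(tab), names(tab)), collapse = "+")
}

#' Parse a pattern label back into run lengths
#'
#' Inverse of [make_pattern_label()]: `"2x3P+1x4P"` becomes `c(3, 3, 4)`.
#'
#' @param label Pattern label string (may be `""`).
#' @return Integer vector of run lengths (ascending).
#' @export
parse_pattern_label <- function(label) {
  stopifnot(length(label) == 1L)
  if (!nzchar(label)) return(integer(0))
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)x([0-9]+)P$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed pattern label: ", label)
  counts <- vapply(m, function(x) as.integer(x[2L]), 1L)
  lens <- vapply(m, function(x) as.integer(x[3L]), 1L)
  sort(rep(lens, counts))
}

#' Profile the polyproline content of one protein
#'
#' @param id Protein identifier (systematic name).
#' @param residues Amino-acid string.
#' @param min_len Minimum run length (default 3).
#' @param min_multi_runs Number of separate runs that flags high eIF5A
#'   dependence (default 2, i.e. at least two separate 3P motifs).
#' @param min_long_run Single-run length that flags high dependence
#'   (default 4, i.e. a PPPP or longer stretch).
#' @return A one-row data frame: `protein_id`, `n_runs`, `run_lengths` and
#'   `run_starts` (comma-joined, starts 1-based), `max_run_len`,
#'   `pattern_label`, `high_dependence`.
#' @export
profile_protein <- function(id, residues, min_len = 3L,
                            min_multi_runs = 2L, min_long_run = 4L) {
  runs <- find_proline_runs(residues, min_len = min_len)
  n <- nrow(runs)
  maxlen <- if (n) max(runs$length) else 0L
  data.frame(
    protein_id = id,
    n_runs = n,
    run_lengths = paste(runs$length, collapse = ","),
    run_starts = paste(runs$start, collapse = ","),
    max_run_len = as.integer(maxlen),
    pattern_label = make_pattern_label(runs$length),
    high_dependence = (n >= min_multi_runs) || (maxlen >= min_long_run),
    stringsAsFactors = FALSE
  )
}

#' Scan a whole proteome for polyproline motifs
#'
#' @param sequences Named character vector of residue strings (e.g. from
#'   [read_protein_fasta()]) or a `Biostrings::AAStringSet`.
#' @inheritParams profile_protein
#' @return A data frame with one row per protein, columns as in
#'   [profile_protein()].
#' @export
scan_proteome <- function(sequences, min_len = 3L,
                          min_multi_runs = 2L, min_long_run = 4L) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by protein id")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate protein ids in proteome")
  }
  rows <- lapply(seq_along(sequences), function(i) {
    profile_protein(names(sequences)[i], sequences[[i]], min_len = min_len,
                    min_multi_runs = min_multi_runs,
                    min_long_run = min_long_run)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- profile_protein("x", "")[0, ]
  }
  out
}

#' Proteome-wide pattern census
#'
#' Tabulates how many proteins carry each polyproline pattern, plus the
#' three totals used in the candidate funnel: proteins scanned, proteins
#' with at least one run, and proteins in the high-dependence class (at
#' least two separate runs, or one run of four or more prolines).
#'
#' @param profiles Profile data frame from [scan_proteome()].
#' @return A list with `counts` (data frame `pattern_label`, `count`,
#'   ordered by label), `n_proteins_scanned`, `n_with_any_run` and
#'   `n_high_dependence`. The pattern counts always sum to `n_with_any_run`.
#' @export
motif_census <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  with_run <- profiles[profiles$n_runs > 0L, , drop = FALSE]
  tab <- table(with_run$pattern_label)
  counts <- data.frame(pattern_label = as.character(names(tab)),
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$pattern_label), , drop = FALSE]
  rownames(counts) <- NULL
  list(
    counts = counts,
    n_proteins_scanned = nrow(profiles),
    n_with_any_run = nrow(with_run),
    n_high_dependence = sum(profiles$high_dependence)
  )
}

#' Write motif profile and census tables as TSV
#'
#' @param profiles Profile data frame from [scan_proteome()].
#' @param census Census list from [motif_census()].
#' @param profile_path,census_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_motif_tables <- function(profiles, census, profile_path, census_path) {
  utils::write.table(profiles, profile_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tot <- data.frame(
    pattern_label = c("__n_proteins_scanned__", "__n_with_any_run__",
                      "__n_high_dependence__"),
    count = c(census$n_proteins_scanned, census$n_with_any_run,
              census$n_high_dependence),
    stringsAsFactors = FALSE
  )
  utils::write.table(rbind(census$counts, tot), census_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(profile_path, census_path))
}
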