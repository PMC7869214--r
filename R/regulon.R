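# Transcription-factor target bookkeeping and direct-target calling by
# promoter consensus scanning (URS1-like sites).

#' Define an IUPAC consensus pattern
#'
#' @param iupac Consensus string over IUPAC nucleotide codes. The default is
#'   the canonical URS1 core bound by Ume6p, `TCGGCGGCT`; URS1 function is
#'   orientation-independent, so both strands are scanned by default.
#' @param both_strands Scan the reverse complement too?
#' @return An object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(iupac = "TCGGCGGCT", both_strands = TRUE) {
  iupac <- toupper(iupac)
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, valid)
  if (length(bad)) {
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  }
  structure(list(iupac = iupac, both_strands = isTRUE(both_strands)),
            class = "consensus_pattern")
}

#' Read promoter sequences from FASTA
#'
#' Promoters are expected 5'-to-3' on the coding strand, ending just
#' upstream of the start codon. Sequences longer than `window` are trimmed
#' to their 3'-most `window` bp (the stretch closest to the start codon).
#'
#' @param path FASTA path; record ids (first header token) must match
#'   target gene ids.
#' @param window Maximum promoter length in bp to retain (default 1000).
#' @return A named `Biostrings::DNAStringSet` (uppercase, alphabet ACGTN).
#' @export
read_promoter_fasta <- function(path, window = 1000L) {
  if (!file.exists(path)) stop("promoter FASTA not found: ", path)
  # read as raw strings first: the DNA reader silently drops invalid
  # letters, which would shift match coordinates
  dna <- Biostrings::readBStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) {
    stop("duplicate promoter ids in FASTA")
  }
  seqs <- toupper(as.character(dna))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("promoter alphabet must be A/C/G/T/N; offending record: ",
         names(dna)[bad][1L])
  }
  long <- nchar(seqs) > window
  seqs[long] <- substring(seqs[long], nchar(seqs[long]) - window + 1L)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(dna)
  out
}

#' Scan one promoter for a consensus pattern
#'
#' Reports every position where the pattern matches under IUPAC degeneracy.
#' With `both_strands`, the reverse complement of the pattern is also
#' searched and reported with strand `"-"`; positions are always 1-based
#' match starts on the given (coding) strand. An `N` in the promoter never
#' matches, even against a degenerate pattern code. Overlapping matches are
#' all reported.
#'
#' @param promoter Promoter sequence (character or `DNAString`).
#' @param pattern A [consensus_pattern()] or IUPAC string.
#' @return Data frame with columns `position` and `strand`, sorted by
#'   position. Zero rows for an empty pattern or a pattern longer than the
#'   promoter.
#' @examples
#' scan_consensus("AATCGGCGGCTTT", consensus_pattern("TCGGCGGCT"))
#' @export
scan_consensus <- function(promoter, pattern) {
  if (is.character(pattern)) pattern <- consensus_pattern(pattern)
  stopifnot(inherits(pattern, "consensus_pattern"))
  subj <- if (methods::is(promoter, "DNAString")) promoter else
    Biostrings::DNAString(toupper(as.character(promoter)))
  empty <- data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  plen <- nchar(pattern$iupac)
  if (plen == 0L || plen > length(subj)) return(empty)
  pat <- Biostrings::DNAString(pattern$iupac)
  hits <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, fixed = "subject")
    st <- Biostrings::start(m)
    # a degenerate pattern code can engulf a literal N in the subject;
    # such windows are not evidence of a site
    if (length(st)) {
      win <- substring(as.character(subj), st, st + plen - 1L)
      st <- st[!grepl("N", win, fixed = TRUE)]
    }
    if (length(st) == 0L) return(empty)
    data.frame(position = st, strand = strand, stringsAsFactors = FALSE)
  }
  out <- hits(pat, "+")
  if (pattern$both_strands) {
    out <- rbind(out, hits(Biostrings::reverseComplement(pat), "-"))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a transcription-factor target table
#'
#' TSV with columns `tf<TAB>target[<TAB>evidence]`; missing evidence
#' defaults to `"documented"`.
#'
#' @param path TSV path; `#` comment lines skipped.
#' @return Data frame with columns `tf`, `target`, `evidence`. Targets must
#'   be unique per TF.
#' @export
read_regulon_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("regulon table needs at least tf and target columns")
  out <- data.frame(tf = as.character(df[[1L]]),
                    target = as.character(df[[2L]]),
                    evidence = if (ncol(df) >= 3L) as.character(df[[3L]])
                               else "documented",
                    stringsAsFactors = FALSE)
  out$evidence[!nzchar(out$evidence)] <- "documented"
  if (anyDuplicated(out[c("tf", "target")])) {
    stop("duplicate (tf, target) rows in regulon table")
  }
  out
}

#' Call direct targets by promoter consensus
#'
#' Upgrades a target's evidence to `"direct_by_consensus"` when its promoter
#' carries at least one consensus match; targets without a promoter sequence
#' are logged and left non-direct.
#'
#' @param regulon Data frame from [read_regulon_table()] (columns `tf`,
#'   `target`, `evidence`).
#' @param promoters Named `DNAStringSet` (or named character vector) of
#'   promoter sequences keyed by target gene id.
#' @param pattern A [consensus_pattern()] or IUPAC string.
#' @return The regulon data frame with updated `evidence`, plus columns
#'   `n_sites` and `match_positions` (comma-joined `pos(strand)` entries).
#'   Attribute `report`: list with `n_targets`, `n_direct`,
#'   `missing_promoter`.
#' @export
classify_direct_targets <- function(regulon, promoters, pattern) {
  if (is.character(pattern)) pattern <- consensus_pattern(pattern)
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  }
  stopifnot(is.data.frame(regulon))
  regulon$n_sites <- rep(0L, nrow(regulon))
  regulon$match_positions <- rep("", nrow(regulon))
  missing <- character(0)
  for (i in seq_len(nrow(regulon))) {
    g <- regulon$target[i]
    if (!g %in% names(promoters)) {
      missing <- c(missing, g)
      next
    }
    m <- scan_consensus(promoters[[g]], pattern)
    if (nrow(m)) {
      regulon$evidence[i] <- "direct_by_consensus"
      regulon$n_sites[i] <- nrow(m)
      regulon$match_positions[i] <-
        paste(sprintf("%d(%s)", m$position, m$strand), collapse = ",")
    }
  }
  if (length(missing)) {
    message(length(missing),
            " target(s) without promoter sequence left non-direct")
  }
  attr(regulon, "report") <- list(
    n_targets = nrow(regulon),
    n_direct = sum(regulon$evidence == "direct_by_consensus"),
    missing_promoter = missing
  )
  regulon
}

#' Overlap a regulon with a tolerance gene set
#'
#' Computes the four counts of the regulon-versus-tolerance comparison:
#' total targets, direct targets, targets that are also tolerance genes, and
#' direct targets that are also tolerance genes (always a subset of the
#' former).
#'
#' @param regulon Annotated regulon data frame (see
#'   [classify_direct_targets()]); any data frame with `target` and
#'   `evidence` columns works.
#' @param tolerance A [gene_set()] of acid-tolerance genes.
#' @return List with `n_targets`, `n_direct`, `n_targets_in_tolerance`,
#'   `n_direct_in_tolerance`, and the two member vectors
#'   `targets_in_tolerance`, `direct_in_tolerance`.
#' @export
overlap_with_tolerance <- function(regulon, tolerance) {
  stopifnot(is.data.frame(regulon), inherits(tolerance, "gene_set"))
  targets <- unique(regulon$target)
  direct <- unique(regulon$target[regulon$evidence == "direct_by_consensus"])
  t_in <- intersect(targets, tolerance$ids)
  d_in <- intersect(direct, tolerance$ids)
  list(
    n_targets = length(targets),
    n_direct = length(direct),
    n_targets_in_tolerance = length(t_in),
    n_direct_in_tolerance = length(d_in),
    targets_in_tolerance = sort(t_in),
    direct_in_tolerance = sort(d_in)
  )
}
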