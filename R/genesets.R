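# Gene-set plumbing: alias resolution, union/intersection, dependence
# filtering and functional categorisation.

#' Construct a gene set
#'
#' A gene set is a named, deduplicated collection of canonical gene
#' identifiers with free-text provenance. Identifiers are stored sorted so
#' that set operations and serialised output are deterministic.
#'
#' @param ids Character vector of canonical identifiers.
#' @param name Set name.
#' @param provenance Free-text origin of the set.
#' @return An object of class `gene_set` with elements `name`, `ids`,
#'   `provenance`.
#' @export
gene_set <- function(ids, name = "geneset", provenance = "") {
  ids <- sort(unique(as.character(ids[nzchar(as.character(ids))])))
  structure(list(name = name, ids = ids, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes", x$name, length(x$ids)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Read an alias-to-canonical identifier map
#'
#' Two-column TSV, `alias<TAB>canonical`, mapping standard gene names to
#' systematic (ORF) names. Canonical identifiers are added as self-mappings
#' so canonicalisation is idempotent.
#'
#' @param path TSV path; lines starting with `#` are skipped.
#' @return Named character vector (names = aliases, values = canonical ids).
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("alias map must have two tab-separated columns")
  map <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  canon <- unique(unname(map))
  self <- stats::setNames(canon, canon)
  # explicit alias entries win over implied self-mappings
  c(map, self[!names(self) %in% names(map)])
}

#' Canonicalise gene identifiers through an alias map
#'
#' Unknown aliases are kept verbatim (never silently dropped, which would
#' corrupt funnel counts) and reported via a message and the `unknown`
#' attribute.
#'
#' @param ids Character vector of identifiers.
#' @param alias_map Named vector from [read_alias_map()], or `NULL` to leave
#'   identifiers untouched.
#' @return Character vector of canonical ids, attribute `unknown` listing
#'   identifiers absent from the map.
#' @export
canonicalize_ids <- function(ids, alias_map = NULL) {
  ids <- as.character(ids)
  if (is.null(alias_map)) {
    attr(ids, "unknown") <- character(0)
    return(ids)
  }
  hit <- ids %in% names(alias_map)
  out <- ids
  out[hit] <- unname(alias_map[ids[hit]])
  unknown <- unique(ids[!hit])
  if (length(unknown)) {
    message(length(unknown), " identifier(s) not in alias map, kept verbatim: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
  }
  attr(out, "unknown") <- unknown
  out
}

#' Load a gene list from a text or TSV file
#'
#' One identifier per line, or the first column of a TSV; `#` comment lines
#' are skipped; identifiers are canonicalised through the alias map.
#'
#' @param path Input file.
#' @param alias_map Optional named vector from [read_alias_map()].
#' @param name Set name (defaults to the file name).
#' @return A [gene_set()].
#' @export
load_gene_list <- function(path, alias_map = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (length(ids) == 0L) {
    warning("gene list is empty: ", path)
  }
  ids <- canonicalize_ids(ids, alias_map)
  gene_set(ids, name = name, provenance = path)
}

#' Deduplicating union of gene sets ("consistency analysis")
#'
#' Resolves the overlapping acid-sensitivity screens into a single
#' non-redundant candidate set: the exact union of alias-resolved
#' identifiers. The attached report records per-source counts, all pairwise
#' overlaps and the union size, so the inclusion-exclusion identity
#' |A union B| = |A| + |B| - |A intersect B| can be audited for every pair.
#'
#' @param sets List of [gene_set()] objects canonicalised with the same
#'   alias map.
#' @param name Name for the union set.
#' @return A [gene_set()]; attribute `report` is a list with `sources`
#'   (data frame of set name and size), `pairwise` (data frame of pair
#'   overlaps) and `union_size`.
#' @export
consistency_union <- function(sets, name = "union") {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "gene_set")))
  ids <- sort(unique(unlist(lapply(sets, `[[`, "ids"), use.names = FALSE)))
  sources <- data.frame(
    set = vapply(sets, `[[`, "", "name"),
    size = vapply(sets, function(s) length(s$ids), 1L),
    stringsAsFactors = FALSE
  )
  pairs <- if (length(sets) >= 2L) utils::combn(length(sets), 2L) else
    matrix(integer(0), nrow = 2L)
  pairwise <- data.frame(
    set_a = sources$set[pairs[1L, ]],
    set_b = sources$set[pairs[2L, ]],
    overlap = apply(pairs, 2L, function(ij)
      length(intersect(sets[[ij[1L]]]$ids, sets[[ij[2L]]]$ids))),
    stringsAsFactors = FALSE
  )
  out <- gene_set(ids, name = name,
                  provenance = paste("union of:",
                                     paste(sources$set, collapse = ", ")))
  attr(out, "report") <- list(sources = sources, pairwise = pairwise,
                              union_size = length(ids))
  out
}

#' Intersection of two gene sets
#'
#' @param a,b [gene_set()] objects with canonicalised identifiers.
#' @param name Name for the result.
#' @return A [gene_set()] whose provenance names both parents.
#' @export
gene_intersect <- function(a, b, name = paste0(a$name, "&", b$name)) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  gene_set(intersect(a$ids, b$ids), name = name,
           provenance = sprintf("intersection of '%s' and '%s'",
                                a$name, b$name))
}

#' Keep genes whose protein is in the high eIF5A-dependence class
#'
#' Subsets a gene set to members whose motif profile is flagged
#' `high_dependence` (at least two separate polyproline runs, or a single
#' run of four or more prolines). Genes with no profile row are logged and
#' excluded.
#'
#' @param genes A [gene_set()].
#' @param profiles Profile data frame from [scan_proteome()].
#' @param name Name for the result.
#' @return A [gene_set()], always a subset of `genes`; attribute
#'   `missing_profile` lists genes not covered by the scan.
#' @export
filter_high_dependence <- function(genes, profiles,
                                   name = paste0(genes$name, ".highdep")) {
  stopifnot(inherits(genes, "gene_set"), is.data.frame(profiles))
  covered <- genes$ids %in% profiles$protein_id
  missing <- genes$ids[!covered]
  if (length(missing)) {
    message(length(missing), " gene(s) without a motif profile excluded")
  }
  hd <- profiles$protein_id[profiles$high_dependence]
  out <- gene_set(intersect(genes$ids, hd), name = name,
                  provenance = sprintf("high-dependence subset of '%s'",
                                       genes$name))
  attr(out, "missing_profile") <- missing
  out
}

#' Read a gene-to-category annotation map
#'
#' TSV with columns `gene<TAB>category`; a gene with several categories
#' appears on several rows (a flat slim mapping, no ontology traversal).
#'
#' @param path TSV path; `#` comment lines skipped.
#' @return Named list mapping gene id to a character vector of categories.
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation map must have two tab-separated columns")
  cats <- as.character(df[[2L]])
  if (any(!nzchar(cats))) stop("empty category label in annotation map")
  split(cats, as.character(df[[1L]]))
}

#' Categorise a gene set by functional annotation
#'
#' A gene carrying k categories contributes one count to each of the k
#' category rows; genes absent from the annotation map are reported under
#' `"unknown function"`. Member lists are emitted so single-count views can
#' be derived downstream.
#'
#' @param genes A [gene_set()].
#' @param ann Named list from [read_annotation_map()].
#' @param unknown_label Label for unannotated genes.
#' @return Data frame with columns `category`, `count`, `members`
#'   (comma-joined gene ids), sorted by decreasing count then label.
#' @export
categorize_genes <- function(genes, ann, unknown_label = "unknown function") {
  stopifnot(inherits(genes, "gene_set"), is.list(ann))
  pairs <- lapply(genes$ids, function(g) {
    cats <- ann[[g]]
    if (is.null(cats) || length(cats) == 0L) cats <- unknown_label
    data.frame(gene = g, category = unique(cats), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(data.frame(category = character(0), count = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  by_cat <- split(pairs$gene, pairs$category)
  out <- data.frame(
    category = names(by_cat),
    count = vapply(by_cat, length, 1L),
    members = vapply(by_cat, function(g) paste(sort(g), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
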