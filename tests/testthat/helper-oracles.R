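# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementations they check.

# position-by-position maximal proline-run scanner
brute_force_runs <- function(residues, min_len = 3L) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] == "P") {
      j <- i
      while (j < n && chars[j + 1L] == "P") j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, length = lens)
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
            V = "B", H = "D", D = "H", B = "V")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# all-offsets IUPAC matcher; a literal N in the promoter matches nothing
brute_force_iupac <- function(promoter, iupac, both_strands = TRUE) {
  match_at <- function(seq_chars, pat) {
    pchars <- strsplit(pat, "", fixed = TRUE)[[1L]]
    L <- length(pchars); n <- length(seq_chars)
    hits <- integer(0)
    if (L >= 1L && L <= n) {
      for (pos in 1:(n - L + 1L)) {
        ok <- TRUE
        for (k in 1:L) {
          if (!seq_chars[pos + k - 1L] %in% iupac_sets[[pchars[k]]]) {
            ok <- FALSE; break
          }
        }
        if (ok) hits <- c(hits, pos)
      }
    }
    hits
  }
  sc <- strsplit(toupper(promoter), "", fixed = TRUE)[[1L]]
  fwd <- match_at(sc, iupac)
  out <- data.frame(position = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- match_at(sc, revcomp_chr(iupac))
    out <- rbind(out, data.frame(position = rev,
                                 strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_protein <- function(len, p_freq = 0.15) {
  alphabet <- c(strsplit("ACDEFGHIKLMNQRSTVWYX", "")[[1L]], "P")
  prob <- c(rep((1 - p_freq) / 20, 20), p_freq)
  paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

random_dna <- function(len, with_n = FALSE) {
  alphabet <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
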