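# Independent brute-force oracle for global pairwise alignment: enumerate
# every monotone alignment of two ungapped sequences and score it directly.
# Deliberately shares no code with the package's dynamic programming.

enum_alignments <- function(a, b) {
  if (!length(a) && !length(b))
    return(list(rbind(character(0), character(0))))
  out <- list()
  if (length(a) && length(b))
    for (al in enum_alignments(a[-1], b[-1]))
      out[[length(out) + 1L]] <- cbind(c(a[1], b[1]), al)
  if (length(a))
    for (al in enum_alignments(a[-1], b))
      out[[length(out) + 1L]] <- cbind(c(a[1], "-"), al)
  if (length(b))
    for (al in enum_alignments(a, b[-1]))
      out[[length(out) + 1L]] <- cbind(c("-", b[1]), al)
  out
}

# score a gapped 2-row alignment: substitution scores plus affine run costs
# open + (k-1)*extend, optionally with free terminal runs
oracle_score_gapped <- function(al, S, go, ge, free = FALSE) {
  ra <- al[1L, ]; rb <- al[2L, ]
  res <- ra != "-" & rb != "-"
  s <- if (any(res)) sum(S[cbind(ra[res], rb[res])]) else 0
  run_cost <- function(gaps) {
    if (!any(gaps)) return(0)
    r <- rle(gaps)
    lens <- r$lengths[r$values]
    if (free) {
      keep <- rep(TRUE, length(lens))
      if (r$values[1L]) keep[1L] <- FALSE
      if (r$values[length(r$values)]) keep[length(keep)] <- FALSE
      lens <- lens[keep]
    }
    if (!length(lens)) 0 else sum(go + (lens - 1L) * ge)
  }
  s - run_cost(ra == "-") - run_cost(rb == "-")
}

oracle_optimal_score <- function(a, b, scheme) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  max(vapply(enum_alignments(a, b), oracle_score_gapped, 0,
             S = scheme$matrix, go = scheme$go, ge = scheme$ge,
             free = scheme$terminal_gaps == "free"))
}

# random gapped test alignment (not via the package's fixture generator)
random_alignment <- function(n_seq, n_col, alphabet = "aa", gap_prob = 0.15) {
  syms <- alphabet_symbols(alphabet, unknown = FALSE)
  mat <- matrix(sample(syms, n_seq * n_col, replace = TRUE), n_seq, n_col)
  mat[matrix(stats::runif(n_seq * n_col) < gap_prob, n_seq, n_col)] <- "-"
  msa(mat, alphabet = alphabet)
}

blosum62 <- load_score_matrix("BLOSUM62")
scheme_linear6 <- scoring_scheme(blosum62, gap_model = "linear", gap = -6)
scheme_affine <- scoring_scheme(blosum62, gap_model = "affine",
                                gap_open = 20, gap_extend = 2)
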