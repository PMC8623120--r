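#' MSA-implied score of a sequence pair
#'
#' Scores the pairwise alignment that a multiple alignment implies for two
#' of its rows. Columns gapped in both rows are skipped entirely: they
#' contribute nothing and, in the affine model, do not break or extend a
#' gap run of either row, so a run interrupted only by shared-gap columns
#' is charged a single gap opening. Residue-vs-residue columns add the
#' substitution score; residue-vs-gap columns are charged through the gap
#' model; terminal gap runs follow the scheme's terminal-gap policy.
#'
#' @param row_a,row_b Gapped rows of equal length: character vectors,
#'   strings, or (via [all_pair_scores()]) rows of an [msa].
#' @param scheme A [scoring_scheme()].
#' @return Numeric score.
#' @examples
#' sch <- scoring_scheme(load_score_matrix("BLOSUM62"),
#'                       gap_model = "linear", gap = -6)
#' implied_pair_score("-T", "TT", sch)  # -6 + 5 = -1
#' @export
implied_pair_score <- function(row_a, row_b, scheme) {
  a <- as_residues(row_a); b <- as_residues(row_b)
  if (length(a) != length(b))
    stop("rows have unequal lengths (", length(a), " vs ", length(b), ")")
  shared <- a == GAP & b == GAP
  if (any(shared)) { a <- a[!shared]; b <- b[!shared] }
  if (!length(a)) return(0)
  ga <- a == GAP; gb <- b == GAP
  res <- !ga & !gb
  sub <- if (any(res)) sum(scheme$matrix[cbind(a[res], b[res])]) else 0
  sub - gap_run_cost(ga, scheme) - gap_run_cost(gb, scheme)
}

#' Optimal global pairwise alignment score
#'
#' Needleman-Wunsch (linear gap model) / Gotoh three-state (affine model)
#' global dynamic programming over two ungapped sequences, under the same
#' run-cost convention as [implied_pair_score()] (`open + (k-1) * extend`).
#' With `terminal_gaps = "free"` in the scheme, leading and trailing gap
#' runs are cost-free (semi-global alignment). An empty sequence is
#' allowed: the score is the gap cost of the other sequence as one run.
#'
#' @param seq_a,seq_b Ungapped sequences (strings or character vectors).
#' @param scheme A [scoring_scheme()].
#' @param traceback If `TRUE`, also return one optimal alignment.
#' @return The optimal score, or - when `traceback = TRUE` - a list with
#'   `score` and `alignment` (character matrix of 2 gapped rows).
#' @examples
#' sch <- scoring_scheme(load_score_matrix("BLOSUM62"),
#'                       gap_model = "linear", gap = -6)
#' optimal_pair_score("T", "TT", sch)  # -1
#' @export
optimal_pair_score <- function(seq_a, seq_b, scheme, traceback = FALSE) {
  a <- as_residues(seq_a); b <- as_residues(seq_b)
  a <- a[a != ""]; b <- b[b != ""]
  if (any(a == GAP) || any(b == GAP)) stop("inputs must be gap-free")
  free <- scheme$terminal_gaps == "free"
  go <- scheme$go; ge <- scheme$ge; S <- scheme$matrix
  n <- length(a); m <- length(b)
  run_cost <- function(k) if (k == 0L) 0 else go + (k - 1L) * ge
  if (n == 0L || m == 0L) {
    sc <- if (free) 0 else -run_cost(max(n, m))
    if (!traceback) return(sc)
    al <- rbind(if (n == 0L) rep(GAP, m) else a,
                if (m == 0L) rep(GAP, n) else b)
    return(list(score = sc, alignment = al))
  }
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)  # X: gap in b (a consumed), Y: gap in a
  M[1L, 1L] <- 0
  X[2L:(n + 1L), 1L] <- if (free) 0 else -(go + (seq_len(n) - 1L) * ge)
  Y[1L, 2L:(m + 1L)] <- if (free) 0 else -(go + (seq_len(m) - 1L) * ge)
  if (traceback) { pM <- pX <- pY <- matrix(0L, n + 1L, m + 1L) }
  for (i in seq_len(n)) {
    Srow <- S[a[i], b]
    for (j in seq_len(m)) {
      cand <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(cand)
      M[i + 1L, j + 1L] <- Srow[j] + cand[k]
      if (traceback) pM[i + 1L, j + 1L] <- k
      cand <- c(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      k <- which.max(cand)
      X[i + 1L, j + 1L] <- cand[k]
      if (traceback) pX[i + 1L, j + 1L] <- k
      cand <- c(M[i + 1L, j] - go, X[i + 1L, j] - go, Y[i + 1L, j] - ge)
      k <- which.max(cand)
      Y[i + 1L, j + 1L] <- cand[k]
      if (traceback) pY[i + 1L, j + 1L] <- k
    }
  }
  ends <- function(i, j) c(M[i, j], X[i, j], Y[i, j])
  if (!free) {
    fin <- ends(n + 1L, m + 1L)
    best <- max(fin)
    end_i <- n + 1L; end_j <- m + 1L; end_s <- which.max(fin)
  } else {
    best <- -Inf; end_i <- n + 1L; end_j <- m + 1L; end_s <- 1L
    for (i in seq_len(n + 1L)) {
      v <- ends(i, m + 1L); k <- which.max(v)
      if (v[k] > best) { best <- v[k]; end_i <- i; end_j <- m + 1L; end_s <- k }
    }
    for (j in seq_len(m + 1L)) {
      v <- ends(n + 1L, j); k <- which.max(v)
      if (v[k] > best) { best <- v[k]; end_i <- n + 1L; end_j <- j; end_s <- k }
    }
  }
  if (!traceback) return(best)

  ra <- character(0); rb <- character(0)
  # free-end suffix
  if (end_i <= n) { ra <- a[end_i:n]; rb <- rep(GAP, n - end_i + 1L) }
  if (end_j <= m) { ra <- rep(GAP, m - end_j + 1L); rb <- b[end_j:m] }
  i <- end_i; j <- end_j; s <- end_s
  repeat {
    if (s == 1L) {                      # M state: a[i-1] vs b[j-1]
      if (i == 1L && j == 1L) break
      ra <- c(a[i - 1L], ra); rb <- c(b[j - 1L], rb)
      s <- pM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (s == 2L) {               # X: a[i-1] vs gap
      if (j == 1L) {                    # boundary column: rest of a gapped in b
        ra <- c(a[seq_len(i - 1L)], ra); rb <- c(rep(GAP, i - 1L), rb)
        break
      }
      ra <- c(a[i - 1L], ra); rb <- c(GAP, rb)
      s <- pX[i, j]; i <- i - 1L
    } else {                            # Y: gap vs b[j-1]
      if (i == 1L) {
        ra <- c(rep(GAP, j - 1L), ra); rb <- c(b[seq_len(j - 1L)], rb)
        break
      }
      ra <- c(GAP, ra); rb <- c(b[j - 1L], rb)
      s <- pY[i, j]; j <- j - 1L
    }
  }
  list(score = best, alignment = rbind(ra, rb))
}

#' Score every sequence pair of an alignment both ways
#'
#' For each of the `N(N-1)/2` pairs, computes the MSA-implied score and the
#' optimal global pairwise score of the degapped sequences under the same
#' scheme. The optimal score can never be smaller than the implied score;
#' the per-pair deficit `optimal - implied` is what the pairwise alignment
#' inconsistency index [pai()] sums.
#'
#' @param aln An [msa] object (at least 2 sequences).
#' @param scheme A [scoring_scheme()].
#' @return Data frame with columns `i`, `j`, `id_i`, `id_j`, `implied`,
#'   `optimal`, `deficit`.
#' @export
all_pair_scores <- function(aln, scheme) {
  N <- n_seq(aln)
  if (N < 2L) stop("need at least 2 sequences")
  pairs <- utils::combn(N, 2L)
  rows <- lapply(seq_len(N), function(i) aln$mat[i, ])
  degapped <- lapply(rows, degap)
  implied <- optimal <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    implied[k] <- implied_pair_score(rows[[i]], rows[[j]], scheme)
    optimal[k] <- optimal_pair_score(degapped[[i]], degapped[[j]], scheme)
  }
  data.frame(i = pairs[1L, ], j = pairs[2L, ],
             id_i = seq_ids(aln)[pairs[1L, ]], id_j = seq_ids(aln)[pairs[2L, ]],
             implied = implied, optimal = optimal,
             deficit = optimal - implied)
}

#' Write a per-pair score report
#'
#' Tab-separated table of implied and optimal scores with the per-pair
#' deficit, as produced by [all_pair_scores()].
#'
#' @inheritParams all_pair_scores
#' @param file Path to write to.
#' @return The report data frame, invisibly.
#' @export
write_pair_report <- function(aln, scheme, file) {
  rep <- all_pair_scores(aln, scheme)
  utils::write.table(rep, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
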