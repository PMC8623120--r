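#' Sum-of-pairs score of an alignment
#'
#' The sum over all `N(N-1)/2` sequence pairs of the pairwise alignment
#' score implied by the multiple alignment, with shared gaps unpenalised:
#' columns gapped in both members of a pair are skipped. Because of that
#' policy, `sps()` is invariant under insertion or deletion of all-gap
#' columns.
#'
#' @param aln An [msa] object.
#' @param scheme A [scoring_scheme()].
#' @return Numeric score.
#' @seealso [wsps()], [pai()], [criterion_delta()]
#' @export
sps <- function(aln, scheme) {
  N <- n_seq(aln)
  if (N < 2L) stop("need at least 2 sequences")
  tot <- 0
  for (i in seq_len(N - 1L))
    for (j in (i + 1L):N)
      tot <- tot + implied_pair_score(aln$mat[i, ], aln$mat[j, ], scheme)
  tot
}

#' Weighted sum-of-pairs score
#'
#' `WSPS = sum over pairs of W[i, j] * S[i, j]`, where `S[i, j]` is the
#' MSA-implied pair score and the weights come from the scheme's
#' `pair_weights` matrix. With all weights 1 (or `pair_weights = NULL`)
#' this reduces exactly to [sps()].
#'
#' @inheritParams sps
#' @return Numeric score.
#' @export
wsps <- function(aln, scheme) {
  N <- n_seq(aln)
  if (N < 2L) stop("need at least 2 sequences")
  W <- scheme$pair_weights
  if (is.null(W)) return(sps(aln, scheme))
  if (!is.matrix(W) || nrow(W) < N || ncol(W) < N || anyNA(W[seq_len(N), seq_len(N)]))
    stop("pair_weights must cover every sequence pair")
  tot <- 0
  for (i in seq_len(N - 1L))
    for (j in (i + 1L):N)
      tot <- tot + W[i, j] * implied_pair_score(aln$mat[i, ], aln$mat[j, ], scheme)
  tot
}

#' Pairwise alignment inconsistency index
#'
#' `PAI = sum over pairs of (optimal - implied)` pair scores: the total
#' deficit between each pair's optimal global alignment score (dynamic
#' programming over the degapped sequences) and the score the MSA implies
#' for that pair. PAI is always non-negative and equals 0 exactly when
#' every implied pair score attains its optimum; larger values indicate a
#' worse alignment.
#'
#' @inheritParams sps
#' @return Non-negative numeric.
#' @export
pai <- function(aln, scheme) {
  ps <- all_pair_scores(aln, scheme)
  sum(ps$deficit)
}

#' Signed criterion improvement between two alignments
#'
#' Compares two alignments of the same sequences (identical ids and
#' identical residues after gap removal) under one criterion, with the sign
#' arranged so that a positive value always means the `after` alignment is
#' better: `after - before` for SPS/WSPS and `before - after` for PAI.
#'
#' For PAI the optimal pair scores depend only on the degapped sequences,
#' which the precondition fixes, so they cancel exactly and the delta is
#' computed from implied scores alone; this also makes a delta over a
#' differing window algebraically equal to the full-alignment delta.
#'
#' @param aln_before,aln_after [msa] objects with the same sequences.
#' @param criterion `"SPS"`, `"WSPS"` or `"PAI"`.
#' @param scheme A [scoring_scheme()].
#' @return Signed numeric improvement (positive = `after` is better).
#' @export
criterion_delta <- function(aln_before, aln_after,
                            criterion = c("SPS", "WSPS", "PAI"), scheme) {
  criterion <- match.arg(criterion)
  check_same_content(aln_before, aln_after)
  if (criterion == "WSPS")
    return(wsps(aln_after, scheme) - wsps(aln_before, scheme))
  # SPS delta; for PAI, optimal scores cancel and
  # pai(before) - pai(after) == sps(after) - sps(before)
  sps(aln_after, scheme) - sps(aln_before, scheme)
}

check_same_content <- function(a, b) {
  if (!identical(seq_ids(a), seq_ids(b)))
    stop("alignments do not contain the same sequence ids in the same order")
  for (i in seq_len(n_seq(a)))
    if (!identical(degap(a$mat[i, ]), degap(b$mat[i, ])))
      stop("degapped content differs for sequence '", seq_ids(a)[i], "'")
  invisible(TRUE)
}
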