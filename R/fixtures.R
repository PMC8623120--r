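with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    old <- get(".Random.seed", envir = globalenv())
  else old <- NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_move <- function(seq, block_start, block_len, direction, slide) {
  data.frame(seq = seq, block_start = block_start, block_len = block_len,
             direction = direction, slide = slide)
}

#' Generate a planted residue-shift fixture
#'
#' Produces a pair of alignments - `clean` and `perturbed` - that differ
#' only by known residue shifts across gap runs, plus the `truth` moves
#' that restore `clean` from `perturbed`. Degapped sequence content is
#' identical between the two states, and generation is deterministic given
#' `seed`.
#'
#' Three presets are available:
#' \describe{
#'   \item{`"random"`}{A consensus-derived alignment with point
#'     substitutions and one sequence carrying a residue block on the
#'     wrong side of a gap run. The consensus at the block's wrong-side
#'     columns is forced to differ from the block residues, so the planted
#'     shift is unambiguously recoverable.}
#'   \item{`"ace2"`}{11 amino-acid sequences, 25 columns. At sites 20-21
#'     one sequence carries `-T` (perturbed) where `T-` (clean) is
#'     correct; the other 10 sequences all bear T at site 20 and split
#'     6 T / 4 I at site 21, the composition under which the two-column
#'     sum-of-pairs contribution is -34 (perturbed) vs -10 (clean) with
#'     gap -6, T/T = 5, T/I = -1.}
#'   \item{`"huntingtin"`}{20 sequences with variable-length glutamine
#'     (Q) tracts followed by a proline (P) region. In the perturbed state
#'     three sequences carry a P residue in a Q-majority column (12 Q, 3 P)
#'     with a sparse all-P column five sites downstream, and three short Q
#'     tracts sit at the wrong end of their gap run. Relocating the P
#'     residues and consolidating the Q tracts raises the PWM differential
#'     while lowering the sum-of-pairs score - the criterion conflict this
#'     preset exists to exhibit.}
#' }
#'
#' @param preset `"random"`, `"ace2"` or `"huntingtin"`.
#' @param n_seq,n_col Dimensions (random preset only).
#' @param alphabet `"aa"` or `"nt"` (random preset only).
#' @param sub_rate Per-site substitution rate away from the consensus.
#' @param seed Integer seed; generation is deterministic given it.
#' @return List with `clean` ([msa]), `perturbed` ([msa]) and `truth`
#'   (data frame of moves restoring `clean` from `perturbed`).
#' @export
make_shift_fixture <- function(preset = c("random", "ace2", "huntingtin"),
                               n_seq = 8L, n_col = 30L,
                               alphabet = c("aa", "nt"),
                               sub_rate = 0.05, seed = 1L) {
  preset <- match.arg(preset)
  alphabet <- match.arg(alphabet)
  switch(preset,
         random = fixture_random(n_seq, n_col, alphabet, sub_rate, seed),
         ace2 = fixture_ace2(sub_rate, seed),
         huntingtin = fixture_huntingtin(sub_rate, seed))
}

fixture_random <- function(n_seq, n_col, alphabet, sub_rate, seed) {
  stopifnot(n_seq >= 3L, n_col >= 12L)
  syms <- alphabet_symbols(alphabet, unknown = FALSE)
  with_seed(seed, {
    consensus <- sample(syms, n_col, replace = TRUE)
    pick <- function(v) v[sample.int(length(v), 1L)]
    s <- sample.int(n_seq, 1L)
    b <- pick(1:3)                       # block length
    g <- pick(b:3)                       # gap-run length >= block
    d <- pick(b:g)                       # slide distance, >= block so the
                                         # shifted block clears its own columns
    b0 <- sample.int(n_col - b - g, 1L)  # block start (clean state)
    # every placement of a block residue inside the gap run must mismatch,
    # so the clean placement is the unique optimum: draw the gap-run
    # consensus from letters disjoint from the block's letters
    blk_syms <- consensus[b0:(b0 + b - 1L)]
    gap_cols <- (b0 + b):(b0 + b + g - 1L)
    consensus[gap_cols] <- sample(setdiff(syms, blk_syms), g, replace = TRUE)
    mat <- matrix(consensus, n_seq, n_col, byrow = TRUE)
    sub <- matrix(stats::runif(n_seq * n_col) < sub_rate, n_seq, n_col)
    sub[s, ] <- FALSE                    # mover stays on-consensus
    for (idx in which(sub)) {
      i <- (idx - 1L) %% n_seq + 1L; j <- (idx - 1L) %/% n_seq + 1L
      mat[i, j] <- sample(setdiff(syms, consensus[j]), 1L)
    }
    mat[s, (b0 + b):(b0 + b + g - 1L)] <- GAP
    clean <- msa(mat, ids = sprintf("seq%02d", seq_len(n_seq)),
                 alphabet = alphabet)
    perturbing <- new_move(s, b0, b, "right", d)
    perturbed <- apply_move(clean, perturbing)
    truth <- new_move(s, b0 + d, b, "left", d)
    list(clean = clean, perturbed = perturbed, truth = truth)
  })
}

fixture_ace2 <- function(sub_rate, seed) {
  n <- 11L; L <- 25L; shifted <- 5L
  with_seed(seed, {
    consensus <- sample(AA_ALPHABET, L, replace = TRUE)
    consensus[20L] <- "T"
    mat <- matrix(consensus, n, L, byrow = TRUE)
    # site 21 among the 10 unshifted sequences: 6 T and 4 I
    others <- setdiff(seq_len(n), shifted)
    mat[others[1:4], 21L] <- "I"
    mat[others[5:10], 21L] <- "T"
    # light substitutions away from the worked-example window
    protect <- 18:23
    sub <- matrix(stats::runif(n * L) < sub_rate, n, L)
    sub[, protect] <- FALSE
    sub[shifted, ] <- FALSE
    for (idx in which(sub)) {
      i <- (idx - 1L) %% n + 1L; j <- (idx - 1L) %/% n + 1L
      mat[i, j] <- sample(setdiff(AA_ALPHABET, mat[i, j]), 1L)
    }
    mat[shifted, 20:21] <- c("T", GAP)   # clean: "T-"
    clean <- msa(mat, ids = sprintf("sp%02d", seq_len(n)), alphabet = "aa")
    perturbed <- apply_move(clean, new_move(shifted, 20L, 1L, "right", 1L))
    truth <- new_move(shifted, 21L, 1L, "left", 1L)
    list(clean = clean, perturbed = perturbed, truth = truth)
  })
}

# 48 columns: flank 1-8 | Q region 9-28 | boundary 29 | 30-33 | sparse 34 |
# P region 35-40 | tail 41-48
fixture_huntingtin <- function(sub_rate, seed) {
  n <- 20L; L <- 48L
  with_seed(seed, {
    flank <- sample(setdiff(AA_ALPHABET, c("Q", "P")), 8L, replace = TRUE)
    tail_ <- sample(setdiff(AA_ALPHABET, c("Q", "P")), 8L, replace = TRUE)
    mat <- matrix(GAP, n, L)
    mat[, 1:8] <- matrix(flank, n, 8L, byrow = TRUE)
    mat[, 41:48] <- matrix(tail_, n, 8L, byrow = TRUE)
    put <- function(i, cols, sym) mat[i, cols] <<- sym
    for (i in 1:12) { put(i, 9:29, "Q"); put(i, 35:40, "P") }          # Q21, P6
    qb <- c(16L, 14L, 12L)
    for (k in 1:3) {                                                    # B group
      i <- 12L + k
      put(i, (29L - qb[k]):28L, "Q")
      put(i, 34L, "P")                   # clean: P joins the run at col 34
      put(i, 35:40, "P")
    }
    put(16L, 19:28, "Q"); put(16L, 34:40, "P")                          # Q10, P7
    put(17L, 18:28, "Q"); put(17L, 30:40, "P")                          # Q11, P11
    for (i in 18:20) { put(i, 23:28, "Q"); put(i, 35:40, "P") }         # Q6, P6
    # substitutions only in the conserved flanks
    sub <- matrix(stats::runif(n * L) < sub_rate, n, L)
    sub[, 9:40] <- FALSE
    for (idx in which(sub)) {
      i <- (idx - 1L) %% n + 1L; j <- (idx - 1L) %/% n + 1L
      mat[i, j] <- sample(setdiff(AA_ALPHABET, c(mat[i, j], "Q", "P")), 1L)
    }
    clean <- msa(mat, ids = sprintf("htt%02d", seq_len(n)), alphabet = "aa")
    # perturbed: P residues of the B group sit in the Q-majority boundary
    # column; the three short Q tracts sit at the left end of their gap run
    perturbing <- rbind(
      new_move(13:15, 34L, 1L, "left", 5L),
      new_move(18:20, 23L, 6L, "left", 14L))
    perturbed <- clean
    for (k in seq_len(nrow(perturbing)))
      perturbed <- apply_move(perturbed, perturbing[k, ])
    truth <- rbind(
      new_move(13:15, 29L, 1L, "right", 5L),
      new_move(18:20, 9L, 6L, "right", 14L))
    list(clean = clean, perturbed = perturbed, truth = truth)
  })
}

#' Generate the codon triplet-shift fixture
#'
#' Three protein-coding nucleotide sequences where the third carries a
#' one-codon deletion. In the clean alignment the gap triplet is placed so
#' that the alignment contains only the deletion; in the perturbed
#' alignment the gap sits one codon to the left, which manufactures a
#' spurious A/G substitution. A triplet-respecting shift (frame step 3)
#' of the displaced codon removes the substitution and restores the
#' higher-scoring alignment.
#'
#' @param seed Integer seed; varies the shared flanking codons only.
#' @return List with `clean`, `perturbed` ([msa], alphabet `"codon"`) and
#'   `truth` (the restoring move).
#' @export
make_codon_fixture <- function(seed = 1L) {
  with_seed(seed, {
    codons <- c("ATG", "GCA", "GCC", "GGT", "TTC", "AAA", "CAT", "GAA",
                "TGG", "TAC")
    lead <- paste(sample(codons, 2L), collapse = "")
    trail <- paste(sample(codons, 2L), collapse = "")
    core_full <- "GCAGCG"            # two near-identical codons: GCA, GCG
    core_del <- "GCA"                # third sequence lacks the second codon
    s_full <- paste0(lead, core_full, trail)
    clean <- msa(c(s1 = s_full, s2 = s_full,
                   s3 = paste0(lead, core_del, "---", trail)),
                 alphabet = "codon")
    # shift the gap one codon left: GCA now faces GCG, a spurious A/G change
    perturbed <- apply_move(clean, new_move(3L, nchar(lead) + 1L, 3L,
                                            "right", 3L))
    truth <- new_move(3L, nchar(lead) + 4L, 3L, "left", 3L)
    list(clean = clean, perturbed = perturbed, truth = truth)
  })
}
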