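#' Per-column residue counts of an alignment
#'
#' Counts each alphabet symbol in each column. Gaps and the unknown symbol
#' (`X`/`N`) are excluded, so for every column the symbol counts plus gaps
#' plus unknowns add up to the number of sequences.
#'
#' @param aln An [msa] object.
#' @return Integer matrix, symbols x columns.
#' @export
column_counts <- function(aln) {
  syms <- alphabet_symbols(aln$alphabet, unknown = FALSE)
  apply(aln$mat, 2L, function(col) {
    tab <- table(factor(col, levels = syms))
    as.integer(tab)
  }) -> m
  if (is.null(dim(m))) m <- matrix(m, nrow = length(syms))
  rownames(m) <- syms
  m
}

#' Build a position weight matrix
#'
#' Log-odds weights per column and symbol. For a column with `n_aj` counts
#' of symbol `a` among `N_j` non-gap (non-unknown) observations,
#' `w_aj = log2( ((n_aj + c_a) / (N_j + sum(c))) / p_a )`, where `p_a` is
#' the background frequency and the pseudocounts are background-
#' proportional, `c_a = p_a * pseudocount_mass`. The weight is strictly
#' increasing in `n_aj`; symbols absent from a column share the column's
#' floor value when the background is uniform. Gaps have no row: the
#' matrix has one row per residue symbol only.
#'
#' @param x An [msa] object or a counts matrix from [column_counts()].
#' @param pseudocount_mass Total pseudocount mass (> 0), default 1.
#' @param background `"uniform"` (default), `"empirical"` (Laplace-smoothed
#'   frequencies over the whole alignment, gaps excluded; only for `msa`
#'   input), or a named numeric vector of frequencies summing to 1.
#' @param log_base Base of the logarithm, default 2.
#' @return An object of class `msa_pwm` with elements `weights`
#'   (symbols x columns), `background`, `pseudocount_mass`, `log_base`,
#'   `source_columns`.
#' @export
build_pwm <- function(x, pseudocount_mass = 1,
                      background = c("uniform", "empirical"),
                      log_base = 2) {
  if (pseudocount_mass <= 0)
    stop("pseudocount_mass must be > 0 (log-odds diverge otherwise)")
  counts <- if (inherits(x, "msa")) column_counts(x) else as.matrix(x)
  syms <- rownames(counts)
  if (is.null(syms)) stop("counts matrix must have symbol rownames")
  if (is.character(background)) {
    background <- match.arg(background)
    if (background == "uniform") {
      p <- stats::setNames(rep(1 / length(syms), length(syms)), syms)
    } else {
      tot <- rowSums(counts)
      p <- stats::setNames((tot + 1) / (sum(tot) + length(syms)), syms)
    }
  } else {
    p <- background[syms]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-8 || any(p <= 0))
      stop("background must cover all symbols, be positive and sum to 1")
  }
  cc <- p * pseudocount_mass
  Nj <- colSums(counts)
  w <- log((sweep(counts, 1L, cc, "+")) /
             matrix(Nj + pseudocount_mass, nrow(counts), ncol(counts), byrow = TRUE) / p,
           base = log_base)
  structure(list(weights = w, background = p,
                 pseudocount_mass = pseudocount_mass, log_base = log_base,
                 source_columns = ncol(w)),
            class = "msa_pwm")
}

#' Construct a PWM from explicit weights
#'
#' Wraps a ready-made weight matrix (symbols x columns) as an `msa_pwm`,
#' e.g. weights published elsewhere or exported by another program.
#'
#' @param weights Numeric matrix with symbol rownames.
#' @param log_base Base the weights are expressed in (informational).
#' @return An `msa_pwm` object.
#' @export
pwm_from_weights <- function(weights, log_base = 2) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) stop("weights must have symbol rownames")
  structure(list(weights = weights, background = NULL,
                 pseudocount_mass = NA_real_, log_base = log_base,
                 source_columns = ncol(weights)),
            class = "msa_pwm")
}

#' @export
print.msa_pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix: %d symbols x %d columns (log base %g)\n",
              nrow(x$weights), ncol(x$weights), x$log_base))
  if (!is.null(x$background))
    cat(sprintf("  pseudocount mass %g, background [%s...]\n",
                x$pseudocount_mass,
                paste(sprintf("%s=%.3f", names(x$background)[1:3],
                              x$background[1:3]), collapse = " ")))
  invisible(x)
}

#' @export
as.matrix.msa_pwm <- function(x, ...) x$weights

#' PWM score of sequences
#'
#' The PWM score (PWMS) of a gapped row is the sum of its residues'
#' weights at the columns they occupy; gap and unknown sites contribute
#' nothing, so adding a shared-gap column to an alignment changes no
#' sequence's PWMS.
#'
#' @param x A gapped row (string or character vector) or an [msa] object.
#' @param pwm An `msa_pwm` whose column count matches the row length.
#' @return A single score, or a named vector of per-sequence scores when
#'   `x` is an [msa].
#' @export
pwms <- function(x, pwm) {
  if (inherits(x, "msa")) {
    return(stats::setNames(
      vapply(seq_len(n_seq(x)), function(i) pwms(x$mat[i, ], pwm), 0),
      seq_ids(x)))
  }
  row <- as_residues(x)
  if (length(row) != pwm$source_columns)
    stop("row length ", length(row), " does not match PWM columns ",
         pwm$source_columns)
  use <- row != GAP & row %in% rownames(pwm$weights)
  if (!any(use)) return(0)
  sum(pwm$weights[cbind(match(row[use], rownames(pwm$weights)), which(use))])
}

#' PWM differential between two alignments
#'
#' `PWMD = sum(PWMS after) - sum(PWMS before)`: the total change in PWM
#' score across all sequences when residues are shifted along indels. A
#' positive PWMD means the `after` alignment is favoured. The PWM used for
#' scoring is dictated by `pwm_policy`: `"before"` (default) scores both
#' alignments under the PWM built from `aln_before`; `"after"` uses the
#' PWM from `aln_after`; `"refreshed"` scores each alignment under its own
#' PWM. An explicit `pwm` overrides the policy.
#'
#' Both alignments must contain the same sequences modulo gap placement;
#' if their column counts differ, shared-gap columns are dropped from both
#' before comparison.
#'
#' @param aln_before,aln_after [msa] objects.
#' @param pwm_policy `"before"`, `"after"` or `"refreshed"`.
#' @param pwm Optional `msa_pwm` used for both alignments.
#' @inheritParams build_pwm
#' @return Numeric PWMD (positive favours `aln_after`).
#' @export
pwmd <- function(aln_before, aln_after,
                 pwm_policy = c("before", "after", "refreshed"),
                 pwm = NULL, pseudocount_mass = 1, background = "uniform",
                 log_base = 2) {
  pwm_policy <- match.arg(pwm_policy)
  check_same_content(aln_before, aln_after)
  if (n_col(aln_before) != n_col(aln_after)) {
    aln_before <- drop_shared_gap_columns(aln_before)$alignment
    aln_after <- drop_shared_gap_columns(aln_after)$alignment
    if (n_col(aln_before) != n_col(aln_after))
      stop("alignments have irreconcilable column counts")
  }
  mk <- function(a) build_pwm(a, pseudocount_mass = pseudocount_mass,
                              background = background, log_base = log_base)
  if (!is.null(pwm)) {
    pb <- pa <- pwm
  } else if (pwm_policy == "before") {
    pb <- pa <- mk(aln_before)
  } else if (pwm_policy == "after") {
    pb <- pa <- mk(aln_after)
  } else {
    pb <- mk(aln_before); pa <- mk(aln_after)
  }
  sum(pwms(aln_after, pa)) - sum(pwms(aln_before, pb))
}

#' Write a PWM as tab-separated text
#'
#' Symbols as rows, 1-based site numbers as column headers.
#'
#' @param pwm An `msa_pwm`.
#' @param file Path to write to.
#' @param digits Number of decimal places.
#' @return `file`, invisibly.
#' @export
write_pwm <- function(pwm, file, digits = 4) {
  w <- round(pwm$weights, digits)
  colnames(w) <- seq_len(ncol(w))
  df <- data.frame(AA = rownames(w), w, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
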