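#' Load a substitution score matrix
#'
#' Loads the built-in BLOSUM62 matrix (from Biostrings, restricted to the
#' 20 standard amino acids) or parses an NCBI-format matrix file: optional
#' `#` comment lines, a header row of symbols, then a square integer body
#' with row labels. The unknown symbol (`X` for amino acids, `N` for
#' nucleotides) is scored 0 against every symbol unless the file provides
#' it, so ambiguity neither rewards nor penalises any placement.
#'
#' @param name_or_source `"BLOSUM62"`, a path to an NCBI-format matrix
#'   file, or a character vector of matrix text lines.
#' @param alphabet Alphabet the matrix is for (used to attach the unknown
#'   symbol); `"aa"` by default, `"nt"` for nucleotide matrices.
#' @return Symmetric numeric matrix with symbol dimnames.
#' @examples
#' m <- load_score_matrix("BLOSUM62")
#' m["T", "T"]  # 5
#' m["T", "I"]  # -1
#' @export
load_score_matrix <- function(name_or_source, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (length(name_or_source) == 1L && toupper(name_or_source) == "BLOSUM62") {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    return(add_unknown(m, "X"))
  }
  lines <- name_or_source
  if (length(lines) == 1L && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)
  else if (length(lines) == 1L) lines <- strsplit(lines, "\n")[[1L]]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix source has no header/body")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  syms <- toupper(vapply(body, `[`, "", 1L))
  vals <- lapply(body, function(x) suppressWarnings(as.numeric(x[-1L])))
  if (any(lengths(vals) != length(header)) || any(vapply(vals, anyNA, TRUE)))
    stop("incomplete matrix: body rows do not match header width")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(syms, toupper(header))
  m <- m[, rownames(m), drop = FALSE]
  if (!isSymmetric(unname(m)))
    stop("asymmetric matrix: score(a,b) must equal score(b,a)")
  add_unknown(m, unknown_symbol(alphabet))
}

add_unknown <- function(m, unk) {
  if (!(unk %in% rownames(m))) {
    m <- rbind(cbind(m, 0), 0)
    rownames(m)[nrow(m)] <- colnames(m)[ncol(m)] <- unk
  }
  m
}

#' Simple match/mismatch nucleotide matrix
#'
#' @param match,mismatch Scores for identical and differing nucleotides.
#' @return Symmetric 5x5 matrix over A, C, G, T, N (N scored 0).
#' @export
nt_score_matrix <- function(match = 5, mismatch = -4) {
  m <- matrix(mismatch, 4L, 4L, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  diag(m) <- match
  add_unknown(m, "N")
}

#' Define a scoring scheme
#'
#' A scoring scheme bundles a substitution matrix with a gap model and the
#' gap policies used throughout: columns gapped in both members of a pair
#' are always skipped (they neither score nor break a gap run), and
#' terminal gaps are penalised by default. Gap penalties are applied as
#' negative contributions: a gap run of length `k` costs `gap_open +
#' (k - 1) * gap_extend` in the affine model and `k * abs(gap)` in the
#' linear model.
#'
#' @param matrix Substitution matrix, e.g. from [load_score_matrix()].
#' @param gap_model `"linear"` or `"affine"`.
#' @param gap Per-gap-site score for the linear model (non-positive, e.g.
#'   `-6`).
#' @param gap_open,gap_extend Positive penalties for the affine model
#'   (`gap_open >= gap_extend >= 0`).
#' @param terminal_gaps `"penalized"` (default) or `"free"`: whether gap
#'   runs touching either end of a pairwise alignment are charged.
#' @param pair_weights Optional symmetric numeric matrix of weights
#'   `W[i, j]` for the weighted sum-of-pairs score; `NULL` means all 1.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scheme <- scoring_scheme(load_score_matrix("BLOSUM62"),
#'                          gap_model = "linear", gap = -6)
#' @export
scoring_scheme <- function(matrix,
                           gap_model = c("affine", "linear"),
                           gap = -6,
                           gap_open = 20, gap_extend = 2,
                           terminal_gaps = c("penalized", "free"),
                           pair_weights = NULL) {
  gap_model <- match.arg(gap_model)
  terminal_gaps <- match.arg(terminal_gaps)
  if (!isSymmetric(unname(as.matrix(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_model == "linear") {
    if (gap > 0) stop("linear gap score must be <= 0")
    go <- ge <- abs(gap)
  } else {
    if (!(gap_open >= gap_extend && gap_extend >= 0))
      stop("affine model requires gap_open >= gap_extend >= 0")
    go <- gap_open; ge <- gap_extend
  }
  if (!is.null(pair_weights) && !isSymmetric(unname(pair_weights)))
    stop("pair_weights must be a symmetric matrix")
  structure(list(matrix = matrix, gap_model = gap_model,
                 go = go, ge = ge,
                 terminal_gaps = terminal_gaps,
                 pair_weights = pair_weights),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  gm <- if (x$gap_model == "linear")
    sprintf("linear, %g per gap site", -x$go)
  else sprintf("affine, open %g extend %g (run cost open + (k-1)*extend)", x$go, x$ge)
  cat("Scoring scheme\n",
      "  matrix:        ", ncol(x$matrix), "x", ncol(x$matrix), " symbols\n",
      "  gap model:     ", gm, "\n",
      "  terminal gaps: ", x$terminal_gaps, "\n",
      "  pair weights:  ", if (is.null(x$pair_weights)) "uniform (1)" else "supplied", "\n",
      sep = "")
  invisible(x)
}

# cost of gap runs in one row of a pairwise alignment (shared-gap columns
# must already be removed); `gaps` is a logical vector marking gap sites
gap_run_cost <- function(gaps, scheme) {
  if (!any(gaps)) return(0)
  r <- rle(gaps)
  lens <- r$lengths[r$values]
  if (scheme$terminal_gaps == "free") {
    first_is_gap <- r$values[1L]
    last_is_gap <- r$values[length(r$values)]
    keep <- rep(TRUE, length(lens))
    if (first_is_gap) keep[1L] <- FALSE
    if (last_is_gap) keep[length(keep)] <- FALSE
    lens <- lens[keep]
    if (!length(lens)) return(0)
  }
  sum(scheme$go + (lens - 1L) * scheme$ge)
}
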