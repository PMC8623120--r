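#' @importFrom stats window
#' @importFrom utils head tail write.table
NULL

GAP <- "-"

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
NT_ALPHABET <- c("A", "C", "G", "T")

#' Symbols of an alignment alphabet
#'
#' Residue symbols for an alphabet tag, excluding the gap character.
#' Amino-acid alignments additionally admit `X` and nucleotide/codon
#' alignments admit `N` as an unknown-residue symbol; unknowns score zero
#' against everything and are excluded from position-weight-matrix counts.
#'
#' @param alphabet One of `"aa"`, `"nt"`, `"codon"`.
#' @param unknown Include the unknown symbol (`X` or `N`)?
#' @return Character vector of symbols.
#' @export
alphabet_symbols <- function(alphabet = c("aa", "nt", "codon"), unknown = TRUE) {
  alphabet <- match.arg(alphabet)
  base <- if (alphabet == "aa") AA_ALPHABET else NT_ALPHABET
  if (unknown) c(base, unknown_symbol(alphabet)) else base
}

unknown_symbol <- function(alphabet) {
  if (alphabet == "aa") "X" else "N"
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` is an ordered set of identically long gapped sequences over a
#' declared alphabet. Codon alignments are stored as nucleotide columns with
#' a reading-frame invariant: the ungapped length of every sequence and the
#' length of every gap run must be a multiple of 3.
#'
#' @param sequences Character vector of (gapped) sequence strings, a list of
#'   per-residue character vectors, or a character matrix with one row per
#'   sequence.
#' @param ids Sequence identifiers; defaults to names of `sequences` or
#'   `seq1`, `seq2`, ...
#' @param alphabet `"aa"` (amino acid), `"nt"` (nucleotide) or `"codon"`.
#' @return An object of class `msa`: a list with elements `mat` (character
#'   matrix, rows = sequences, `rownames` = ids) and `alphabet`.
#' @examples
#' aln <- msa(c(a = "AC-T", b = "ACGT"), alphabet = "nt")
#' n_col(aln)
#' @export
msa <- function(sequences, ids = NULL, alphabet = c("aa", "nt", "codon")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.character(sequences)) sequences <- strsplit(toupper(sequences), "")
    else sequences <- lapply(sequences, function(s) toupper(as.character(s)))
    if (is.null(ids)) ids <- names(sequences)
    lens <- lengths(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- if (!is.null(ids)) ids[which(lens != lens[1L])[1L]] else which(lens != lens[1L])[1L]
      stop("ragged lengths: sequence '", bad, "' does not match the first sequence")
    }
    mat <- matrix(unlist(sequences), nrow = length(sequences), byrow = TRUE)
  }
  mat[] <- toupper(mat)
  if (is.null(ids) || !length(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  blank <- !nzchar(ids) | is.na(ids)
  if (any(blank)) {
    warning("empty sequence id(s) replaced by placeholder")
    ids[blank] <- paste0("seq", which(blank))
  }
  rownames(mat) <- ids
  obj <- structure(list(mat = mat, alphabet = alphabet), class = "msa")
  validate_msa(obj)
  obj
}

validate_msa <- function(aln) {
  mat <- aln$mat
  ok <- alphabet_symbols(aln$alphabet)
  bad <- !(mat %in% c(ok, GAP))
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(mat))
    stop("symbol '", mat[idx[1L], idx[2L]], "' outside alphabet in sequence '",
         rownames(mat)[idx[1L]], "' at column ", idx[2L])
  }
  if (aln$alphabet == "codon") {
    for (i in seq_len(nrow(mat))) {
      row <- mat[i, ]
      if (sum(row != GAP) %% 3L != 0L)
        stop("codon frame violation: ungapped length of '", rownames(mat)[i],
             "' is not a multiple of 3")
      r <- rle(row == GAP)
      if (any(r$lengths[r$values] %% 3L != 0L))
        stop("gap run not multiple of 3 in sequence '", rownames(mat)[i], "'")
    }
  }
  invisible(aln)
}

#' @rdname msa
#' @param x,aln An `msa` object.
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @rdname msa
#' @export
n_col <- function(aln) ncol(aln$mat)

#' @rdname msa
#' @export
seq_ids <- function(aln) rownames(aln$mat)

#' @export
dim.msa <- function(x) dim(x$mat)

#' @export
as.character.msa <- function(x, ...) {
  stats::setNames(apply(x$mat, 1L, paste, collapse = ""), rownames(x$mat))
}

#' @export
print.msa <- function(x, n = 8L, width = 60L, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns (%s)\n",
              n_seq(x), n_col(x), x$alphabet))
  shown <- utils::head(seq_len(n_seq(x)), n)
  strs <- as.character.msa(x)[shown]
  trunc <- nchar(strs) > width
  strs[trunc] <- paste0(substr(strs[trunc], 1L, width - 3L), "...")
  cat(sprintf("  %-15s %s\n", substr(names(strs), 1L, 15L), strs), sep = "")
  if (n_seq(x) > n) cat("  ... and", n_seq(x) - n, "more sequences\n")
  invisible(x)
}

#' Remove gaps from a sequence
#'
#' @param x A character vector of residues or a single string.
#' @return Character vector of residues with gap characters removed.
#' @export
degap <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  x[x != GAP]
}

as_residues <- function(x) {
  if (length(x) == 1L && is.character(x)) x <- strsplit(toupper(x), "")[[1L]]
  toupper(as.character(x))
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA source (wrapped or unwrapped lines) into an
#' [msa] object, normalising residues to upper case and validating that all
#' rows have equal length, that every symbol belongs to the declared
#' alphabet (or is `-`, or the unknown symbol), and - for codon
#' alignments - that gap runs and ungapped lengths respect the reading
#' frame.
#'
#' @param source Path to a FASTA file, or a character vector of FASTA text
#'   lines.
#' @param alphabet `"aa"`, `"nt"` or `"codon"`.
#' @return An [msa] object.
#' @examples
#' aln <- read_fasta_alignment(c(">a", "AC-T", ">b", "ACGT"), alphabet = "nt")
#' @export
read_fasta_alignment <- function(source, alphabet = c("aa", "nt", "codon")) {
  alphabet <- match.arg(alphabet)
  if (length(source) > 1L || grepl("\n", source) || grepl("^>", source[1L])) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(unlist(strsplit(source, "\n")), tmp)
    source <- tmp
  }
  set <- Biostrings::readBStringSet(source)
  if (length(set) < 2L) stop("aligned FASTA must contain at least 2 records")
  ids <- sub("\\s.*$", "", names(set))
  msa(as.character(set), ids = ids, alphabet = alphabet)
}

#' Write an alignment as aligned FASTA
#'
#' Sequences are written at 60 characters per line; a read/write round trip
#' reproduces the alignment exactly (ids, order, residues).
#'
#' @param aln An [msa] object.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_fasta_alignment <- function(aln, file) {
  set <- Biostrings::BStringSet(as.character.msa(aln))
  Biostrings::writeXStringSet(set, file, width = 60L)
  invisible(file)
}

#' Extract a window of alignment columns
#'
#' Returns the sub-alignment spanning 1-based columns `first_site` to
#' `last_site` inclusive, preserving sequence order. Site numbering is
#' 1-based and column-oriented throughout the package.
#'
#' @param x An [msa] object.
#' @param first_site,last_site 1-based first and last column (inclusive).
#' @param ... Unused.
#' @return An [msa] with `last_site - first_site + 1` columns.
#' @examples
#' aln <- msa(c("ACDEF", "ACDEF"), alphabet = "aa")
#' n_col(window(aln, 2, 4))
#' @export
window.msa <- function(x, first_site, last_site = first_site, ...) {
  if (first_site < 1L || last_site > n_col(x) || first_site > last_site)
    stop("window out of range: [", first_site, ", ", last_site, "] for ",
         n_col(x), " columns")
  sub <- x$mat[, first_site:last_site, drop = FALSE]
  structure(list(mat = sub, alphabet = x$alphabet), class = "msa")
}

#' Delete columns that are gaps in every sequence
#'
#' Shared-gap columns carry no residue and arise routinely when residue
#' shifts vacate a site; under the skip-shared-gap scoring policy their
#' removal leaves the sum-of-pairs score unchanged. In codon alignments
#' only complete shared-gap triplets are removed, preserving the frame
#' invariant.
#'
#' @param aln An [msa] object.
#' @return A list with elements `alignment` (the reduced [msa]) and
#'   `removed` (ascending 1-based indices of deleted columns in the original
#'   coordinates; empty when nothing was removed).
#' @export
drop_shared_gap_columns <- function(aln) {
  all_gap <- colSums(aln$mat != GAP) == 0L
  remove <- all_gap
  if (aln$alphabet == "codon" && any(all_gap)) {
    # remove only maximal all-gap stretches in multiples of 3, left-anchored
    remove <- rep(FALSE, length(all_gap))
    r <- rle(all_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      keep3 <- (r$lengths[k] %/% 3L) * 3L
      if (keep3 > 0L) remove[starts[k]:(starts[k] + keep3 - 1L)] <- TRUE
    }
  }
  if (!any(remove)) return(list(alignment = aln, removed = integer(0)))
  out <- structure(list(mat = aln$mat[, !remove, drop = FALSE],
                        alphabet = aln$alphabet), class = "msa")
  list(alignment = out, removed = which(remove))
}
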