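#' Enumerate residue-shift moves
#'
#' A move slides a contiguous residue block of one sequence across part of
#' an adjacent gap run, preserving the sequence's degapped content. Every
#' residue block of length at most `max_block` that touches a gap run
#' yields one candidate per slide distance `1..min(run length, max_slide)`.
#' In codon mode (`frame_step = 3`) block lengths and slide distances are
#' multiples of 3, so shifts never break the reading frame. Moves are
#' returned in deterministic order: ascending sequence index, block start
#' column, block length, slide distance.
#'
#' @param aln An [msa] object.
#' @param frame_step 1 (residue mode) or 3 (codon mode).
#' @param max_block Largest block length considered (in columns).
#' @param max_slide Largest slide distance considered; `Inf` means the full
#'   gap-run length.
#' @return Data frame of moves with columns `seq`, `block_start`,
#'   `block_len`, `direction` (`"left"`/`"right"`: the side the block
#'   slides toward), `slide`. Zero rows for a gap-free alignment.
#' @export
enumerate_moves <- function(aln, frame_step = 1L, max_block = 10L,
                            max_slide = Inf) {
  stopifnot(frame_step %in% c(1L, 3L))
  out <- list()
  for (s in seq_len(n_seq(aln))) {
    row <- aln$mat[s, ]
    r <- rle(row == GAP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      g0 <- starts[k]; g <- r$lengths[k]
      slides <- seq.int(frame_step, min(g, max_slide), by = frame_step)
      if (!length(slides) || slides[1L] > min(g, max_slide)) next
      # residue run to the left of the gap: suffix blocks slide right
      if (k > 1L && !r$values[k - 1L]) {
        R <- r$lengths[k - 1L]
        for (l in seq.int(frame_step, min(R, max_block), by = frame_step))
          for (d in slides)
            out[[length(out) + 1L]] <-
              list(seq = s, block_start = g0 - l, block_len = l,
                   direction = "right", slide = d)
      }
      # residue run to the right: prefix blocks slide left
      if (k < length(r$values) && !r$values[k + 1L]) {
        R <- r$lengths[k + 1L]
        for (l in seq.int(frame_step, min(R, max_block), by = frame_step))
          for (d in slides)
            out[[length(out) + 1L]] <-
              list(seq = s, block_start = g0 + g, block_len = l,
                   direction = "left", slide = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq = integer(0), block_start = integer(0),
                      block_len = integer(0), direction = character(0),
                      slide = integer(0)))
  }
  mv <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  mv <- mv[order(mv$seq, mv$block_start, mv$block_len, mv$slide), , drop = FALSE]
  rownames(mv) <- NULL
  mv
}

# shift one row according to a move; returns the modified residue vector
shift_row <- function(row, move) {
  b <- move$block_start; l <- move$block_len; d <- move$slide
  blk <- b:(b + l - 1L)
  if (any(row[blk] == GAP)) stop("stale move: block positions are not all residues")
  if (move$direction == "right") {
    gap_cols <- (b + l):(b + l + d - 1L)
    if (max(gap_cols) > length(row) || any(row[gap_cols] != GAP))
      stop("stale move: gap run does not match current alignment")
    row[c(blk, gap_cols)] <- c(rep(GAP, d), row[blk])
  } else {
    gap_cols <- (b - d):(b - 1L)
    if (min(gap_cols) < 1L || any(row[gap_cols] != GAP))
      stop("stale move: gap run does not match current alignment")
    row[c(gap_cols, blk)] <- c(row[blk], rep(GAP, d))
  }
  row
}

#' Apply a residue-shift move to an alignment
#'
#' Permutes only the target sequence's characters: its degapped content,
#' every other sequence, and the column count are unchanged. Applying a
#' move and then its inverse (same block at its new start, opposite
#' direction, same slide) restores the original alignment.
#'
#' @param aln An [msa] object.
#' @param move A one-row data frame or list with fields `seq`,
#'   `block_start`, `block_len`, `direction`, `slide` (see
#'   [enumerate_moves()]).
#' @return The shifted [msa]. A move that does not match the current gap
#'   structure raises a "stale move" error.
#' @export
apply_move <- function(aln, move) {
  move <- as.list(move)
  s <- move$seq
  if (is.null(s) || s < 1L || s > n_seq(aln)) stop("move has invalid sequence index")
  aln$mat[s, ] <- shift_row(aln$mat[s, ], move)
  aln
}

criterion_choices <- c("SPS", "WSPS", "PAI", "PWMD")

# per-move improvement deltas, given precomputed state
move_deltas <- function(aln, moves, criterion, scheme, pwm = NULL) {
  N <- n_seq(aln)
  deltas <- numeric(nrow(moves))
  W <- scheme$pair_weights
  base_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(moves))) {
    mv <- as.list(moves[k, ])
    s <- mv$seq
    row0 <- aln$mat[s, ]
    row1 <- shift_row(row0, mv)
    if (criterion == "PWMD") {
      deltas[k] <- pwms(row1, pwm) - pwms(row0, pwm)
    } else {
      key <- as.character(s)
      if (is.null(base_cache[[key]])) {
        base_cache[[key]] <- vapply(seq_len(N), function(j)
          if (j == s) 0 else implied_pair_score(row0, aln$mat[j, ], scheme), 0)
      }
      base <- base_cache[[key]]
      d <- 0
      for (j in seq_len(N)) {
        if (j == s) next
        wij <- if (!is.null(W) && criterion == "WSPS") W[s, j] else 1
        d <- d + wij * (implied_pair_score(row1, aln$mat[j, ], scheme) - base[j])
      }
      deltas[k] <- d
    }
  }
  deltas
}

#' Greedy post-alignment refinement
#'
#' Iteratively improves an alignment under one criterion. Each sweep
#' enumerates all residue-shift moves, evaluates their improvement, and
#' applies the single best strictly improving move (delta > `tolerance`;
#' ties broken by enumeration order); shared-gap columns created by the
#' move are then deleted. For the PWMD criterion the position weight
#' matrix is rebuilt at the start of each sweep, not per move, so deltas
#' within a sweep are additive. Refinement stops when no move improves or
#' after `max_sweeps` sweeps (in which case `converged` is `FALSE`).
#'
#' The search is deterministic: identical inputs and settings always give
#' identical output. PAI improvement is evaluated through implied scores
#' only, since a move never changes the degapped sequences and hence never
#' changes the optimal pair scores.
#'
#' @param aln An [msa] object.
#' @param criterion `"SPS"`, `"WSPS"`, `"PAI"` or `"PWMD"`.
#' @param scheme A [scoring_scheme()]; required for SPS/WSPS/PAI, used
#'   only for reporting initial/final values under PWMD (may be `NULL`).
#' @param pwm_settings List of [build_pwm()] settings for PWMD:
#'   `pseudocount_mass`, `background`, `log_base`.
#' @param frame_step 1 or 3; codon alignments require 3.
#' @param max_sweeps Sweep budget.
#' @param tolerance Smallest delta counted as an improvement (> 0).
#' @param max_block,max_slide Move-neighbourhood bounds, see
#'   [enumerate_moves()].
#' @param seed Reserved for optional randomized move sampling; the default
#'   pipeline is deterministic and ignores it.
#' @return An object of class `msa_refinement`: list with `alignment`
#'   (refined [msa]), `initial` (input), `criterion`, `moves` (log of
#'   accepted moves: sweep, coordinates, delta, moves evaluated),
#'   `deleted` (sweep, original column index of each deleted shared-gap
#'   column), `initial_value`/`final_value` (criterion values; for PWMD
#'   the cumulative differential from 0), `final_delta_total`, `sweeps`,
#'   `converged`.
#' @export
greedy_refine <- function(aln,
                          criterion = c("SPS", "WSPS", "PAI", "PWMD"),
                          scheme = NULL,
                          pwm_settings = list(),
                          frame_step = if (aln$alphabet == "codon") 3L else 1L,
                          max_sweeps = 50L,
                          tolerance = 1e-9,
                          max_block = 10L, max_slide = Inf,
                          seed = NULL) {
  criterion <- match.arg(criterion)
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (aln$alphabet == "codon" && frame_step != 3L)
    stop("codon alignments require frame_step = 3")
  if (criterion != "PWMD" && is.null(scheme))
    stop("criterion ", criterion, " requires a scoring scheme")
  ps <- pwm_settings
  mk_pwm <- function(a) build_pwm(
    a,
    pseudocount_mass = ps$pseudocount_mass %||% 1,
    background = ps$background %||% "uniform",
    log_base = ps$log_base %||% 2)
  crit_value <- function(a) switch(criterion,
    SPS = sps(a, scheme), WSPS = wsps(a, scheme),
    PAI = pai(a, scheme), PWMD = NA_real_)

  initial <- aln
  initial_value <- crit_value(aln)
  log_rows <- list()
  del_rows <- list()
  converged <- FALSE
  sweep <- 0L
  total <- 0
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    pwm <- if (criterion == "PWMD") mk_pwm(aln) else NULL
    moves <- enumerate_moves(aln, frame_step = frame_step,
                             max_block = max_block, max_slide = max_slide)
    if (!nrow(moves)) { converged <- TRUE; sweep <- sweep - 1L; break }
    deltas <- move_deltas(aln, moves, criterion, scheme, pwm)
    best <- which.max(deltas)
    if (deltas[best] <= tolerance) { converged <- TRUE; sweep <- sweep - 1L; break }
    mv <- as.list(moves[best, ])
    aln <- apply_move(aln, mv)
    total <- total + deltas[best]
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      sweep = sweep, seq = mv$seq, block_start = mv$block_start,
      block_len = mv$block_len, direction = mv$direction, slide = mv$slide,
      criterion = criterion, delta = deltas[best],
      n_evaluated = nrow(moves), accepted = TRUE)
    dropped <- drop_shared_gap_columns(aln)
    aln <- dropped$alignment
    if (length(dropped$removed))
      del_rows[[length(del_rows) + 1L]] <- data.frame(
        sweep = sweep, column = dropped$removed)
  }
  if (!converged)
    warning("refinement stopped at max_sweeps = ", max_sweeps,
            " before convergence; returning best alignment so far")
  res <- structure(list(
    alignment = aln,
    initial = initial,
    criterion = criterion,
    scheme = scheme,
    pwm_settings = ps,
    frame_step = frame_step,
    moves = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(sweep = integer(0), seq = integer(0), block_start = integer(0),
                 block_len = integer(0), direction = character(0),
                 slide = integer(0), criterion = character(0),
                 delta = numeric(0), n_evaluated = integer(0),
                 accepted = logical(0)),
    deleted = if (length(del_rows)) do.call(rbind, del_rows) else
      data.frame(sweep = integer(0), column = integer(0)),
    initial_value = initial_value,
    final_value = if (criterion == "PWMD") total else crit_value(aln),
    final_delta_total = total,
    sweeps = sweep,
    converged = converged), class = "msa_refinement")
  if (criterion == "PWMD") {
    res$initial_value <- 0
    res$final_value <- total
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msa_refinement <- function(x, ...) {
  cat(sprintf("Greedy alignment refinement under %s\n", x$criterion))
  cat(sprintf("  %d sequences, %d -> %d columns\n", n_seq(x$initial),
              n_col(x$initial), n_col(x$alignment)))
  cat(sprintf("  accepted moves: %d in %d sweep(s); %s\n", nrow(x$moves),
              x$sweeps, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  criterion: %.4f -> %.4f (total improvement %.4f)\n",
              x$initial_value, x$final_value, x$final_delta_total))
  invisible(x)
}

#' @export
summary.msa_refinement <- function(object, ...) {
  print(object)
  if (nrow(object$moves)) {
    cat("\nAccepted moves:\n")
    print(object$moves, row.names = FALSE)
  }
  if (nrow(object$deleted)) {
    cat("\nShared-gap columns deleted (1-based, coordinates at deletion time):\n")
    print(object$deleted, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the criterion trajectory of a refinement
#'
#' Cumulative criterion improvement after each accepted move.
#'
#' @param x An `msa_refinement`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.msa_refinement <- function(x, ...) {
  traj <- c(0, cumsum(x$moves$delta))
  graphics::plot(seq_along(traj) - 1L, x$initial_value + traj, type = "s",
                 xlab = "accepted moves",
                 ylab = paste(x$criterion, "value"),
                 main = sprintf("Refinement trajectory (%s)", x$criterion), ...)
  invisible(x)
}

#' Replay a refinement log
#'
#' Re-applies the accepted moves and shared-gap column deletions of a
#' refinement, in order, to the alignment it started from; the result is
#' exactly the refined alignment.
#'
#' @param aln The input [msa] (typically `refinement$initial`).
#' @param refinement An `msa_refinement` (or a list with `moves` and
#'   `deleted` data frames in the same layout).
#' @return The replayed [msa].
#' @export
replay_refinement <- function(aln, refinement) {
  mv <- refinement$moves
  del <- refinement$deleted
  for (k in seq_len(nrow(mv))) {
    aln <- apply_move(aln, as.list(mv[k, c("seq", "block_start", "block_len",
                                           "direction", "slide")]))
    cols <- del$column[del$sweep == mv$sweep[k]]
    if (length(cols)) {
      keep <- setdiff(seq_len(n_col(aln)), cols)
      aln <- structure(list(mat = aln$mat[, keep, drop = FALSE],
                            alphabet = aln$alphabet), class = "msa")
    }
  }
  aln
}

#' Serialize a refinement log
#'
#' Writes the accepted-move log (and deleted columns) as tab-separated
#' text or structured JSON; all coordinates are 1-based.
#'
#' @param refinement An `msa_refinement`.
#' @param file Path to write to.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_refinement_log <- function(refinement, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(refinement$moves, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(criterion = refinement$criterion,
           converged = refinement$converged,
           sweeps = refinement$sweeps,
           initial_value = refinement$initial_value,
           final_value = refinement$final_value,
           final_delta_total = refinement$final_delta_total,
           moves = refinement$moves,
           deleted_columns = refinement$deleted),
      file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Tabulate candidate moves under all three criteria
#'
#' Evaluates every candidate move under SPS, PAI and PWMD simultaneously
#' and flags sign disagreements - moves that one criterion favours and
#' another rejects. SPS and PAI improvements coincide move-by-move (a move
#' leaves optimal pair scores untouched), so disagreements arise between
#' the pairwise criteria and PWMD, as when relocating a minority residue
#' into a sparsely occupied column gains PWM score but splits gap runs of
#' its partners.
#'
#' @param aln An [msa] object.
#' @param scheme A [scoring_scheme()] for SPS/PAI.
#' @param pwm_settings List of [build_pwm()] settings (see
#'   [greedy_refine()]).
#' @param frame_step,max_block,max_slide See [enumerate_moves()].
#' @return Data frame of moves with `delta_sps`, `delta_pai`,
#'   `delta_pwmd` and logical `conflict`; zero rows for a gap-free
#'   alignment.
#' @export
explain_conflict <- function(aln, scheme, pwm_settings = list(),
                             frame_step = if (aln$alphabet == "codon") 3L else 1L,
                             max_block = 10L, max_slide = Inf) {
  moves <- enumerate_moves(aln, frame_step = frame_step,
                           max_block = max_block, max_slide = max_slide)
  ps <- pwm_settings
  if (!nrow(moves)) {
    moves$delta_sps <- moves$delta_pai <- moves$delta_pwmd <- numeric(0)
    moves$conflict <- logical(0)
    return(moves)
  }
  pwm <- build_pwm(aln,
                   pseudocount_mass = ps$pseudocount_mass %||% 1,
                   background = ps$background %||% "uniform",
                   log_base = ps$log_base %||% 2)
  d_sps <- move_deltas(aln, moves, "SPS", scheme)
  d_pwm <- move_deltas(aln, moves, "PWMD", scheme, pwm)
  moves$delta_sps <- d_sps
  moves$delta_pai <- d_sps  # PAI improvement equals the SPS delta per move
  moves$delta_pwmd <- d_pwm
  moves$conflict <- (d_sps > 0 & d_pwm < 0) | (d_sps < 0 & d_pwm > 0)
  moves
}
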