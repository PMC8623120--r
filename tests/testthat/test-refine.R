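test_that("move enumeration finds boundary blocks, in deterministic order", {
  fx <- make_shift_fixture("ace2", seed = 1)
  mv <- enumerate_moves(fx$perturbed)
  s <- fx$truth$seq
  # the recovery move: slide the displaced T one column left across the gap
  expect_true(any(mv$seq == s & mv$block_start == 21 & mv$block_len == 1 &
                    mv$direction == "left" & mv$slide == 1))
  # deterministic ordering
  expect_identical(mv, mv[order(mv$seq, mv$block_start, mv$block_len,
                                mv$slide), ])
  # gap-free alignment yields no moves
  expect_equal(nrow(enumerate_moves(msa(c("ARND", "ARND"), alphabet = "aa"))),
               0L)
})

test_that("codon-mode enumeration only emits frame-respecting moves", {
  aln <- msa(c("ATG---GGA", "ATGCCAGGA", "ATGCCAGGA"), alphabet = "codon")
  mv <- enumerate_moves(aln, frame_step = 3)
  expect_true(nrow(mv) > 0)
  expect_true(all(mv$block_len %% 3 == 0))
  expect_true(all(mv$slide %% 3 == 0))
  # blocks adjacent to the triplet gap on both sides are present
  expect_true(any(mv$block_start == 1 & mv$direction == "right" & mv$slide == 3))
  expect_true(any(mv$block_start == 7 & mv$direction == "left" & mv$slide == 3))
})

test_that("applying a move permutes one sequence only and is invertible", {
  fx <- make_shift_fixture("random", n_seq = 6, n_col = 25, seed = 4)
  mv <- fx$truth
  after <- apply_move(fx$perturbed, mv)
  s <- mv$seq
  expect_identical(after$mat[-s, ], fx$perturbed$mat[-s, ])
  expect_identical(degap(after$mat[s, ]), degap(fx$perturbed$mat[s, ]))
  expect_equal(n_col(after), n_col(fx$perturbed))
  inverse <- mv
  inverse$block_start <- if (mv$direction == "left") mv$block_start - mv$slide
                         else mv$block_start + mv$slide
  inverse$direction <- if (mv$direction == "left") "right" else "left"
  expect_identical(apply_move(after, inverse)$mat, fx$perturbed$mat)
  # a stale move is rejected
  expect_error(apply_move(after, mv), "stale move")
})

test_that("greedy SPS refinement fixes the worked example in one move", {
  fx <- make_shift_fixture("ace2", seed = 1)
  r <- greedy_refine(fx$perturbed, "SPS", scheme_linear6)
  expect_true(r$converged)
  expect_equal(nrow(r$moves), 1L)
  expect_equal(r$moves$delta, 24)
  expect_identical(r$alignment$mat, fx$clean$mat)
  expect_equal(r$final_value - r$initial_value, 24)
  # refining the already-optimal alignment is the identity
  r2 <- greedy_refine(fx$clean, "SPS", scheme_linear6)
  expect_equal(nrow(r2$moves), 0L)
  expect_identical(r2$alignment$mat, fx$clean$mat)
})

test_that("codon fixture is recovered under SPS with frame step 3 and the
           frame guard rejects step 1", {
  fx <- make_codon_fixture(seed = 1)
  sch <- scoring_scheme(nt_score_matrix(), gap_model = "linear", gap = -6)
  expect_gt(sps(fx$clean, sch), sps(fx$perturbed, sch))
  r <- greedy_refine(fx$perturbed, "SPS", sch, frame_step = 3)
  expect_identical(r$alignment$mat, fx$clean$mat)
  expect_error(greedy_refine(fx$perturbed, "SPS", sch, frame_step = 1),
               "frame_step = 3")
})

test_that("refinement preserves degapped content, is monotone, deterministic
           and idempotent", {
  for (seed in c(2, 9, 15)) {
    fx <- make_shift_fixture("random", n_seq = 7, n_col = 28, seed = seed)
    for (crit in c("SPS", "PWMD")) {
      r <- greedy_refine(fx$perturbed, crit, scheme_linear6)
      for (i in seq_len(n_seq(fx$perturbed)))
        expect_identical(degap(r$alignment$mat[i, ]),
                         degap(fx$perturbed$mat[i, ]))
      expect_true(all(r$moves$delta > 0))
      expect_equal(r$final_delta_total, sum(r$moves$delta))
      if (crit != "PWMD")
        expect_gte(r$final_value, r$initial_value)
      # determinism
      r2 <- greedy_refine(fx$perturbed, crit, scheme_linear6)
      expect_identical(r2$alignment$mat, r$alignment$mat)
      expect_identical(r2$moves, r$moves)
      # idempotence on the converged alignment
      r3 <- greedy_refine(r$alignment, crit, scheme_linear6)
      expect_equal(nrow(r3$moves), 0L)
      expect_identical(r3$alignment$mat, r$alignment$mat)
    }
  }
})

test_that("replaying the log reproduces the refined alignment exactly", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  r <- greedy_refine(fx$perturbed, "PWMD", max_sweeps = 60)
  expect_true(r$converged)
  expect_identical(replay_refinement(r$initial, r)$mat, r$alignment$mat)
  # and for an SPS run on a random fixture
  fx2 <- make_shift_fixture("random", n_seq = 6, n_col = 24, seed = 12)
  r2 <- greedy_refine(fx2$perturbed, "SPS", scheme_linear6)
  expect_identical(replay_refinement(r2$initial, r2)$mat, r2$alignment$mat)
})

test_that("hitting the sweep budget warns and flags non-convergence", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  expect_warning(r <- greedy_refine(fx$perturbed, "PWMD", max_sweeps = 1),
                 "max_sweeps")
  expect_false(r$converged)
  expect_equal(nrow(r$moves), 1L)
})

test_that("WSPS refinement honours pair weights", {
  fx <- make_shift_fixture("ace2", seed = 1)
  W <- matrix(1, 11, 11)
  schW <- scoring_scheme(blosum62, gap_model = "linear", gap = -6,
                         pair_weights = W)
  r <- greedy_refine(fx$perturbed, "WSPS", schW)
  expect_identical(r$alignment$mat, fx$clean$mat)
  expect_equal(r$moves$delta, 24)
})

test_that("refinement log serializes to TSV and JSON", {
  fx <- make_shift_fixture("ace2", seed = 1)
  r <- greedy_refine(fx$perturbed, "SPS", scheme_linear6)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".json")
  write_refinement_log(r, f1, "tsv")
  expect_equal(utils::read.delim(f1)$delta, 24)
  write_refinement_log(r, f2, "json")
  j <- jsonlite::read_json(f2)
  expect_equal(j$criterion, "SPS")
  expect_equal(j$moves[[1]]$delta, 24)
  expect_true(j$converged)
})

test_that("explain_conflict flags PWMD-vs-SPS disagreements on the
           huntingtin preset and none on the concordant example", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  ec <- explain_conflict(fx$perturbed, scheme_affine)
  expect_true(any(ec$delta_pwmd > 0 & ec$delta_sps < 0))
  expect_true(any(ec$conflict))
  expect_equal(ec$delta_pai, ec$delta_sps)
  # worked-example window: the three criteria agree in sign on the
  # recovery move
  fa <- make_shift_fixture("ace2", seed = 1)
  eca <- explain_conflict(fa$perturbed, scheme_linear6)
  rec <- eca[eca$seq == fa$truth$seq & eca$block_start == 21 &
               eca$block_len == 1 & eca$slide == 1 &
               eca$direction == "left", ]
  expect_equal(nrow(rec), 1L)
  expect_gt(rec$delta_sps, 0)
  expect_gt(rec$delta_pwmd, 0)
  expect_false(rec$conflict)
  # gap-free alignment: empty report
  expect_equal(nrow(explain_conflict(msa(c("ARND", "ARND"), alphabet = "aa"),
                                     scheme_linear6)), 0L)
})

test_that("huntingtin SPS ordering mirrors the criterion conflict: the
           pairwise criteria favour the pre-refinement alignment", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  expect_gt(sps(fx$perturbed, scheme_affine), sps(fx$clean, scheme_affine))
  # while the PWM differential favours the refined placement
  expect_gt(pwmd(fx$perturbed, fx$clean, pwm_policy = "before"), 0)
})
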