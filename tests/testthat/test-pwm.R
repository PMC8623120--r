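test_that("column counts exclude gaps and unknowns and sum to n_seq", {
  fx <- make_shift_fixture("ace2", seed = 1)
  cc <- column_counts(fx$clean)
  # in the clean state all 11 sequences bear T at site 20
  expect_equal(unname(cc["T", 20]), 11)
  expect_equal(sum(cc[, 21]), 10)     # one gap in the shifted sequence
  # gaps + unknowns + counts account for every sequence in every column
  aln <- msa(c("AX-", "A-C", "AAC"), alphabet = "aa")
  cc2 <- column_counts(aln)
  gaps <- colSums(aln$mat == "-")
  unk <- colSums(aln$mat == "X")
  expect_equal(colSums(cc2) + gaps + unk, rep(3, 3), ignore_attr = TRUE)
  expect_true(all(column_counts(msa(c("-", "-", "-"), alphabet = "aa")) == 0))
})

test_that("huntingtin preset carries the minority-P / sparse-P columns", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  cc <- column_counts(fx$perturbed)
  # boundary column: 12 Q mixed with 3 P
  expect_equal(unname(cc["Q", 29]), 12)
  expect_equal(unname(cc["P", 29]), 3)
  # sparse downstream column: 2 P and nothing else
  expect_equal(unname(cc["P", 34]), 2)
  expect_equal(sum(cc[, 34]), 2)
})

test_that("PWM weights follow the log-odds closed form and sign pattern", {
  # two sequences, one column, both T: w = log2(((2 + 0.05)/(2 + 1))/(1/20))
  aln <- msa(c("T", "T"), alphabet = "aa")
  p <- build_pwm(aln)
  expect_equal(unname(p$weights["T", 1]), log2(((2 + 0.05) / 3) / 0.05))
  expect_equal(unname(p$weights["A", 1]), log2(((0 + 0.05) / 3) / 0.05))
  # unanimous column: occupant positive, all others negative and equal
  fx <- make_shift_fixture("ace2", seed = 1)
  pw <- build_pwm(fx$clean)
  expect_gt(pw$weights["T", 20], 0)
  others <- setdiff(rownames(pw$weights), "T")
  expect_true(all(pw$weights[others, 20] < 0))
  expect_equal(unname(diff(range(pw$weights[others, 20]))), 0)
  # mixed column: both occupants positive, majority larger, rest at floor
  p21 <- build_pwm(window(fx$clean, 21, 21))
  expect_gt(p21$weights["T", 1], p21$weights["I", 1])
  expect_gt(p21$weights["I", 1], 0)
  expect_true(all(p21$weights[setdiff(rownames(p21$weights), c("T", "I")), 1] < 0))
  expect_error(build_pwm(aln, pseudocount_mass = 0), "pseudocount")
})

test_that("weights are strictly monotone in the column count", {
  counts <- matrix(0L, 20, 3, dimnames = list(alphabet_symbols("aa", FALSE),
                                              NULL))
  counts["Q", ] <- c(3L, 7L, 12L)
  counts["P", ] <- c(12L, 8L, 3L)   # keep N_j = 15 fixed
  p <- build_pwm(counts)
  expect_true(all(diff(p$weights["Q", ]) > 0))
  expect_true(all(diff(p$weights["P", ]) < 0))
  # count ordering matches weight ordering within each column
  for (j in 1:3)
    expect_equal(order(p$weights[c("Q", "P"), j]),
                 order(counts[c("Q", "P"), j]))
})

test_that("PWMS sums occupied-site weights, is additive over column blocks
           and ignores shared-gap columns", {
  fx <- make_shift_fixture("ace2", seed = 1)
  p <- build_pwm(fx$clean)
  expect_equal(pwms(rep("-", 25), p), 0)
  row <- fx$clean$mat[2, ]
  full <- pwms(row, p)
  k <- 10
  pL <- pwm_from_weights(p$weights[, 1:k])
  pR <- pwm_from_weights(p$weights[, (k + 1):25])
  expect_equal(pwms(row[1:k], pL) + pwms(row[(k + 1):25], pR), full)
  expect_error(pwms(row[1:10], p), "does not match")
  # one-column PWM with an explicit tabulated weight
  p1 <- pwm_from_weights(matrix(4.2457, 1, 1, dimnames = list("T", NULL)))
  expect_equal(pwms("T", p1), 4.2457)
  # inserting a shared-gap column changes no sequence's PWMS
  ins <- cbind(fx$clean$mat[, 1:10], "-", fx$clean$mat[, 11:25])
  aln_ins <- msa(ins, alphabet = "aa")
  p_ins <- pwm_from_weights(cbind(p$weights[, 1:10], 0, p$weights[, 11:25]))
  expect_equal(unname(pwms(aln_ins, p_ins)), unname(pwms(fx$clean, p)))
})

test_that("PWMD of the tabulated T-relocation move is 0.6481", {
  # published partial PWM for the 11-sequence example at sites 20-21;
  # site 20 weights from the post-move alignment's table, site 21 from the
  # pre-move alignment's, which is the arithmetic the worked example uses
  # (0.6481 = 4.2457 - 3.5976)
  w <- matrix(c(
    -3.4621, -3.4621, -3.4632, -3.4632, -3.4620, -3.4620, -3.4625, -3.4625,
    -3.4757, -3.4757, -3.4632, -3.4632, -3.4616, -3.4616, -3.4625, -3.4625,
    -3.4673, -3.4673, -3.4628,  2.9353, -3.4612, -3.4612, -3.4624, -3.4624,
    -3.4645, -3.4645, -3.4629, -3.4629, -3.4628, -3.4628, -3.4619, -3.4619,
     4.2457,  3.5976, -3.4649, -3.4649, -3.4632, -3.4632, -3.4621, -3.4621),
    nrow = 20, byrow = TRUE,
    dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                    NULL))
  tab <- pwm_from_weights(w)
  fx <- make_shift_fixture("ace2", seed = 1)
  before <- window(fx$perturbed, 20, 21)   # "-T" in the shifted sequence
  after <- window(fx$clean, 20, 21)        # "T-"
  expect_equal(pwmd(before, after, pwm = tab), 0.6481)
})

test_that("PWMD identities: zero on identity, antisymmetry, permutation
           invariance", {
  fx <- make_shift_fixture("ace2", seed = 2)
  a <- fx$perturbed; b <- fx$clean
  for (pol in c("before", "after", "refreshed"))
    expect_equal(pwmd(a, a, pwm_policy = pol), 0)
  # antisymmetry under fixed-PWM policies
  p <- build_pwm(a)
  expect_equal(pwmd(a, b, pwm = p), -pwmd(b, a, pwm = p))
  expect_equal(pwmd(a, b, pwm_policy = "before"),
               -pwmd(b, a, pwm_policy = "after"))
  # swapping two identical residues within a sequence changes nothing
  aln <- msa(c("QQP", "QQP", "QPP"), alphabet = "aa")
  swapped <- aln
  swapped$mat[1, c(1, 2)] <- swapped$mat[1, c(2, 1)]
  expect_equal(pwmd(aln, swapped, pwm_policy = "before"), 0)
  # the worked-example move is favoured under PWMs from either state
  expect_gt(pwmd(a, b, pwm_policy = "before"), 0)
  expect_gt(pwmd(a, b, pwm_policy = "after"), 0)
})

test_that("moving a residue to a column where its weight is larger gives
           strictly positive PWMD", {
  checked <- 0L
  for (i in 1:25) {
    fx <- make_shift_fixture("random", n_seq = 6, n_col = 20, seed = 100 + i)
    mv <- fx$truth
    if (mv$block_len != 1L) next
    p <- build_pwm(fx$perturbed)
    src <- mv$block_start
    dest <- src + if (mv$direction == "right") mv$slide else -mv$slide
    res <- fx$perturbed$mat[mv$seq, src]
    if (p$weights[res, dest] > p$weights[res, src]) {
      expect_gt(pwmd(fx$perturbed, apply_move(fx$perturbed, mv), pwm = p), 0)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 3L)
})

test_that("PWM serialization writes the tabular site layout", {
  fx <- make_shift_fixture("ace2", seed = 1)
  p <- build_pwm(fx$clean)
  f <- tempfile(fileext = ".tsv")
  write_pwm(p, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$AA, rownames(p$weights))
  expect_equal(back[["20"]], unname(round(p$weights[, 20], 4)))
})

test_that("empirical background shifts weights but keeps count ordering", {
  fx <- make_shift_fixture("huntingtin", seed = 1)
  p <- build_pwm(fx$perturbed, background = "empirical")
  expect_equal(sum(p$background), 1)
  cc <- column_counts(fx$perturbed)
  j <- 29
  expect_gt(p$weights["Q", j], p$weights["P", j])  # 12 Q vs 3 P
})
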