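# msarefine

Post-alignment evaluation and automatic refinement of multiple sequence
alignments (MSAs).

Progressive aligners freeze early pairwise decisions; when two gap
placements are momentarily equivalent the aligner picks one, and the pick
can become wrong once more sequences join the profile. Iterating the guide
tree does not repair such errors. `msarefine` is for anyone who feeds MSAs
into phylogenetics or comparative analysis and wants those frozen
suboptimal placements found and fixed with an explicit, reproducible
criterion instead of by eye.

## What it computes

For an alignment of *N* sequences:

* **SPS / WSPS** — sum-of-pairs score: `Σ_{i<j} W_ij S_ij.MSA` over the
  `N(N−1)/2` implied pairwise alignments, shared gaps skipped, with a
  linear or affine gap model (affine run cost `GO + (k−1)·GE`). Unit
  weights give plain SPS.
* **PAI** — pairwise alignment inconsistency:
  `Σ S_ij − Σ S_ij.MSA ≥ 0`, where `S_ij` is the optimal global pairwise
  score from the built-in Needleman–Wunsch/Gotoh aligner. Zero means every
  pair attains its optimum; larger is worse.
* **PWM / PWMS / PWMD** — per-column log-odds weights
  `w_aj = log2(((n_aj + c_a)/(N_j + Σc))/p_a)` with background-
  proportional pseudocounts; PWMS is a sequence's summed weights, and
  `PWMD = Σ PWMS_after − Σ PWMS_before` scores a candidate adjustment
  using information from *all* sequences at once, with no dynamic
  programming.
* **Greedy refinement** — `greedy_refine()` slides contiguous residue
  blocks across adjacent gap runs (codon-aware with `frame_step = 3`),
  accepting the best strictly improving move per sweep until convergence,
  deleting all-gap columns as they appear, and logging everything for
  exact replay. `explain_conflict()` tabulates every candidate move under
  SPS, PAI and PWMD and flags sign disagreements.

## Worked example

The bundled `ace2` preset reconstructs the classic two-column case: one
sequence reads `-T` at sites 20–21 where `T-` is correct, the other ten
sequences all carry T at site 20 and split 6 T / 4 I at site 21.

```r
library(msarefine)
fx <- make_shift_fixture("ace2", seed = 1)
scheme <- scoring_scheme(load_score_matrix("BLOSUM62"),
                         gap_model = "linear", gap = -6)

ref <- greedy_refine(fx$perturbed, "SPS", scheme)
ref
#> Greedy alignment refinement under SPS
#>   11 sequences, 25 -> 25 columns
#>   accepted moves: 1 in 1 sweep(s); converged
#>   criterion: 7676.0000 -> 7700.0000 (total improvement 24.0000)
identical(ref$alignment$mat, fx$clean$mat)
#> [1] TRUE
```

The single accepted move slides the displaced T one column left, worth
+24 SPS: the ten pairs involving that sequence contribute −34 before and
−10 after (10 `T/-` at −6, 6 `T/T` at +5, 4 `T/I` at −1, versus
6 `T/-`, 10 `T/T`, 4 `I/-`), and the identical +24 appears as the drop in
PAI. On the `huntingtin` preset the criteria disagree — PWMD refinement
converges (+8.09 over six moves) while SPS falls from 26,617 to 25,603
under GO 20 / GE 2 / BLOSUM62, because consolidating repeat residues
splits gap runs of pairwise alignments:

```r
fh <- make_shift_fixture("huntingtin", seed = 1)
aff <- scoring_scheme(load_score_matrix("BLOSUM62"),
                      gap_open = 20, gap_extend = 2)
subset(explain_conflict(fh$perturbed, aff), conflict)[1, ]
#>  seq block_start block_len direction slide delta_sps delta_pai delta_pwmd conflict
#>   13          13         3      left     1      -216      -216     0.0061     TRUE
```

A command-line wrapper over the same functions is installed at
`inst/cli/msarefine` (subcommands `score`, `pwm`, `refine`, `simulate`).
The methods vignette (`vignettes/msa-refinement.Rmd`) documents the
models, conventions and design choices.

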