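---
title: "Post-alignment criteria and greedy refinement of multiple sequence alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-alignment criteria and greedy refinement of multiple sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msarefine)
```

## The problem

Progressive multiple sequence aligners (MAFFT, MUSCLE and kin) freeze early
pairwise decisions into the final alignment. When two placements of a
residue are equally good at the moment a sequence joins the profile - say,
a threonine that can sit on either side of a one-column gap - the aligner
must pick one, and the pick can turn out wrong once more sequences arrive.
Iterating the guide tree does not repair such errors, and manual
post-alignment editing is impractical at genomic scale and inconsistent
without an explicit criterion.

`msarefine` implements three explicit criteria for comparing alternative
gap placements of the *same* set of sequences, and a deterministic greedy
engine that searches residue-shift moves until no move improves the chosen
criterion.

## The three criteria

**Sum-of-pairs score (SPS).** An alignment of $N$ sequences implies
$N(N-1)/2$ pairwise alignments. SPS is the sum of their scores under a
substitution matrix and a gap model, with *shared gaps* - columns gapped in
both members of a pair - skipped entirely. The weighted form is
$\mathrm{WSPS} = \sum_{i<j} W_{ij} S_{ij}$, which reduces to SPS at unit
weights. Weights $W_{ij}$ are accepted as user input; the package does not
derive them.

**Pairwise alignment inconsistency (PAI).** With $S_{ij}$ the optimal
global pairwise score (dynamic programming over the degapped sequences)
and $S_{ij.\mathrm{MSA}}$ the score the MSA implies for the pair,
$$\mathrm{PAI} = \sum_{i<j} S_{ij} - \sum_{i<j} S_{ij.\mathrm{MSA}} \ge 0,$$
because the optimum can never be beaten. PAI is zero exactly when every
implied pair attains its optimum; larger is worse. The package reports
improvements with a positive sign (before minus after), so that a positive
delta always means "better" for every criterion.

**Position weight matrix differential (PWMD).** From the column counts
$n_{aj}$ of residue $a$ at column $j$ (gaps and unknowns excluded, $N_j$
non-gap observations) the package builds log-odds weights
$$w_{aj} = \log_2 \frac{(n_{aj} + c_a) / (N_j + \sum_b c_b)}{p_a},$$
with background frequencies $p_a$ and pseudocounts $c_a = p_a \cdot m$.
A sequence's PWM score (PWMS) is the sum of its residues' weights at their
columns; gaps have no row and contribute nothing. A candidate adjustment is
evaluated by
$$\mathrm{PWMD} = \sum_{\mathrm{seq}} \mathrm{PWMS}_{\mathrm{after}}
                 - \sum_{\mathrm{seq}} \mathrm{PWMS}_{\mathrm{before}},$$
positive values favouring the adjustment. Unlike SPS and PAI, which look at
pairs, PWMD pools evidence from all sequences in a column, and it is cheap:
no dynamic programming is involved.

## Scoring conventions

* **Gap models.** Linear (a flat per-gap-site score, e.g. $-6$) or affine,
  where a run of $k$ gap sites costs $\mathrm{GO} + (k-1)\,\mathrm{GE}$.
  The "open includes the first site" convention matters when comparing
  against other software: an aligner that charges
  $\mathrm{GO}' + k\,\mathrm{GE}$ matches this package at
  $\mathrm{GO}' = \mathrm{GO} - \mathrm{GE}$, an identity the test suite
  exercises against `Biostrings::pairwiseAlignment`.
* **Shared gaps** never score and never break a gap run: a pair's run
  interrupted only by shared-gap columns is charged one opening. This
  makes SPS invariant under insertion or deletion of all-gap columns.
* **Terminal gaps** are penalised by default; a `terminal_gaps = "free"`
  scheme treats leading/trailing runs as free (semi-global).
* **Unknown residues** (`X` for amino acids, `N` for nucleotides) score 0
  against everything and are excluded from PWM counts, so ambiguity never
  pushes a move in either direction.
* **Matrices.** BLOSUM62 ships via Biostrings (T/T = 5, T/I = $-1$);
  NCBI-format matrix files are parsed directly; `nt_score_matrix()` gives
  the usual +5/−4 nucleotide scheme.

Defaults for the PWM are uniform background ($p_a = 1/20$ or $1/4$),
pseudocount mass $m = 1$, and log base 2; an empirical (Laplace-smoothed)
background is selectable. Published PWM tables built with other tools use
their own pseudocount and background defaults, so absolute weights differ
across implementations; the package targets the defining arithmetic and the
qualitative structure (majority residue largest, absent residues at the
column floor, strict monotonicity in the count), all of which are tested.

## Moves and the greedy engine

A **move** slides a contiguous residue block of one sequence across part of
an adjacent gap run. It permutes characters within one row only: the
degapped sequence is untouched, so alignments before and after a move are
always alignments of the same data. In codon mode the alignment stores
nucleotide columns under a frame invariant (every gap run and every
ungapped length is a multiple of 3) and moves are constrained to triplet
blocks and triplet slides, so a shift can never split a codon.

`greedy_refine()` repeats sweeps of: enumerate all moves (blocks up to
`max_block = 10` columns, slides up to the gap-run length), evaluate each
move's delta, apply the single best strictly improving one
(`delta > tolerance`, default $10^{-9}$, which absorbs floating-point noise
in PWMD while leaving integer SPS deltas exact), then delete any all-gap
columns the move left behind. For PWMD the weight matrix is rebuilt once
per sweep, not per move - per-move refreshes would make deltas
non-additive and order-dependent. Best-move acceptance with ties broken by
enumeration order (lowest sequence, then leftmost column, then shortest
block, then shortest slide) makes the whole pipeline deterministic;
equally good alternative alignments exist in repeat regions, and the tie
rule picks one canonically. The accepted-move log supports exact replay
(`replay_refinement()`), which the tests assert.

PAI deserves a note: a move never changes degapped sequences, so the
optimal pair scores cancel from any PAI comparison of two states of the
same data. PAI-guided refinement is therefore driven by implied scores
alone - move by move it coincides with SPS - and the package computes it
that way, asserting equality with the full PAI difference in tests. This
is also why the pairwise criteria are "generally concordant" while PWMD
can disagree with both.

## When the criteria conflict

In homopolymer repeats the criteria genuinely part ways. Consider a
glutamine (poly-Q) tract region, with a proline-rich region downstream, as
in huntingtin: a P residue sitting in a column of 12 Qs contributes
strongly negative PWM weight there, and relocating it across a gap run
into a sparsely occupied all-P column raises PWMD sharply (few
observations, all agreeing, give that column a high P weight). But the
same relocation splits the gap runs of its pairwise alignments with the
Q-bearing partners, charging fresh gap openings: the SPS delta is negative.
`explain_conflict()` tabulates every move under all three criteria and
flags such sign disagreements. On the bundled `huntingtin` preset, PWMD
refinement converges while *lowering* SPS - the pairwise criteria prefer
the pre-refinement alignment, the PWM criterion the refined one, and which
is "right" is a modelling question (the PWM view is consistent with
replication slippage expanding and shrinking repeat tracts more often than
point substitution occurs).

## The synthetic-data generators

All fixtures are built in code, deterministically from a seed.

* `make_shift_fixture("ace2")` - 11 amino-acid sequences, 25 columns. At
  sites 20-21 one sequence reads `-T` (perturbed) where `T-` (clean) is
  right; the ten others all carry T at site 20 and split 6 T / 4 I at
  site 21. Under a flat gap score of $-6$ with BLOSUM62, the 10 pairs
  involving the shifted sequence contribute $-34$ (perturbed) vs $-10$
  (clean): a $+24$ SPS improvement, with the identical figure appearing as
  the PAI difference. The flanking columns are conserved consensus with a
  5% substitution rate - they cancel from every windowed comparison.
* `make_shift_fixture("huntingtin")` - 20 sequences, 48 columns: a
  conserved flank, a 21-column Q-tract region (tract lengths 6-21), a
  proline region, and a conserved tail. The perturbed state plants three
  P residues in the Q-majority boundary column (12 Q + 3 P) with a 2-P
  sparse column five sites downstream, and left-flushes three short Q
  tracts. This is the conflict demonstration preset.
* `make_shift_fixture("random")` - a consensus alignment with one planted
  block shift. The gap-run consensus letters are drawn disjoint from the
  block's letters, so the clean placement is the *unique* optimum and
  recovery is well defined; the recovery suite demands at least 95%
  exact recovery over 200 seeded fixtures under both SPS and PWMD (the
  residual failures come from random substitutions in the other sequences
  occasionally creating an equally attractive alternative).
* `make_codon_fixture()` - three codon sequences in which a misplaced gap
  triplet manufactures a spurious A/G substitution; a frame-step-3 shift
  removes it.

What the generators deliberately do not emulate: real residue
composition beyond the planted structure, phylogenetic correlation among
sequences (every criterion here treats sequences exchangeably, as if on a
star tree), alignment-length heterogeneity, and aligner-specific error
modes other than the frozen-choice and codon-boundary errors described
above. Passing the recovery suites therefore shows that the criteria and
engine do what they claim on alignments with those error structures - not
that refinement improves any particular real data set, and not that the
PWMD optimum is phylogenetically preferable (taxon sampling can reverse
the verdict on which placement is "correct").

## Numerical and design choices

* Site numbering is 1-based and column-oriented everywhere; the gap
  character is `-` only.
* Integer matrices keep SPS/PAI deltas exact; the single `tolerance`
  default ($10^{-9}$) exists for PWMD.
* Columns with no observations get the pure-pseudocount weight
  ($\log_2$ of 1 = 0 under uniform background); such columns are deletion
  candidates anyway.
* The PWM scoring policy for a before/after comparison defaults to the
  PWM of the *before* alignment (`pwm_policy = "before"`), the natural
  choice when asking "does this move look good from where I stand?";
  `"after"` and `"refreshed"` are available, and an explicit PWM can be
  supplied to reproduce published tables.
* Problem sizes in the shipped tests - 200 recovery fixtures of 8×30,
  1,000 random PAI alignments of 3×8, exhaustive pairwise enumeration up
  to combined length 12 - were chosen so the whole suite documents the
  claimed properties at meaningful scale while running in well under a
  minute on one core.
* `greedy_refine()` accepts a `seed` argument reserved for optional
  randomized move sampling; the default pipeline has no randomness and
  ignores it.

## Worked example

```{r example}
fx <- make_shift_fixture("ace2", seed = 1)
scheme <- scoring_scheme(load_score_matrix("BLOSUM62"),
                         gap_model = "linear", gap = -6)
sps(fx$perturbed, scheme)
ref <- greedy_refine(fx$perturbed, "SPS", scheme)
ref
identical(ref$alignment$mat, fx$clean$mat)
```

```{r conflict}
fh <- make_shift_fixture("huntingtin", seed = 1)
aff <- scoring_scheme(load_score_matrix("BLOSUM62"),
                      gap_open = 20, gap_extend = 2)
rh <- greedy_refine(fh$perturbed, "PWMD", max_sweeps = 60)
c(sps_before = sps(fh$perturbed, aff), sps_after = sps(rh$alignment, aff))
head(subset(explain_conflict(fh$perturbed, aff), conflict), 3)
```

## Limitations

The engine only ever relocates existing residue blocks across existing
gap runs: it cannot create or destroy indels, change the relative order of
residues, or re-align globally, so it repairs placement errors rather than
alignment errors at large. The move neighbourhood is single-sequence;
coordinated multi-sequence rearrangements are reached only as chains of
single moves, and a greedy chain can stall when no single step improves.
None of the criteria use the sequences' evolutionary history. Likelihood-
based co-estimation of tree and alignment would address that but is far
too slow at scale, which is the reason these fast criteria exist.
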