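---
title: "Methods: exact clade-skew tests for gene presence/absence profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact clade-skew tests for gene presence/absence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladescan)
```

## The inference problem

cladescan works on binary phylogenetic profiles: for each of N samples
(de novo transcriptome assemblies) and each of a set of protein-family
HMMs, was at least one homologous transcript detected? Transcriptomes are
intrinsically incomplete — lowly or conditionally expressed genes are
missed at random — so a single absence is uninformative. The signal of a
genuine evolutionary loss (or lineage-restricted gain) is instead a
*clustered* pattern of absences: a clade in which the family is missing far
more often than the background detection rate predicts. Conditioning on the
observed number of positives makes the analysis robust to the overall
incompleteness level: a family seen in 60% of samples is judged against
what random scatter of that same 60% would look like.

Two assumptions matter. First, detection failures are taken to be
independent across samples given the margin; systematically shallower
sequencing in one clade would mimic loss. Second, a hit is equated with
presence of a family member, which inherits whatever specificity the HMM
has — the score-ratio rule below is the mitigation for families embedded
in large superfamilies.

## Presence calling

* **Threshold rule.** A sample is positive for an HMM when some transcript
  scores **strictly more than 10 bits** (`presence_call()`, `threshold`
  argument). Ten bits is the conventional cutoff for this kind of search;
  we read "above" as a strict inequality and expose the threshold, since
  scores exactly at the boundary are conceivable with rounded inputs.
  Multiple hits per transcript or sample are tolerated; only the maximum
  matters, which is the least surprising aggregation when the search
  reports several domain matches.
* **Score-ratio rule.** For a family inside a diverse superfamily (the
  motivating case is a CbbX-type Rubisco activase inside AAA+), a sample is
  positive only if some transcript has target score > 10 bits *and* at
  least 5 × its best score against the broader reference HMM
  (`ratio_call()`, `factor`). The comparison is per transcript on the
  linear bitscore scale, using each transcript's best score per HMM. When a
  transcript has no reference hit at all, its reference score is imputed at
  the 10-bit floor: absent reference evidence should weaken, not
  disqualify, a strong target hit. A consequence worth knowing: ratio
  positives are always a subset of plain-threshold positives at the same
  floor.
* Samples listed in the metadata but absent from the hit table are retained
  as all-zero rows — non-detection is absence, which is the semantics of
  the whole analysis.

## The exact 2×K test

For group sizes $n_1,\dots,n_K$ and positives $k_1,\dots,k_K$, the point
probability of a table conditional on both margins is
$\prod_i \binom{n_i}{k_i} / \binom{N}{T}$ with $T=\sum_i k_i$. The
two-sided p-value is the total probability of all tables with the observed
margins whose point probability does not exceed the observed one. Design
choices:

* **Tie tolerance.** Floating-point evaluation of "equally extreme" tables
  is unreliable at the tail, so tables with probability within a relative
  factor $1+10^{-7}$ of the observed one count as ties and are included.
  This matches the convention of standard 2×2 implementations, and our 2×2
  case agrees with `stats::fisher.test` to better than $10^{-9}$ relative
  over randomized tables (a tested invariant).
* **Log-space accumulation.** All point probabilities are handled as
  natural logs (via `lchoose`) and summed with a streaming log-sum-exp.
  p-values below the double-precision underflow threshold (~$10^{-308}$)
  remain exact as `log10_p`; `p_value` itself is the exponentiated value
  and is the authoritative number everywhere it is representable.
* **Class collapsing.** Tables are enumerated as *probability
  configurations*: groups of equal size are interchangeable, so only the
  multiset of counts within each size class matters, with a multinomial
  multiplicity accounting for the collapsed tables. A partition with m
  singleton clusters thus contributes a factor of order T rather than
  $2^m$. This is exact, not an approximation.
* **Enumeration guard.** The walk refuses (with an error, never a silent
  approximation) tables needing more than $10^7$ configurations
  (`max_tables`). Monte Carlo fallbacks are deliberately out of scope; the
  package's claims are exactness claims.
* **Degenerate tables.** K = 1, all-positive, and all-negative margins
  admit a single table and return p = 1.

`skew_scan()` applies the test per HMM against a clade map and sorts by
ascending `log10_p` (so extreme ties order correctly), breaking exact ties
lexicographically by HMM id for reproducibility. Raw p-values are reported;
the ranked list is the object of interest, and Benjamini–Hochberg
adjustment is available separately (`bh_adjust()`) rather than applied by
default. `concordance_test()` reduces co-gain/co-loss of two families to a
2×2 of joint calls and uses the same machinery.

## Tree procedures

`cut_levels()` generates the successive partitions of a rooted tree: the
root's subtrees first, then refinements expanding one internal node at a
time, shallowest first, ties at equal depth broken by preorder index. A
root polytomy simply yields more than two clusters at the first level.
Branch lengths are ignored throughout — the tests use topology only.

`branch_scan()` computes the exact p for every HMM at every cut level,
flags levels with p < α (default **α = 0.001**) and marks the minimal-p
level per HMM, ties resolved to the earliest (coarsest) level.

`simplify_tree()` descends the same candidate expansions top-down and keeps
an expansion only if, for at least one HMM, the refined partition's p is
below α **and** at least `improvement_factor` (default **10**) times
smaller than the unrefined partition's p. "Substantially improves" is not
quantified in the procedures this mirrors; one order of magnitude is our
operationalization and both knobs are exposed. Samples under a rejected
expansion remain merged in the parent's retained cluster — this is also how
the ambiguous case "no descendant meets the threshold" resolves: upward.
Because evaluation is strictly top-down, a loss clade that is invisible at
every coarser cut (e.g. a small clade deep inside an otherwise uniform
subtree, with α strict) will leave the tree unsplit; that conservatism is
inherent to the cut-then-test design rather than a defect of the
implementation. The stop rule is purely the significance criterion — there
is no target cluster count.

## The synthetic generator

`sim_config()` + `generate_dataset()` emulate, in order:

1. **Phylogeny** — a Yule (pure-birth) tree, or a balanced tree with unit
   branch lengths for closed-form checks.
2. **Trait evolution** — a two-state continuous-time Markov chain per
   branch: losses arrive at `loss_rate` (default **0.1** per unit length)
   while present, gains at `gain_rate` (default **0.01**) while absent.
   The 10:1 asymmetry makes losses common and regains rare, the
   Dollo-like regime in which interpreting skew as loss is sensible.
   Deterministic single-loss histories can be pinned to a named clade
   (`forced_losses`) for planted-truth experiments.
3. **Observation** — each truly present (sample, gene) pair is detected
   independently with `detection_prob` (default **0.9**, a plausible rate
   for moderately expressed genes in shallow assemblies); detected pairs
   draw a bitscore at `threshold + 1 + Exp(scale = 20)` bits, and
   Poisson(`spurious_rate` = **0.1**) sub-threshold noise hits (uniform on
   (0, 10) bits) are added per pair — these exercise the strict-inequality
   calling edge without ever creating false positives above threshold.

Everything is a pure function of the configuration including its seed;
outputs are byte-identical across runs, and the seed is recorded in each
file's header comment. The truth JSON (versioned schema) records root
states, per-branch events and tip states, sufficient to score any detector
(`evaluate_detection()`: power, false discovery rate, best-branch
accuracy).

What the generator does **not** emulate: sequence-level realism (no
transcripts or HMM emissions), expression-abundance distributions,
clade-correlated sequencing depth (dropout is i.i.d.), HMM
cross-reactivity, or contamination. Passing the simulation-based tests
therefore demonstrates the statistical machinery is correct and calibrated
under the stated model — not that real transcriptome surveys are free of
the systematic effects listed above.

## Problem sizes and test design

The test suite verifies the exact test against two independent brute-force
oracles (all tables, and all $\binom{N}{T}$ sample-level assignments) for
N ≤ 14, K ≤ 4; checks normalization of the enumerated distribution for
margins up to N = 60; and checks the closed form
$p = 1/\binom{32}{8} \approx 9.51\times10^{-8}$ for a planted 8-of-32
clade loss whose cut isolates a single extreme table. Simulation studies
use a 32-tip tree with an 8-tip planted loss at 90% detection (100
replicates for power; 100 no-loss replicates for the per-HMM type-I rate;
1000 null genes for calibration of $P(p \le \alpha)$) — sizes chosen to
put at least a thousand Bernoulli draws behind every frequency that is
asserted, while keeping the default check quick on a laptop. On a balanced
32-tip tree the analogous cut has a symmetric sister clade, so the extreme
table is duplicated and the minimal p doubles — the reason closed-form
checks use a tree whose root isolates the lost clade.

## Known limitations

* The exactness guarantee ends where the enumeration guard begins: very
  fine partitions of large sample sets with many distinct cluster sizes
  error out rather than approximate.
* `simplify_tree()` inherits the top-down blindness discussed above.
* The lipid module takes abundances as provided (AUC units);
  internal-standard normalization happens upstream. The DGTS detectability
  threshold defaults to 0 (any nonzero AUC counts), configurable via
  `detect_threshold`.
* Newick parse errors are reported without character offsets (the
  underlying parser does not expose them).
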