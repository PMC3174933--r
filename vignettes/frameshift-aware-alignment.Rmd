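---
title: "Frameshift- and stop-codon-aware alignment of coding sequences: model and methods"
author: "frameAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift- and stop-codon-aware alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frameAlign)
```

# The problem

Coding nucleotide sequences are best compared through their amino-acid
translations, but translation presumes an intact reading frame.
Pseudogenes, raw sequencing reads and mis-annotated CDSs violate that
premise with 1–2 nt indels (frameshifts) and premature stop codons. A
translate-then-align pipeline garbles everything downstream of the first
defect; a plain nucleotide aligner ignores codon structure and happily
opens gaps of length 1 or 2 anywhere. `frameAlign` aligns the
nucleotides directly under an amino-acid objective in which the frame
disruption itself is a first-class, explicitly priced event.

# The objective function

The atomic unit of every alignment is the **codon site**: a
three-character cell over `{A,C,G,T,N,!,-}` that is either a gap
(`---`), a full codon, or a *frameshifted codon* — one or two `!`
padding the 1–2 observed nucleotides of a codon hit by a small deletion.
Mixed cells (gap characters together with nucleotides) are invalid; this
is what keeps codon structure intact in every output.

The score of an alignment is the sum of independent per-column,
per-side contributions (maximised; all penalties are $\le 0$):

* both sides full, neither a stop: the substitution matrix entry
  $d(a_1, a_2)$ of their translations (BLOSUM62 by default; codons
  containing `N` translate to `X` and use the matrix's `X` row);
* a frameshifted side contributes that row's frameshift score
  $c_{fs}$ (default $-30$), *once per site* whether it carries one or
  two `!`: one small deletion is one biological event. No substitution
  term is added for the partial codon — its translation is undefined;
* a side that is an internal stop codon contributes that row's stop
  score $c_{stop}$ (default $-100$); a stop facing a frameshifted site
  therefore costs $c_{stop} + c_{fs}$;
* gaps are affine *in codon-site units*: $g_o$ (default $-7$) at each
  opening plus $g_e$ (default $-1$) per `---` site. Nucleotide-level gap
  lengths are never scored — the objective is purely the amino-acid
  alignment cost.

Three positional exemptions implement the semi-global convention:
terminal gap runs are free at both ends of a pairwise comparison; a
trailing partial codon (the site containing a row's final nucleotide) is
scored as terminal gap extension, i.e. free, rather than as a
frameshift; and a stop codon occupying a row's final codon position is
free — genes end in stops.

Two penalty sets may coexist: rows labelled `lowpen` use override scores
`fsLowpen`/`stopLowpen`. The shipped guidelines are $-20/-10$ for
pseudogenes (frameshifts and stops are *expected*, so they are cheap)
and $-10/-60$ for sequencing reads (frameshifts are likely sequencing
errors, stops should still be resisted).

## Why the stop penalty must be lowered for pseudogenes

A consequence of the additive model worth knowing: under the defaults, an
internal stop aligned in frame costs $-100$, but the optimizer can
"mask" it by splitting the stop triplet into two frameshifted sites plus
a one-site gap in the partner, for about $2 c_{fs} + g_o + g_e = -68$.
Optimal alignments under default penalties therefore tend to hide real
stops out of frame. This is not a defect of the implementation — it is
exactly the economics the parameters encode, and it is why the
pseudogene guideline drops the stop cost to $-10$: at that price the
in-frame explanation wins and the `*` surfaces at its true codon. The
package's stop-recovery tests run under the lenient setting for this
reason.

# The pairwise dynamic program

Write $n$, $m$ for the nucleotide lengths of the two sequences. The DP
state is the pair of prefix lengths $(i, j)$, *not* codon counts, so
frames may desynchronise and recover. Each cell is reached from the 4×4
square of predecessors consuming $(\delta_a, \delta_b) \in \{0..3\}^2
\setminus \{(0,0)\}$ nucleotides: 15 moves. Three (3,3 / 3,0 / 0,3) are
the classical amino-acid substitution/deletion/insertion moves; the other
12 consume 1 or 2 nucleotides on at least one side and create the
corresponding frameshifted site(s). Per-cell work is therefore exactly
5× that of 3-move Needleman–Wunsch, at identical $O(nm)$ asymptotics.

Affine gaps use the standard three-state construction: matrices $M$, $I$,
$D$ hold the best score of a partial alignment ending in a
match/substitution-class site, an insertion, or a deletion. All moves
with $\delta_a \ge 1$ and $\delta_b \ge 1$ enter $M$; $\delta_b = 0$
enters $D$, $\delta_a = 0$ enters $I$. A frameshifted-codon-vs-gap move
(e.g. $\delta_a \in \{1,2\}, \delta_b = 0$) charges *both* the
frameshift score and the gap open/extension: a partial codon facing
nothing is both an event and a gap. Only cell $(0,0)$ of $M$ is
initialised (to 0); every other boundary access goes through an accessor
returning $-\infty$, which can never win a maximisation, so the first
rows and columns need no special-casing. Because a gap run in $D$ keeps
$j$ fixed, a run is terminal exactly when $j \in \{0, m\}$, which makes
terminal-gap freedom a one-line condition.

**Determinism.** Ties are broken by a fixed candidate order: fewer
frameshifts first, then $(3,3) \succ (3,0) \succ (0,3)$, then
lexicographically larger $(\delta_a, \delta_b)$; predecessor states in
order $M \succ D \succ I$; improvements must be strict. Identical inputs
give byte-identical outputs.

**Insertions are represented as deletions elsewhere.** An extra 1–2 nt
in one sequence never yields a "ghost codon"; it surfaces as `!` padding
in the *other* rows facing real nucleotides. Modelling insertion-type
frameshifts explicitly would break the columnar representation multiple
alignment needs; representing them as small deletions in the other
sequences slightly overpenalises them in the multiple case but keeps
every alignment a plain site matrix.

## The brute-force oracle

`oracleAlign()` is an independent check, not a fallback: a depth-first
enumeration of *all* move sequences consuming both inputs (refused above
24 nt combined), with incremental scoring and a branch-and-bound prune.
The bound on any suffix is $\min(\lceil r_a/3 \rceil, \lceil r_b/3
\rceil) \cdot \max_{xy} d(x,y)$ — events and gaps only subtract, so this
upper bound is admissible and pruning branches that cannot *strictly*
beat the incumbent preserves the exact maximum. The test suite requires
exact score agreement with the DP on hundreds of random pairs under
random penalty draws, and the acceptance script recomputes that
agreement rate at every run.

# Multiple alignment

## Guide tree

Pairwise similarities are estimated from nucleotide k-mer *type* sets:
$\mathrm{sim}(i,j) = |K_i \cap K_j| / \min(|K_i|, |K_j|)$, distance
$1 - \mathrm{sim}$ clamped to $[0,1]$. The default $k = 6$ follows
common compositional-distance practice for coding DNA — long enough to
be informative, short enough that moderately diverged orthologs still
share most types; it is a plain argument for anyone who disagrees. A
UPGMA (average-linkage) agglomeration gives a rooted, strictly binary
guide tree; ties merge the pair whose cluster labels (smallest member
id) sort first, for reproducibility. The tree groups similar sequences
for alignment order — it is explicitly not a phylogeny estimate.

## Merging

Internal nodes are processed bottom-up with three move repertoires:

* **leaf–leaf**: the full 15-move pairwise DP;
* **leaf–block**: a 7-move hybrid DP consuming 0/1 block column and 0–3
  nucleotides of the sequence, so *new* frameshifts can still be placed
  in the incoming sequence relative to the block;
* **block–block**: columns are atomic (3 moves); merging can reposition
  columns but never invent frameshifts — forced by the requirement that
  both induced sub-alignments be preserved exactly.

The block objective is sum-of-pairs over cross pairs: per-side event
costs and substitution terms exactly as in the pairwise model, gap
extensions from per-column gap configurations, and gap *openings* by the
quasi-natural ("pessimistic") count — an opening is charged for a row
pair whenever the current pair column is (gap, residue) and the previous
pair column was not, which overcounts only in the gap-gap → gap-residue
configuration. With three DP states the previous merged column is fully
determined by the predecessor state, so the count needs no extra state.
Sites containing `!` count as residues throughout. Two approximations
apply *inside the merge DP only*: gap cells lying before a row's first
or after its last residue are treated as free, and within-block pair
contributions (which the merge cannot change, except for both-gap column
drops) are omitted. The score reported on every returned alignment is
never the DP estimate: it is an exact `spScore()` recomputation — the
sum over all row pairs of the induced pairwise score after dropping
both-gap columns, with the full terminal exemptions. The DP estimate is
kept as an attribute and tested to be a lower bound (pessimism) that is
exact on gap-free merges.

## 2-cut refinement

Each clade of the guide tree (including single tips, excluding the root)
splits the current alignment into clade rows versus the rest; all-gap
columns are dropped in each part; the parts are re-merged (the 7-move
hybrid when one side is a single row — the one place refinement can
*re-place* a frameshift); the candidate replaces the incumbent only if
its exact sum-of-pairs score strictly improves. After a full sweep the
guide tree is re-estimated from the alignment itself — similarity of
rows $i,j$ is their induced pair score normalised by
$\max(s_{ii}, s_{jj})$, the larger self-score — and sweeps continue
until none improves or `maxIter` (default 10, in practice 1–3 suffice)
is reached. Acceptance-only updates make the final score provably $\ge$
the draft score; the test suite asserts the full accepted trajectory is
strictly increasing across seeded runs.

# The synthetic generator

`evolveOrf()` produces families with known ground truth: a random
stop-free ancestor ORF starting `ATG`, evolved on a *star* topology
(independent descendants — chosen so that every mutation in a descendant
is attributable, at the price of no shared internal branches), with
per-codon substitutions drawn uniformly over non-stop codons, optional
whole-codon indels, then requested frameshift (1–2 nt deletion) and
premature-stop injections, all under one seed. The default study
condition used by the recovery experiments is 5 sequences × 100 codons
at substitution probability 0.05 per codon per lineage with one injected
1 nt deletion — a divergence regime typical of congeneric pseudogene
comparisons. What the generator does *not* emulate: codon-model
selection (dN/dS), rate heterogeneity, homopolymer-biased errors,
alignment-ambiguous repeats. Passing recovery tests therefore show the
method localises isolated frame defects under realistic divergence; they
do not certify behaviour on tandem repeats or error bursts.

Localisation is scored within ±1 codon of the injection because a 1 nt
deletion on a codon boundary is representable one codon to either side
at identical cost; the recovery bar (≥90% over 100 seeded replicates) is
a property of this artifact's conditions, not an external benchmark.

# Numerical and engineering choices

* Scores are integers throughout but carried as doubles; the $-\infty$
  sentinel is $-10^{18}$, far below any reachable score at supported
  input sizes.
* The three DP kernels (15-move pairwise, 7-move hybrid, 3-move block)
  are C++ (Rcpp), as is usual for alignment inner loops; everything
  else — scoring, UPGMA, refinement control, IO — is R.
* Problem sizes in the shipped test and acceptance harnesses are chosen
  to exercise every code path at depth while keeping a full run in
  minutes on one core: 500 oracle pairs at 1–8 nt, 100
  Needleman–Wunsch-reduction ORF pairs at 5–15 codons, 100 refinement
  runs on 5–10 × 18-codon families, 100 recovery replicates at 5 × 100
  codons.
* Genetic codes come from the NCBI tables (via Biostrings), selectable
  per run and per sequence (`sequence_id <TAB> table_id` file); stop
  detection always uses the owning row's code.
* The `!` pad is placed before the observed nucleotides of a
  frameshifted codon (`!AG`, `!!A`); the choice is cosmetic — only the
  count of `!` per site is model-relevant — but it is applied
  consistently so outputs are byte-reproducible.

# Known limitations

* Insertion-type frameshifts are representable but mildly overpenalised
  in multiple alignments (they induce gaps in all other rows).
* The sum-of-pairs objective is optimised heuristically (progressive +
  2-cut), as exact SP optimisation is intractable; only pairwise
  alignment is provably optimal.
* Under harsh stop penalties real stops may be explained away as
  frameshifts (see above); choose the penalty set to match what the
  sequences are.
* No local alignment mode: sequences are assumed to be coding over
  (essentially) their full length, UTR overhangs surviving only via free
  terminal gaps.
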