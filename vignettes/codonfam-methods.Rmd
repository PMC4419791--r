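---
title: "Methods: codon bias, divergence and gene-family statistics in codonfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon bias, divergence and gene-family statistics in codonfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`codonfam` studies expression-mediated selection on protein-coding genes in a
pair of closely related species: do highly and widely expressed genes show
stronger codon usage bias and slower protein evolution, and how do both
covary with gene family size and pathway position? This vignette documents
the models and procedures, the tunable parameters, the numerical choices,
and the design decisions behind the implementation, together with what the
synthetic-data validation does and does not demonstrate.

## The synthetic-data generator

Every downstream stage is validated against planted ground truth, so the
generator is first-class, tested code rather than a fixture.

**Codon bias coupled to expression.** `gen_biased_cds()` draws amino acids
uniformly over the twenty residues (the composition profile is deliberately
neutral; real proteomes are not uniform, but composition does not enter any
statistic we compute) and chooses synonyms with a bias parameter
$b \in [0,1]$ per expression decile: at each site of a degenerate family
with $n_{syn}$ synonyms the planted optimal codon is used with probability
$b + (1-b)/n_{syn}$, every other synonym with probability $(1-b)/n_{syn}$.
At $b = 0$ synonym choice is uniform; at $b = 1$ the gene is fully
optimized. The default ramp `bias_ramp()` rises linearly from $b = 0.02$ in
decile 1 to $b = 0.8$ in decile 10, a regime in which the extreme-group
contrast recovers the planted optimal set essentially perfectly at a
thousand genes. The default planted optimal set is one codon per degenerate
amino acid, A/T-ending where possible, which reproduces the empirically
observed negative correlation of Fop with GC3s in conifers (optimal codons
avoiding G/C third positions). One optimal codon per amino acid is planted;
amino acids with two co-optimal codons (as reported for arginine in real
spruce data) are representable in the scoring functions but not simulated
by default.

**Divergence.** `evolve_cds_gy94()` evolves each codon site independently
under the Goldman–Yang (GY94) continuous-time Markov chain (below). Stop
codons are not part of the 61-codon state space, so nonsense changes are
impossible by construction rather than by rejection. No indels are
simulated; the codon-aware aligner is exercised by constructed deletion
cases in the tests instead.

**Families.** `gen_family_set()` draws family sizes from a discrete power
law $p(s) \propto s^{-\gamma}$ on $2..s_{max}$ (defaults $\gamma = 2.5$,
$s_{max} = 150$). When at least 30 families are requested, the first six
are pinned to representative sizes (2, 3, 7, 14, 50, 120) so every size
class from single-copy to >100 genes is present. Size-2 families are
one-to-one orthologs; larger families split binomially between species,
which also produces occasional lineage-specific ("orphan") families. All
members of a family descend from one ancestral biased CDS evolved with the
family's $(t, \kappa, \omega)$; each branch gets $t/2$ so any cross-species
pair is separated by approximately $t$.

Three couplings are planted, mirroring the genome-wide patterns the
statistics are meant to detect. The paper-scale data motivate the signs of
these couplings but give no quantitative form, so the effect sizes are the
package's own choices: the family's mean expression decile decreases with
size ($\mu = 10 - 2.2\log_2 s$ plus unit Gaussian noise, clamped to 1..10);
$\omega$ increases linearly with $\log_2 s$ across the configured omega
range; and per-tissue expression is on with probability
$\mathrm{logit}^{-1}((d - 2.5)/1.3)$, so high-decile genes are also broadly
expressed. Codon bias follows the decile through the bias ramp, which
induces the Fop–breadth and Fop–family-size relationships downstream.

**Expression.** `gen_expression_matrix()` emits log-normal signals with
log-mean proportional to the planted per-tissue decile and zero signal in
non-hit cells. The default hit rule follows the planted on/off state; a
constant hit probability can be substituted to exercise boundary cases.
This emulates the *structure* of an eight-tissue expression resource
(signals, presence/absence hits, decile ranks), not the error model of any
real microarray or RNA-seq pipeline — no probe effects, library-size
variation, or between-replicate dispersion. Passing tests therefore show
the statistics behave correctly when their assumptions hold, not that any
particular real dataset satisfies those assumptions.

## Codon usage statistics

Counts exclude stop codons and codons containing ambiguous bases (tallied
separately). With $n_c$ the count of codon $c$ in a gene:

* **RSCU**: $\mathrm{RSCU}(c) = n_c / (\bar n_{fam})$ where $\bar n_{fam}$
  is the family total divided by family size; undefined (NA) for amino
  acids absent from the gene.
* **GC3s**: G+C fraction at third positions of codons from degenerate
  families only; ATG, TGG and stops carry no synonymous third position.
* **Fop**: optimal codons used, divided by codons belonging to amino acids
  that possess an optimal codon (the CodonW-style Fop without a penalty
  term for non-optimal codons).
* **CAI**: $\exp(\sum n_c \ln w_c / \sum n_c)$ over degenerate-family
  codons, with relative adaptiveness $w_c = n^{ref}_c / \max_{fam}
  n^{ref}$ on pooled reference counts; zero reference counts are floored
  at 0.5 counts so $\ln w$ stays finite.
* **CBI**: $(N_{opt} - N_{ran}) / (N_{tot} - N_{ran})$ with $N_{ran}$ the
  expected optimal usage under uniform synonym choice; 1 at full
  optimization, 0 at random usage, negative when optimal codons are
  avoided.

## Correspondence analysis and optimal codon identification

The CA input is the gene × codon count matrix over the 59 codons of
degenerate families (Met, Trp, stops excluded), the convention of
codon-usage ordination tools; genes with fewer than 100 countable codons
are dropped by default (configurable) because short genes contribute
mostly sampling noise to the $\chi^2$ metric. The analysis is the standard
one: divide by the grand total, form standardized residuals
$(P - rc^\top)/\sqrt{rc^\top}$, decompose by SVD, and report principal
coordinates; the total inertia equals the Pearson $\chi^2$ statistic of
the table divided by its grand total, which the tests assert numerically
against an independent implementation (`MASS::corresp`).

An SVD axis has arbitrary sign, so axis 1 is oriented by its Spearman
correlation with a per-gene expression measure when one is supplied: the
high-expression pole is positive. `identify_optimal_codons()` then pools
codon counts of the genes in the top and bottom deciles of the axis-1
score (fractions configurable) and tests each codon's 2×2 table (this
codon vs the rest of its family, high vs low pool) with Yates-corrected
chi-square. A codon is called optimal when its within-family relative
usage is higher in the high pool at $\alpha = 0.01$ per codon, without
multiplicity correction — the traditional practice for this contrast,
logged and configurable. The extremes fraction (10%) and the use of counts
rather than RSCU as CA input are defaults of this package, kept
configurable because the upstream tools leave them unspecified.

## Divergence estimation

**Alignment.** Pairs are aligned at the protein level
(Needleman–Wunsch, affine gaps, BLOSUM62, EMBOSS-Needle-like defaults
gap open 10, extension 0.5) and codons are threaded back through the
protein alignment, which guarantees frame preservation; codon columns
containing a gap are removed before estimation. A gap of length $L$ costs
$10 + 0.5L$, with terminal gaps penalized; the tests pin this convention
to a brute-force dynamic-programming oracle.

**NG86.** The counting estimator enumerates the nine single-nucleotide
neighbours of each codon for site counts (nonsense mutations disregarded,
reducing the per-position denominator), averages synonymous/nonsynonymous
difference counts over stop-free mutational pathways for codons differing
at several positions, and applies the Jukes–Cantor correction
$d = -\tfrac34\ln(1 - \tfrac43 p)$; proportions $\ge 3/4$ are flagged
saturated rather than extrapolated.

**GY94 maximum likelihood.** The rate matrix over the 61 sense codons is
$q_{ij} = \pi_j \kappa^{[ts]} \omega^{[nonsyn]}$ for single-nucleotide
changes, scaled to one expected substitution per codon at $t = 1$.
Transition probabilities come from an eigendecomposition in the
$\pi^{1/2}$-symmetrized basis (the chain is reversible; asymmetry residue
tolerance $10^{-9}$ is enforced by explicit symmetrization). The pairwise
likelihood is $\sum_{sites} \log(\pi_i P(t)_{ij})$ over aggregated site
patterns. Codon frequencies default to F3x4 estimated from the pair
itself (F1x4 and F61 available); F3x4 products are floored at $10^{-8}$
and renormalized so the decomposition stays defined. Optimization is
bounded L-BFGS-B in log-parameters ($t \in [10^{-4}, 50]$,
$\kappa \in [0.1, 100]$, $\omega \in [10^{-4}, 20]$). Each of `n_repeats`
(default 10, matching the common practice of repeated codeml runs keeping
the best log-likelihood) runs `n_restarts` optimizations — one anchored at
a data-informed start, the rest at random points in the central band of
the log-parameter box — keeps the best lnL, and the retained estimates are
averaged across repeats. What varies between the repeated runs of the
original protocol is not documented anywhere we could find; here repeats
differ only by their random restart points, which is recorded in the
output rather than asserted as anyone's intent. $d_N$ and $d_S$ derive
from $(\hat t, \hat\kappa, \hat\omega)$ by partitioning the substitution
flux into synonymous and nonsynonymous classes and dividing by the
per-codon site numbers $3\rho^{(1)}_S$, $3\rho^{(1)}_N$ computed at
$\omega = 1$ (the mutational-opportunity definition), so
$d_N/d_S = \hat\omega$ exactly.

Parameter recovery is honest only from a stationary ancestor;
`random_cds()` draws one from the model's equilibrium frequencies. A
biased gene (from `gen_biased_cds()`) is *not* stationary under uniform
frequencies, and fitting it without matching frequencies visibly biases
$\hat\omega$ downward — the validation therefore separates
estimator-recovery experiments (stationary ancestors) from the
pipeline-level qualitative patterns (biased genes, NG86 ranks).

**Filters.** Estimates are discarded in rule order: $d_S < 0.01$
(unreliable $\omega$), then $d_S > 2$ or $d_N > 2$ (saturation), then
$\omega > 10$; per-rule counts plus retained always equal the input size.
Retained estimates are labelled purifying ($\omega < 1$), neutral
($\omega = 1$) or positive ($\omega > 1$).

## Ortholog clustering

The all-vs-all protein similarity graph replaces a BLASTP search with
exhaustive global alignment, which is exact at desk scale (up to a few
thousand genes) — the clustering consumes the graph, not the search
heuristic. Two shortcuts keep it fast without changing what the graph
means: candidate pairs must share at least 5 distinct 4-mers (the
word-match seeding idea; unrelated random proteins essentially never
qualify, so this only prunes pairs that could not pass the identity
threshold), and equal-length pairs whose ungapped identity already clears
the threshold are accepted on the trivial diagonal alignment. Edge weight
is fractional identity over ungapped aligned columns (e-values are
undefined without a database model), kept when identity $\ge 0.4$ and
those columns cover $\ge 0.5$ of the longer sequence.

MCL runs on the column-stochastic matrix with self-loops at each node's
maximum incident weight (the usual regularization), alternating expansion
(matrix squaring) and inflation (entrywise power 1.5, renormalization),
pruning entries below $10^{-8}$, until the maximum entry change is below
$10^{-6}$ or 100 iterations (non-convergence clusters the current state
with a warning). Clusters are connected components of the limit support;
genes in no multi-gene cluster are reported unclustered.

Family-size classes follow the six-bin scheme: single-copy (exactly one
gene in each species), then total sizes 2–5, 5–10, 10–20, 20–100, >100.
The published bin labels share their boundary values; this package uses
half-open bins $[2,5), [5,10), [10,20), [20,100), [100,\infty)$ — a
repository decision, flagged here because the original rule is not stated.

## Expression and family statistics

Within each tissue, genes with positive signal are ranked into ten
near-equal classes (sizes differ by at most one when the count is not
divisible by ten); silent genes get class 0, matching the 0–10 display
scale. Ties break by stable gene-id order so runs are reproducible.
Breadth is the number of hit tissues (0–8 by default). Family-size
contrasts use Kruskal–Wallis (rank-based, suitable for very unequal group
sizes) and one-sided Mann–Whitney with an explicit direction argument —
the directions in the motivating analyses are implied by the narrative,
never stated per test, so the API refuses to guess. Correlations default
to Spearman for rank-derived quantities (deciles, pathway positions) and
Pearson for class-mean summaries such as the Fop-vs-breadth curve; the
method is recorded in every output. Enrichment is an upper-tail
hypergeometric test per term against a flat gene→term table with
Benjamini–Hochberg control at FDR 0.05; ontology graph propagation is
deliberately out of scope.

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:
GY94 recovery on 2,000-codon pairs at $t = 0.5$, $\kappa = 2$,
$\omega \in \{0.1, 0.5, 1, 2\}$ with 10 replicates each; NG86/GY94
agreement at $t = 0.05$, $\kappa = 1$; optimal-codon precision and recall
on 1,000 genes of 300 codons; MCL recovery on 100 planted-partition
graphs (3 blocks of 10, $p_{in} = 0.9$, $p_{out} = 0.02$); Kruskal–Wallis
type-I error over 10,000 null simulations; and the qualitative
breadth–Fop, family-size and pathway-position patterns on six replicate
genomes of 300 families (roughly 1,300 genes). These sizes were chosen so
each experiment has clear statistical resolution while the whole
validation remains a desk-scale computation.

## Known limitations

* The generator plants one optimal codon per amino acid, uniform amino
  acid composition, and no indels, transposable elements or genome-size
  structure; conclusions about the statistics transfer to real data only
  to the extent real data resemble these assumptions.
* The pairwise likelihood has no among-site rate variation and no codon
  model selection; only the two-sequence case is implemented.
* NG86 is known to underestimate $\omega$ at substantial divergence when
  $\kappa > 1$; it is used as a fast cross-check and for genome-scale
  screening, with the ML estimator as the reference method.
* The similarity graph is exhaustive and in-memory; it is not intended
  for proteome-scale inputs.
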