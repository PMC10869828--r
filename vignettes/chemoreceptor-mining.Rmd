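---
title: "Mining chemoreceptor gene families and testing their loss dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining chemoreceptor gene families and testing their loss dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomine)
```

## The problem

Vertebrate chemoreception runs through six multigene families of
G-protein-coupled receptors: the olfactory and pheromone receptors *OR*,
*TAAR*, *V1R* and *V2R*, and the taste receptors *T1R* and *T2R*. These
families are large (hundreds of copies per genome in some lineages), highly
dynamic, and full of pseudogenes, which makes annotating them in a genome
assembly a specialised task: generic gene predictors miss fragmented or
pseudogenised copies, and naive homology search conflates the families,
which are all seven-transmembrane receptors and therefore resemble one
another at the sequence-composition level.

`chemomine` implements a desk-scale version of this annotation problem plus
the comparative statistics that typically follow it: classifying every mined
locus into **complete / pseudogene / truncated / edge / ambiguous**, mapping
gene losses onto a phylogeny from shared loss-of-function (LoF) mutations,
testing whether losses concentrate in particular branch categories (for
example diet classes), and regressing gene counts on ecological predictors
with phylogenetic generalized least squares (pGLS). Because the real inputs
(hundreds of vertebrate assemblies, published time trees) are far beyond a
test suite, the package also ships first-class synthetic-data generators
that create genomes and trees with known ground truth; every claim the
package makes about itself is tested against that truth.

## The two mining procedures

**Single-exon families** (*OR*, *TAAR*, *T2R*, and *V1R* outside ray-finned
fishes) are mined in two rounds. Round one: the family's reference proteins
are searched against the six-frame translation of every scaffold at a
permissive expectation-value tier (1e-5); overlapping hits are merged and
only the single best-scoring hit's span per overlap cluster is kept
("best-hit regions"); regions are extended by 1000 bp on each side; open
reading frames at the family's complete-gene length floor (750 nt for *OR*
and *T2R*, 810 for *V1R*, 850 for *TAAR*) are extracted and assigned to a
family by their best match against a mixed database of family queries,
outgroups and non-chemoreceptor GPCR decoys. Intact, family-confirmed ORFs
become *complete* candidates. Round two re-searches the genome using the
complete candidates themselves plus the references as queries at a stringent
tier (1e-20), masks everything already owned by round-one candidates, and
classifies the remaining regions by a frameshift-aware alignment to the
best reference: at least one LoF mutation makes a *pseudogene*; otherwise a
fragment is *edge* if its region was clipped at a scaffold border (an
assembly-artifact signature) and *truncated* if not. Any candidate whose
sequence contains an ambiguity code is *ambiguous*, regardless of anything
else.

**Multi-exon families** (*V2R*, *T1R*, and the ray-finned-fish *V1R*) use
hit extension by 30 kb, per-region inference of the expected exon count from
the translated-search hits themselves (hits of at least 50 bp, merged when
closer than 100 bp), spliced gene-model prediction, and an iterative model
selection: predictions with more exons than the inferred cap are discarded;
a length threshold starts at the family's mean expected gene length (900 nt
for *V1R*, 2700 nt for *V2R*/*T1R*), the best-scoring prediction among
overlapping survivors is kept, accepted models and everything overlapping
them are removed, and the threshold is lowered until nothing qualifies.
*V2R*/*T1R* sequences under 400 bp are dropped entirely, and a complete call
requires an intact CDS of at least 810/2100/2200 nt (*V1R*/*V2R*/*T1R*).

The decrement schedule of the length-threshold loop is not fully specified
by the procedure it follows; this implementation halves the threshold at
each iteration and never lets it fall below the family's reporting floor.
Both the schedule and the floor are parameters of `family_params()`.

### The built-in aligners, and what they claim

The translated search is a seed-and-extend local aligner (exact k-mer
seeds, k = 4, at least three seeds per diagonal cluster; banded
Smith-Waterman extension with BLOSUM62 and affine gaps 11/1) with a
Karlin-Altschul expectation value computed over the search space of summed
query length times summed scaffold length, using the ungapped BLOSUM62
parameters (lambda = 0.267, K = 0.041). No numerical equivalence with any
external search tool is claimed: the E-value tiers (1e-5, 1e-20) act as
stringency levels, and the contract — tested, not assumed — is full recall
of planted genes and monotonicity of E in score.

Three guards keep local alignment honest around gene structure, all of them
consequences of reading-frame arithmetic rather than tuning: in-frame stop
codons are heavily penalised (-30) so alignments end at reading-frame
boundaries instead of running through them; gaps may not consume a stop
codon of the subject, so an alignment cannot "tunnel" across an intron by
pairing a long insertion with a deletion; and any alignment whose running
score ever falls more than 60 below its running peak is split at the
valley, because genuine coding alignments never dip that far while
intron-crossing ones must.

The spliced-gene predictor chains collinear, non-overlapping exon seeds on
one strand by dynamic programming (seed scores minus an intron penalty per
junction, with a bonus for canonical GT..AG introns; introns are capped at
2 kb by default). Junctions where adjacent seeds overlap on the query are
trimmed codon-wise, preferring the split that restores a GT..AG intron, and
the final exon is extended through the terminal stop codon, which protein
queries cannot supply. Users who prefer an external spliced aligner can
import its GFF3 output via `gene_models_from_gff()`; all the downstream
filters (exon cap, length loop, overlap resolution) operate on those models
unchanged.

LoF detection aligns candidate DNA to a reference protein with a
codon-level dynamic program that allows 1-2 nt slips (frameshifts),
whole-codon indels, and stop read-through. Two penalty relationships
matter and are asserted in tests rather than assumed: the stop penalty (18)
stays below twice the codon-gap penalty (2 x 11), otherwise the optimal
alignment hides a genuine stop codon behind an insertion-deletion pair; and
the frameshift penalty (25) is high enough that a frameshift is only
reported when a substantial aligned continuation follows it. Premature
stops within 15 codons of the reference C-terminus are not called LoF
(`stop_margin`), since natural C-terminal variation would otherwise be
labelled pseudogenising; no published value exists for this margin, so it
is a documented, configurable default.

Family assignment is by best local-alignment score against the whole
reference database (ties broken toward the lexicographically smaller
reference id), with rejection when an outgroup or decoy wins. Two
confidence floors stand in for the full pipeline's discard-everything-that-
does-not-cluster-with-known-genes tree step, which is out of scope here:
the best-match identity must exceed 0.35, and a *complete* call requires
the best-match alignment to cover at least 80% of the candidate protein.
The coverage floor exists because of a real failure mode: a pseudogene with
an early frameshift can present a long ORF that is one-third genuine gene
tail and two-thirds shifted-frame read-through; it matches its family with
local identity 1.0 but coverage far below 1.

The seven-transmembrane screen is a declared hydropathy heuristic
(Kyte-Doolittle, window 19, segment threshold 1.6, minimum segment 15
window centers, segments closer than 5 residues merged, pass at 6+
segments), standing in for dedicated TM-topology predictors. It is recorded
on every candidate and never changes a status.

## Phylogenetic loss analysis

`reclassify_gene_status()` folds all per-species evidence into four
categories (complete, high-confidence loss, low-confidence loss,
undetermined): two *distant* LoF mutations (>= 50 reference codons apart by
default), corroboration by a second assembly of the same species or a
shared mutation in a relative, or a clean deletion (gene absent with both
flanking genes on one scaffold) make a loss high-confidence; single
uncorroborated mutations or absences without flanking-gene support are
low-confidence.

`infer_loss_branches()` places one loss on the stem branch of each maximal
clade whose non-functional tips all share an identical LoF key
(`kind@codon`), and terminal losses on tips that share nothing with their
relatives; the result never nests one loss inside another.
`count_losses_by_category()` counts independent losses per branch category
and corrects the denominator: intact branches exclude loss branches *and
all their descendants*, because a branch below a loss is not available to
lose the gene again. The resulting 2 x k table feeds `contingency_tests()`
(Pearson chi-squared without continuity correction, and Fisher's exact
test).

`simulate_random_losses()` draws `n_draws` branches sequentially among the
branches that still carry a complete gene — uniformly or with probability
proportional to branch length — and marks each drawn branch and all its
descendants lost; replicates that run out of branches are discarded and
redrawn, and do not enter the p-value denominator. The per-category
p-value is the fraction of replicates with at least the observed number of
independent losses. Three design points the procedure leaves open are
resolved as follows and flagged here: the branch universe is every non-root
branch (the root has no branch above it); a drawn branch that is an
ancestor of an earlier draw absorbs it, so independent losses are drawn
branches with no drawn ancestor; and weighted sampling without replacement
is sequential (draw, remove, renormalise). The simulator is validated
against exhaustive enumeration of the draw process on all small tree
shapes.

`simulate_shared_missing()` answers an assembly-quality question: if each
of several species is missing `N_i` genes from a reference set of `G`,
how many genes would they be missing *in common* by chance? Uniform draws
have expectation `G * prod(N_i / G)`, which the simulation reproduces;
length-weighted draws model the fact that long genes fragment more easily
in poor assemblies. `screen_contamination()` covers the complementary
hygiene check, flagging mined candidates whose best foreign-database match
(at a permissive E <= 10) exceeds 90% identity on the codon-threaded
protein alignment — the signature of cross-taxon contamination rather than
homology.

## pGLS with Pagel's lambda

`pgls_fit()` fits `y = X beta + e`, `e ~ N(0, sigma^2 V(lambda))`, where
`V` holds shared path lengths from the tree and Pagel's lambda multiplies
its off-diagonal entries. Lambda is estimated by maximising the restricted
likelihood over (1e-6, 1] (Brent search, with both interval ends checked,
since boundary optima at 0 and 1 are common in practice); full ML and fixed
lambda are options. Estimation is by whitening with the Cholesky factor of
`V(lambda)`; R-squared is `1 - RSS/TSS` in whitened space against the
whitened intercept-only fit at the same lambda, and the reported p-value is
the overall F-test against that intercept-only model — one p per model, as
comparative tables conventionally report. Categorical predictors are
dummy-coded with the lexicographically first level as baseline. This
R-squared definition is declared, not asserted to be identical to any other
implementation's; the test suite cross-checks coefficients and lambda
against `nlme::gls()` with `ape::corPagel()`, which is an independent
route to the same model. `family_count_correlations()` applies `pgls_fit()`
to every ordered pair of family counts, plus the aggregate
olfactory-versus-taste pair, and `diet_from_trophic_level()` implements the
standard fish diet coding (<= 2.19 herbivore, 2.2-2.79 omnivore, >= 2.8
carnivore, after rounding to two decimals).

## What the synthetic data emulates — and what it does not

`generate_synthetic_genome()` builds receptor-like reference proteins from
scratch: seven strongly hydrophobic 21-mers joined by short mildly polar
loops, with family-appropriate termini (long extracellular N-terminal
domains for *V2R*/*T1R*), so the hydropathy screen, the family classifier
and the length thresholds all engage realistically — and, importantly, so
the repository ships no third-party sequence data. Proteins are
reverse-translated with uniformly drawn synonymous codons, mutated
according to each plant's recipe (premature stops written as TAA,
frameshifts as 1-nt indels, ambiguity as a 21-nt N run placed well inside
one exon), split by GT..AG introns at codon boundaries for multi-exon
plants, and embedded at non-overlapping positions in an iid background of
configurable GC content. Fragment plants are bracketed by a short guard
whose three reading frames all contain stop codons, so a truncated plant
can never concatenate with background into a spuriously complete ORF —
this models the biological fact that real intergenic sequence is dense in
stops, which iid background underrepresents around a deliberately planted
fragment. Edge plants sit flush against the border of their own small
scaffold.

Deliberate non-goals of the generator: no repeat landscapes, no realistic
codon-usage bias, no assembly gaps beyond N runs, no paralogue clusters
with partial identity gradients. Passing the round-trip tests therefore
demonstrates that the mining rules are implemented correctly and are
internally consistent, not that the pipeline's sensitivity on real,
repeat-rich, diverged genomes equals that of the full-scale toolchain it
models.

`generate_loss_scenario()` produces Yule trees with root-to-tip Markov
branch categories and loss branches drawn by the same sequential scheme the
null simulation uses, so planted scenarios live exactly on the simulator's
null. Draws are redrawn until mutually independent, which makes "plant
`n` losses" well-defined; each lost clade's tips share one unique LoF key
and carry up to two private ones, with globally unique positions so that
key collisions cannot fake shared ancestry.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on the forward strand everywhere
  inside the package; minus-strand features keep forward coordinates plus a
  strand flag, and CDSs are reverse-complemented at extraction. 1-based
  conversions happen only at the I/O boundary (tabular hit import, GFF3).
* Ties are broken deterministically everywhere: (score desc, start asc,
  query id lexicographic) for best-hit merging and model selection,
  lexicographic reference ids in family assignment. Mining contains no
  randomness at all; every stochastic function takes a `seed`.
* All randomness flows through R's RNG (including the C++ simulation
  kernel, via R's own generator), so `set.seed()`/`seed =` make every
  result bit-reproducible.
* Degenerate inputs error early with plain messages: empty genomes return
  empty tables rather than failing; `n_draws` exceeding the branch count,
  missing categories, unknown scaffolds and singular design matrices are
  rejected; non-ultrametric trees are accepted with a warning.
* Problem sizes in the tests (twenty 1-Mb genomes with 12 plants each for
  the mining round trip; 40,000 replicates for simulation-versus-
  enumeration; 200 seeds for pGLS coverage) were chosen as the smallest
  scales at which the statistical assertions have comfortable Monte-Carlo
  margins.

## Known limitations

The built-in aligners favour transparency over sensitivity; strongly
diverged family members (well below ~50% identity to every reference) may
be missed where a profile-based search would find them, and the GFF3 import
path exists precisely so users can substitute a heavier spliced aligner.
The identity and coverage floors are proxies for phylogenetic placement,
which the package deliberately does not do. The pGLS implementation covers
the single-response, fixed-tree case with Pagel's lambda only — no
Ornstein-Uhlenbeck models, no measurement error, no tree uncertainty.
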