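---
title: "Testing scleractinian monophyly: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing scleractinian monophyly: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coralphy` asks one question of multi-gene data: do the stony corals
(Scleractinia, the union of the Complexa and Robusta clades) form a clade,
with the skeleton-less Corallimorpharia as their sister group, or are
corallimorpharians nested within the corals ("naked corals", implying
secondary loss of calcification)? This vignette documents the models and
algorithms behind each stage, the tunable parameters, what the simulator
does and does not emulate, and the design decisions taken where several
reasonable choices existed.

## Substitution models and likelihood

Sequences evolve under reversible Markov models: GTR (six free
exchangeabilities, frequencies taken as observed unless optimized) for
nucleotides, the published JTT empirical matrix for amino acids
(optionally `+F`, replacing the JTT frequencies with alignment-wide
observed frequencies). The generator is scaled so one unit of branch
length is one expected substitution per site at stationarity.

Among-site rate variation uses the discrete-gamma approximation with
`k = 4` categories; each category rate is the *mean* of its
equal-probability quantile bin, so the rates average to one for every
shape `alpha`. With a proportion `p_inv` of invariant sites the variable
classes' rates are divided by `1 - p_inv`, which keeps the expected rate
of the full mixture at one; conventions differ between programs on this
point, so it is stated here explicitly (the chosen convention matches
phangorn and PhyML rather than RAxML, and fitted branch lengths are
therefore comparable across `p_inv` values).

Likelihoods are computed by Felsenstein pruning over pattern-compressed
columns in compiled code, with per-pattern rescaling engaged only when
partial likelihoods approach the underflow threshold (`1e-220`). Gaps and
ambiguity codes enter as indicator vectors over their compatible states; a
fully ambiguous code is identical to a gap. The invariant class
contributes `p_inv * sum(pi[s])` over the states compatible with every
taxon at that column, i.e. only at constant-compatible sites. Matrix
exponentials use the symmetric eigendecomposition of
`diag(sqrt(pi)) Q diag(1/sqrt(pi))`, valid for all reversible models used
here.

## Optimization and tree search

Branch lengths are optimized one at a time by Brent search on the log
scale within `[1e-8, 10]`, along an Euler tour of the tree so each sweep
costs a constant number of full pruning passes. Sweeps stop when the
log-likelihood improves by less than `1e-4` (`optimize_branch_lengths`'s
contract; the likelihood never decreases across sweeps). Model parameters
are fitted coordinate-wise — `alpha` and `p_inv` by bounded
one-dimensional search, exchangeabilities by L-BFGS-B on log scale,
frequencies on the simplex or fixed at observed counts — cycling with the
branch lengths until the joint gain per cycle is below `1e-3`.

Tree search starts from neighbor joining on maximum-likelihood pairwise
distances and hill-climbs over nearest-neighbor interchanges. Candidates
are scored with the central branch re-optimized (a common and effective
shortcut); the best candidate is then fully re-optimized and accepted only
if it improves the log-likelihood by more than `1e-3`. Bootstrap
replicates resample columns with replacement (within partition subsets
when a scheme is given) and rerun the full search per replicate; because
only the replicate *topologies* enter the support counts, replicate
searches use a looser branch-length tolerance (`0.1` per sweep, at most 4
sweeps) — support values are unchanged while replicates run several times
faster. The study's original rapid-bootstrap shortcut is not reproduced;
the plain nonparametric bootstrap is substituted, which only matters below
the saturated 100% support level at which the critical nodes are read.

## Bayesian MCMC

A single Metropolis-Hastings sampler stands in for both supermatrix and
per-gene Bayesian analyses (they differ only in data and model). Priors:
uniform over unrooted topologies, exponential with mean 0.1 on branch
lengths, exponential with mean 1 on `alpha`, uniform on `p_inv`, flat
Dirichlet on frequencies and exchangeabilities. Proposals: NNI across a
random internal edge; a single-branch multiplier with log-uniform factor
in `[1/e, e]`; and model-parameter moves (multipliers for `alpha`,
a reflecting sliding window for `p_inv`, Dirichlet proposals with
concentration 500 for frequencies and exchangeabilities), each with its
exact Hastings correction. Default weights are 0.45/0.45/0.10. The
default schedule mirrors the study design — 2,000,000 generations,
sampling every 1,000, 25% burn-in, four independent runs — and is scaled
down through `mcmc_settings` everywhere in the tests.

Runs start from the NJ tree on ML distances (a random tree under
`prior_only`); with the strong signal of concatenated data the chains
reach the posterior mode within a small fraction of the burn-in.
Correctness of the sampler is checked three ways in the test suite:
prior-only runs recover the branch-length prior mean, a two-taxon
posterior matches direct numerical integration of prior times likelihood,
and a four-taxon topology posterior matches exhaustive computation over
the three topologies with Monte-Carlo-integrated marginal likelihoods.
Convergence is summarized by the maximum between-run split-frequency
difference (`maxdiff`, converged below 0.1 — the cited tools' documented
rule, adopted here even though the source text prints the inequality the
other way around) and the initial-positive-sequence effective sample size
of the lnL trace (converged above 300).

## Supermatrix and partitions

Per-gene amino-acid alignments are back-translated onto their coding
sequences (each residue becomes its codon, gaps become `---`, internal
stops and translation mismatches are hard errors naming taxon and
position), concatenated with exact charset bookkeeping (one-to-one
orthologs only: taxon-set mismatches are errors, never padded), and
partitioned either by gene or by codon position within gene — the
pre-merge partition definitions. The greedy model-based merging used by
PartitionFinder-style tools is deliberately out of scope: the hypothesis
tests are invariant to it, and the merge heuristic belongs to that tool.
Partitioned likelihoods share topology and branch lengths across subsets
with one positive rate multiplier per subset (proportional model,
parameter-light), normalized to a length-weighted mean of one.

## Classification and the gene-pattern table

A tree is classified after (conceptually) rooting on the outgroup:
`monophyly` when Complexa+Robusta forms a clade, otherwise `naked_coral`
when Robusta+Corallimorpharia forms a clade, otherwise `other`. On a
binary tree containing at least one complexan the two conditions are
mutually exclusive, so the precedence order never decides a call;
actiniarian placement is ignored because neither hypothesis constrains
it. Bayesian per-gene results are classified on the majority-rule
consensus tree (not the maximum-a-posteriori topology), matching how
consensus summaries are read in practice; polytomous consensus trees are
classified as-is, since the clade tests are well defined on them.

Genes are grouped by their tuple of calls across inference configurations
and ranked by abundance. The aligned lengths of the two fully concordant
classes are compared with a Mann-Whitney U test: `U` counts pairs with
`x > y` plus half the ties; the exact mode computes the full null
distribution of the rank sum by dynamic programming over (doubled)
midranks, which handles ties exactly and is used automatically up to 40
observations; the normal mode applies the tie-corrected normal
approximation with continuity correction. Two-sided p-values are
`2 * min(lower tail, upper tail, 0.5)`. Aligned (trimmed-matrix) column
counts are used as "gene length", the quantity actually available after
alignment.

## Concordance factors

For each candidate clade, each gene contributes the weighted frequency of
its posterior sample containing the clade; the sample-wide concordance
factor is the unweighted mean over genes. This is the independence limit
of Bayesian concordance analysis: the Dirichlet-process prior that shares
topologies across genes in the original two-stage method is not
implemented, because the downstream inference (broad gene support for a
clade) reads CF magnitudes, not the gene-clustering structure. The 95%
credibility interval is Monte Carlo: per replicate one topology is drawn
per gene and the concordant fraction recorded. The primary concordance
tree greedily assembles mutually compatible clades by descending CF.

## Composition and saturation diagnostics

Composition profiles count only unambiguous residues; A+T content for
nucleotides, and the fractions of amino acids encoded by A+T-rich codons
(F, Y, M, I, N, K) and G+C-rich codons (G, A, R, P) for proteins, with
unweighted per-clade means (weighting by gene length is not applied, as
the per-clade averages are descriptive). Homogeneity across taxa is a
Pearson chi-square on the taxa-by-states count table. The saturation
screen divides the mean per-site entropy of the observed states by the
exact expected entropy of the same number of iid draws from the observed
base frequencies; the critical value is calibrated by simulating
alignments of matched dimensions over a ladder of tree depths and
locating, by logistic regression, the index level at which
neighbor-joining recovery of the reference topology drops to 50%. The
original tool's published critical-value regression is not reproduced (no
formulas are available); only the significance verdict feeds the
downstream decision, and the simulation-based calibration answers the
same question on matched dimensions.

## The simulator and what passing tests mean

`scenario_spec()` defaults encode the study conditions: 3 Complexa,
6 Robusta, 3 Corallimorpharia, 2 Actiniaria and one octocoral outgroup
(15 taxa); 291 genes with log-normal lengths (median 400 codons, sigma
0.4, floored at 30 codons — the implied amino-acid supermatrix is on the
order of 1.2e5 columns); a root-to-tip depth of 0.3 expected
substitutions per site; a 15% minority of genes generated under the
alternative topology at one third the length. Within-group subtrees are
random coalescent-style ultrametric trees (the true within-clade
relationships are irrelevant to the hypotheses); backbone nodes sit at
fixed fractions of the total depth (actiniarian split at 0.2, the
corallimorph split at 0.4, the Complexa/Robusta split at 0.55, group
crowns in the last quarter), so every root-to-tip path equals the
requested depth. The default generating model is GTR+G+I with mildly
AT-rich frequencies (0.28/0.22/0.22/0.28, i.e. 56% A+T as observed in
hexacorallian nuclear data), transition-favouring exchangeabilities,
`alpha = 0.6` and `p_inv = 0.25` — realistic values for conserved nuclear
protein-coding genes.

Genes are simulated as codon triplets under the nucleotide model; codon
columns containing a stop codon in any taxon are redrawn, conditioning
the generator on stop-free coding sequences, and amino-acid companions
are obtained by translation, so `back_translate()` round-trips exactly.
The simulator does not produce indels, alignment or assembly errors,
missing taxa, paralogy, or lineage-specific rate shifts; passing tests
therefore demonstrate correctness of the inference machinery under the
study's idealized design, not robustness to those real-data artifacts.
Compositional bias can be injected deliberately
(`inject_composition_bias`): target-group sites are redrawn, with the
smallest probability admitting a valid redraw distribution, so the
expected composition moves by exactly the requested shift — this is what
the homogeneity screen's power is measured against.

## Numerical choices and scale

Tolerances: branch-length sweeps `1e-4` (search acceptance `1e-3`),
model-fit cycles `1e-3`, Brent bracket tolerance `2e-4` on log branch
length, branch-length bounds `[1e-8, 10]`. Ties in pattern ranking and
model selection break toward first occurrence and fewer parameters
respectively. Desk-scale problem sizes used throughout the tests and the
analysis stages — 20-50 genes of a few hundred codons, 100 bootstrap
replicates, 50,000-generation two-run MCMC — were chosen so that each
stage's statistical behaviour (full support for the generating topology,
concordance factors tracking the discordant fraction, calibrated
p-values) is already saturated at that size; the full study scale of 291
genes only narrows Monte-Carlo error further. Degenerate inputs are
handled explicitly: three taxa return the unique unrooted topology with a
warning, two-taxon trees are allowed in likelihood and MCMC (topology
fixed), empty alignments, mismatched leaf sets, ragged matrices and
negative branch lengths are errors.

## Known limitations

Site-heterogeneous mixture models (CAT-style) are out of scope, as are
SPR/TBR search, Metropolis-coupled chains, marginal-likelihood
estimation, genome-wide (as opposed to sample-wide) concordance factors,
and topology tests of the AU/SH family. The bootstrap and MCMC defaults
are calibrated for the 15-taxon design; much larger trees would want
profile-likelihood shortcuts and smarter proposal mixtures than the ones
shipped here.
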