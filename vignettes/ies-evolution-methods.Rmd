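---
title: "Models and methods for IES evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for IES evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesevo)
```

# Scope

`iesevo` studies the evolutionary dynamics of internal eliminated
sequences (IESs) — the short, TA-bounded, germline-limited segments that
*Paramecium* excises from its developing somatic macronucleus (MAC). The
package provides (i) generators that simulate every input the analysis
needs (genome pairs, read sets, gene families, gain/loss histories,
mobile-element bursts), (ii) the inference machinery (ancestral state
reconstruction under a two-rate Markov model, duplication-aware branch
rates, mobile-family discovery, k-mer genome sizing with a somatic-DNA
contamination correction), and (iii) reporting utilities. Because every
generator records its ground truth, each inference stage is validated by
parameter recovery rather than by fixture comparison.

# Sequence conventions

An IES is stored as the excised fragment, which always begins with `TA`;
the germline (MIC) sequence around an IES is
`prefix + excised + TA + suffix` and the somatic (MAC) sequence is
`prefix + TA + suffix` — one TA of the boundary pair is left at the
junction. This convention makes excision/reinsertion a bit-exact
round trip (`insert(excise(x)) == x`), which the generators re-check on
every simulated genome. Coordinates are 0-based and half-open
internally; GFF3 output is 1-based inclusive per the standard.

A *floating* IES is one whose boundaries overlap a tandemly repeated
motif, so that excising an equally long TA-bounded fragment at a shifted
position produces the identical MAC sequence. `detect_floating()`
reports every offset within a ±10 bp window whose excision is
equivalent; the bound applies to the offset, not to the total span of
the alternatives. The canonical representative of a floating IES is the
annotated position, with offsets stored relative to it (the leftmost
valid offset is a deterministic alternative representative when one is
needed). The generator engineers floating boundaries by requiring a
second TA two (or more) bases downstream of the junction and seeding the
fragment start with the MAC motif, so a configurable fraction of
simulated IESs is floating by construction.

# The species tree fixture

`species_tree()` returns the nine-species phylogeny used throughout: the
eight *aurelia*-complex species (subclade A: `pso`, `pse`; subclade B:
`ppr`, `pbi`, `ppe`, `pte`, `poc`, `ptr`) with *P. caudatum* (`pca`) as
outgroup, internal nodes labelled `n1`..`n8` in preorder. The topology
is fixed; branch lengths (substitutions per site, the time
proxy of all rate computations) are a modelling choice of this package,
set once to plausible values: short internal branches
(0.02–0.05), terminal branches 0.06–0.12 within *aurelia*, a deep
*aurelia* stem (0.25) and a long outgroup branch (0.45). All rates are
therefore "per unit branch length", never absolute time.

# Genome-size estimation and the contamination correction

`count_kmers()` counts canonical 17-mers (a k-mer and its reverse
complement collapse onto the lexicographically smaller encoding).
`find_depth_peak()` delimits the sequencing-error cloud by the first
local minimum after multiplicity 1 and takes the largest peak beyond it
as the sequencing depth; `estimate_genome_size()` divides the k-mer mass
beyond the cutoff by that depth. Note that the relevant depth is k-mer
coverage, which is lower than read coverage by a factor
`1 - (k - 1) / read_length`.

MIC preparations are contaminated by the highly polyploid MAC.
MAC-destined k-mers then receive coverage from both sources and pile up
in a second peak above the true MIC depth `d` (the first peak). The
correction treats the coverage excess of every k-mer with multiplicity
`m` in `(d, 500]` as MAC-derived: such k-mers are counted at depth `d`
(equivalently, the fraction `(m - d)/m` of their mass is removed), while
k-mers deeper than 500 are taken to be genuinely repeated germline
sequence and kept whole. The corrected size is the remaining mass over
`d`. On the package's own recovery scenario (1 Mb MIC, 40% MIC-specific
sequence, half the read mass of MAC origin) this correction is exact up
to sampling noise, whereas proportional-attribution variants that
down-weight the whole sub-500 range (including the MIC-specific peak)
are not; that is why the excess-depth form was adopted. The depth-500
ceiling is a configuration default (`mac_attribution_max_depth`), since
it is tied to the sequencing depths of the original study. A limitation
follows from the same logic: true two-copy germline repeats whose
multiplicity lands between `d` and the ceiling are partially
mis-attributed when a correction is requested, so the correction should
only be applied to samples with evidence of contamination.

The contamination fraction itself comes from the IES retention score
(IRS = retained / (retained + excised) junction reads). In a pure MIC
sample the IRS distribution peaks near 1; MAC reads add excised-junction
support and shift the peak. `estimate_mac_fraction()` reports one minus
the histogram mode (bin width 0.05, centres at multiples of 0.05); the
mean IRS is attached as a diagnostic only, because the mode is robust to
the tails near 0 and 1. Equating the IRS complement with the MAC *mass*
fraction implicitly assumes comparable local coverage scaling, i.e.
that the somatic and somatic-destined germline sequence have similar
sizes; when 40% of the MIC is germline-limited this identification is
biased (the simulation shows a 0.5 mass fraction reading as ≈0.65), but
the histogram-based size correction above does not depend on it.

# The gain/loss model

Presence/absence of an IES locus evolves on a fixed (gene) tree as a
two-state continuous-time Markov chain with one gain rate `g` and one
loss rate `l`, shared by all loci of a family; priors are
`g, l ~ Exp(alpha)` with hyperprior `alpha ~ Exp(1)`. The likelihood is
Felsenstein pruning (compiled); uncertain tips enter as missing data
(partial likelihood (1,1)). `mcmc_sample()` is Metropolis-within-Gibbs:
multiplicative log-normal proposals for the rates — tuned towards a
20–50% acceptance rate during an initial tuning phase only — and an
exact conjugate Gibbs draw for `alpha` (its full conditional is
Gamma(3, g + l + 1)). By default every 50th post-burn-in sample is kept
and the first 10% discarded; ancestral marginals (the two-pass up/down
algorithm) are averaged over the retained samples. Split-R̂ and an
autocorrelation-based effective sample size are reported;
a zero-variance chain flags `diagnostic_ok = FALSE` rather than failing
silently.

Root handling deserves care, and four options are exposed:

* `stationary` (default): the chain's stationary frequencies
  `(l, g)/(g + l)`. Correct when the root is an exchangeable draw from
  the process.
* `uniform`, or an explicit numeric prior.
* `empirical`: each locus gets its own smoothed tip prevalence.
* `sampled`: a free per-family root-occupancy probability with a
  uniform prior, sampled alongside the rates.

The `sampled` option exists because simulated (and plausibly real)
families are *not* at stationarity at the root: an ancestral insertion
burst seeds many loci that the stationary prior would re-explain as
parallel recent gains on the root-adjacent branches, badly inflating
their apparent gain rates. Estimating the root occupancy as a parameter
removes that artefact without leaking any per-locus truth into the
inference.

A second modelling device matters for rate calibration: the presence
matrix may carry a collapsed all-absent site pattern weighted by the
number of well-aligned TA sites that harbour no IES in any species
(`weights` argument, standard site-pattern weighting). Without it the
fitted per-locus gain rate is conditioned on loci that exist somewhere,
which inflates it by orders of magnitude and smears ancestral posterior
switches across neighbouring branches; with it, `g` is interpretable as
a per-site insertion rate and posterior switch placement is sharp.

# Branch rates on reconciled gene trees

A species-tree branch `i -> j` corresponds, in a reconciled gene tree,
to every path connecting a node labelled speciation(`i`) to a node
labelled speciation(`j`) through duplication nodes only; a duplication
doubles the number of such paths (`k` counts them). Paths interrupted by
gene loss lack the speciation(`j`) endpoint and are excluded — both from
the path count and from the rate denominators, which keeps the estimator
consistent. Per path, `p+` accumulates the positive per-edge increments
of the posterior probability of presence and `p-` the negative ones;
per-edge increments (rather than endpoint differences) count every
switch on a multi-edge path, and on the worked two-path duplication
example they reproduce the expected arithmetic exactly
(G = 5 gains/kb/unit, L = 2 losses/IES/unit). The branch estimators are

    G_ij = sum_g p+_gij / (sum_g n_g * k_gij * b_ij)
    L_ij = sum_g p-_gij / (sum_g I_g * k_gij * b_ij)

with `n_g` the well-aligned alignment length (kb), `I_g` the number of
IES loci of the family and `b_ij` the species-tree branch length. Two
intrinsic properties of these estimators are worth knowing. First, the
loss denominator counts every locus of the family on every branch, so
loci that did not yet exist (gained later) or no longer existed (lost
upstream) dilute `L_ij` towards zero; the effect is proportional to the
share of such locus-branch pairs. Second, with duplications the paths
spanning a branch share their pre-duplication segment, so `k * b`
slightly over-states the amount of independent history.

Insertion dating collects every gene-tree node with posterior presence
above 0.99, maps their MRCA onto the species tree (speciation nodes via
their label, duplication nodes via the LCA of their descendant species)
and classifies the insertion as `New` (single species), `Old` (MRCA at
the root, i.e. predating the *aurelia*/*caudatum* split) or the species
node label otherwise.

# The recovery study

`recovery_study()` is the package's end-to-end validation harness: 500
families on the reference phylogeny, true gain rate 1.0 gains/kb/unit
and loss rate 0.2 losses/IES/unit, 5 kb of well-aligned sequence per
family, 40 ancestral loci per kb at the root (the root density is a free
parameter of the generator; an ancestral-dominated catalog keeps the
loss-denominator dilution discussed above small), a TA-site panel of
100 sites/kb for the weighted absent pattern, `root_prior = "sampled"`,
and a desk-scale MCMC (2,000 sampling iterations after a 400-iteration
tuning phase, thinning 10) per family. Branch rates are then compared to
the truth on branches with at least 50 expected events, and
`dating_study()` scores insertion dating on the loci whose posteriors
are decisive (above 0.99 at every truly present node, below 0.01 at
every truly absent one) — dating is only claimed for well-reconstructed
loci. These sizes keep the whole study within a few minutes on one CPU
while leaving hundreds to thousands of events per tested branch.

The study uses duplication-free families by default: with duplications,
branch-level truth itself becomes ambiguous (shared pre-duplication
segments), so duplication-aware path enumeration is validated separately
against a DFS oracle and the two-path worked example rather than by
rate recovery.

What passing recovery does *not* show about real data: the generator
plants substitution-only mobile elements, engineered (not emergent)
floating boundaries, uniform AT composition, no assembly error and no
detection noise beyond the explicit uncertainty masking; real catalogs
add all of these.

# Mobile-IES discovery

All-vs-all comparison uses 12-mer seeded, gapped local alignments on
both strands (match +2, mismatch −3, gap open 5, gap extend 2), with an
*empirical* expectation score: best local scores of first-order-Markov
shuffled decoy pairs (matched dinucleotide composition, hence matched AT
content) are fitted with a Gumbel tail and multiplied by the number of
possible pairs. The conventional threshold values are kept (1e-8 for
mobile-element discovery, 1e-5 for permissive homolog counting) but they
are calibrated quantities of this scorer, not of BLAST. A hit counts as
whole-element homology only when the alignment covers the first and last
20 nt of both sequences; since a local alignment is contiguous this is a
full-length-coverage rule, and it is what separates mobile elements from
repeats nested inside pre-existing IESs. Pairs whose 100 + 100 nt
MAC-side flanks align at ≥75% identity over ≥150 nt are homologous loci
(vertical inheritance), the rest are candidate mobile copies; candidates
cluster by single linkage, clusters with ≥10 members are profiled (star
alignment on the best-connected member, per-column log-odds against the
empirical IES base composition, gap-dominated edges trimmed), and
profiles are scanned over the whole catalog (both strands, Gumbel-
calibrated expectation, threshold 1e-3). A significant match reaching
both IES extremities within 3 bp is a *mobile* copy, an internal match a
*nested* one; each IES is assigned to its best-scoring profile so that
split clusters of one underlying family cannot double-count copies.
Families whose consensus exceeds 92% A+T are flagged
composition-suspect (similarity may be compositional rather than
homologous) instead of silently dropped.

# Reliability filters and reporting

IESs on scaffolds shorter than 10 kb are removed outright. Genes with
extreme MIC-read coverage (below the per-species 10th or above the 90th
percentile of mean per-gene depth, or under 15 reads) mark their IESs as
uncertain — those enter the presence matrices as missing data — and
flagged genes without any annotated IES are reported as potentially
containing undetected ones. Weak IESs are called at strictly more than
10% retention. MAC-variable regions are called from scaffold extremities
in 2 kb windows, reported only above 4 kb. Grouped proportions are
tested by chi-squared without continuity correction (the choice is
recorded in the report metadata), with a small-sample flag when any
expected cell drops below 5; expression deciles are equal-count bins;
IES density is counted per kb of MAC-destined sequence with at least
15x MIC read depth.

# Numerical choices and degenerate inputs

Pruning rescales partial likelihoods per locus to avoid underflow; the
transition matrix is the closed form of the two-state chain and reduces
to the identity when `g + l = 0` or `t = 0`. Histogram mode ties in
`estimate_mac_fraction()` warn and resolve to the larger-IRS mode. A
monotonically decreasing k-mer histogram (no genomic peak) is an error,
not a silent zero. `build_genome_pair()` fails explicitly when the
requested IES density cannot be placed with the minimum junction
spacing (12 bp, which also guarantees clean ±10 bp floating-detection
windows). Families the sampler cannot initialize raise an error naming
the cause. All generators are deterministic functions of their seed;
derived seeds use a rolling-hash splitter so that family-level streams
are distinct.

# Known limitations

* Read simulation has substitution errors only (no indels, no quality
  ramps), and junction support counting uses a fixed 5 bp anchor.
* The conserved-block filter is a deterministic three-parameter stand-in
  for the usual block-filtering heuristics; its mask can be replaced by
  an externally computed one via TSV.
* The IRS-based contamination fraction equates a read-mass fraction with
  the retention mode, which is biased when the MAC and MAC-destined MIC
  differ substantially in size (see above).
* Mobile-element profiles are position-specific score matrices, not
  profile HMMs: they tolerate substitutions but not indels within
  copies, matching the generator's substitution-only element model.
* Branch-rate estimators inherit the dilution biases of their
  definitions, quantified in the recovery study.
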