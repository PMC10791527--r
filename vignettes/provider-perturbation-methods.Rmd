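---
title: "Methods: multi-layer network analysis of a food-provisioning perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-layer network analysis of a food-provisioning perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provnet)
```

## The question and the design

provnet analyses a single-individual, in-situ perturbation of a primate
social group: one mid-ranked "provider" female is given control of a
high-quality food resource, and the question is whether — and in which of
her social relationships — her network position changes. The design
compares a baseline observation phase with an experimental phase of equal
length (four weeks each by default). Behaviour is recorded as dyadic
events in six layers: three agonistic/status layers (aggression,
displacement, peaceful silent bared-teeth displays, "SBTs") and three
affiliative/socio-spatial layers (grooming, huddling, proximity).
Aggression, displacement, SBT and grooming events are directed; huddling
and proximity are undirected associations.

Because the perturbation targets one individual, the inferential unit is
the *focal's change relative to the group's change distribution*, not a
group-level model fit. Every downstream statistic follows from that idea.

## Networks and centrality

For each behaviour and phase a weighted network is built over the eligible
individuals — adults (3+ years) present in both phases; animals removed
during the study are excluded from group-level summaries, and the focal is
always retained. Edge weights are raw dyadic event counts: observation
effort is the same in both phases, so counts are directly comparable and
no rate normalisation is applied. Aggression events enter the network only
when met with a clear submissive response, i.e. only decided conflicts
carry dominance-relevant signal. Isolated eligible individuals are kept as
nodes so that a centrality of zero is distinct from exclusion; the group
change distributions therefore always cover the same individuals in every
layer. Whether isolates should contribute to group means is, in our view,
genuinely open; keeping them is the default and the networks expose enough
structure (edge lists, GraphML) to redo summaries without them.

Centralities are the standard weighted-graph pair: *degree* (number of
distinct partners, split in/out for directed layers) and *strength* (total
number of interactions). Nothing fancier (eigenvector, betweenness) is
computed: the perturbation hypotheses concern how much and with how many
partners the focal interacts.

## The focal change statistic

For a metric $x$ (a degree or strength variant) and individual $i$, the
change score is $\Delta_i = x_i^{\mathrm{exp}} - x_i^{\mathrm{bl}}$. The
focal's change is standardised against the group:

$$ z = \frac{\Delta_{\mathrm{focal}} - \bar{\Delta}}{s_\Delta}, $$

where $\bar\Delta$ and $s_\Delta$ are the mean and sample ($n-1$) standard
deviation of the change scores over **all** eligible individuals,
*including the focal*. Including the focal makes the reported group
columns and the z-score internally consistent (the published table this
package reproduces is consistent only under that convention); at $n
\approx 80$ the inclusion/exclusion difference is below the 2-decimal
reporting precision anyway. Two-tailed p-values are normal-tail
probabilities, $p = 2(1 - \Phi(|z|))$ — a deliberately conservative
reading when no direction is assumed; a one-tailed variant
$1 - \Phi(z)$ is available where a directional hypothesis exists (net
grooming receipt).

The normal reference is a choice, not a necessity: the change scores are
integer-valued and their distribution is only approximately normal. The
pipeline therefore offers `p_mode = "permutation"`, which relabels which
eligible individual is "focal" and recomputes $z$. Because the statistic
under relabelling depends only on each individual's own standardised
change, the permutation null can be enumerated exactly — every individual
takes a turn as focal — and the exact version is the default
(`n_permutations = NULL`); sampled permutation is available but only adds
Monte-Carlo noise at these group sizes. The default mode remains
`"normal"` to match the reference analysis.

Under the null (no perturbation) the focal is exchangeable with every
other group member, so the calibration property is distribution-free:
$|z| > 1.96$ should occur in roughly the fraction of group members that
lie beyond 1.96 group standard deviations — about 5% for the near-normal
change distributions here. The test suite measures this over 1000
simulated null studies per network and bounds it at 7% to absorb the
discreteness of small-count layers and Monte-Carlo noise.

## Grooming balance

Grooming balance is grooming received minus grooming given (in-strength
minus out-strength in the directed grooming network of one phase);
positive values mean net receipt. Balances sum to zero over the group when
all participants are eligible, since every event contributes $+1$ to one
member and $-1$ to the other. The focal's balance is standardised with the
same focal-z machinery. Here the focal-included and focal-excluded
variants can differ noticeably (the focal may be the main outlier of a
distribution whose spread she then inflates), and published analyses are
not always explicit about the convention; `grooming_balances()` therefore
reports both. A fully reciprocal network has a degenerate (zero-variance)
balance distribution; the balances are still returned, with no z.

## Dominance ranks from pathway-completed win-loss matrices

Only status signalling is used for ranking: a displacement credits the
displacer with a win; a peaceful SBT credits the *recipient*, because the
signal marks the signaller as the subordinate. Aggression outcomes are not
used — decided conflicts already require a submissive response, but the
cleaner status currency is the signalling itself.

Direct observation leaves many dyads empty, so the win-loss matrix is
completed with transitive pathways: if A dominates B and B dominates C,
the A→B→C chain is evidence that A dominates C. Concretely, for ordered
pair $(i, j)$,

$$ \mathrm{imputed}_{ij} = w_{ij} + \sum_{\ell = 2}^{L}
   \sum_{\text{simple paths } i \to \cdots \to j,\ |path| = \ell}
   \prod_{\text{steps } (a,b)} \frac{w_{ab}}{w_{ab} + w_{ba}}, $$

with $w$ the direct counts and $L$ = `max_path_len` (default 2). Each
step contributes its win *proportion* rather than its raw count, so a
chain's total contribution is at most 1 and indirect evidence cannot swamp
direct observation; steps with no direct data contribute nothing. This is
a deliberately transparent reduction of percolation-style ranking methods
to their core idea; it is not a reimplementation of any specific package's
algorithm. Dyadic dominance probabilities are
$d_{ij} = \mathrm{imputed}_{ij} / (\mathrm{imputed}_{ij} +
\mathrm{imputed}_{ji})$, with $d_{ij} = 1/2$ where no information exists
at all, and ordinal ranks order individuals by mean dominance probability
(ties: more total direct wins first, then id — a documented, deterministic
tie-break).

Two properties worth knowing. First, on a fully observed transitive
tournament the recovered order is exactly the topological order. Second,
identifiability has a hard limit: an *adjacent* pair in the latent
hierarchy that is never observed (directly, and for which no transitive
chain exists — chains around adjacent pairs require rank-reversed
evidence) yields exactly tied mean probabilities, and no ranking method
can order it from the data. Simulation-based recovery checks must
therefore use observation densities at which adjacent dyads are observed
with high probability; the test suite uses 20 individuals with dense
status signalling (8 expected signals per dyad per phase), where exact
recovery of the full order occurs in well over 95% of replicates.

## Partner composition

Kinship is matriline-label equality; "descended from the same founding
female" collapses to matriline membership because the roster carries no
pedigree. For each socio-spatial layer and phase, the focal's events are
summarised as total interactions, % involving kin, distinct partners and
% kin partners, with percentages rounded half-up to 2 decimals (the
convention of the tables this format mirrors). Rank composition of
agonistic partners is summarised as the percentage of events received
(or given) whose other participant outranks the individual; counting per
event is the default and per-distinct-partner counting is available via
`mode = "actors"`, since published phrasing is ambiguous between the two.

## The synthetic-data generator

`simulate_roster()` / `simulate_phase()` / `generate_study()` emulate the
study's data structure: 83 adults (the study group's adult count) in 7
matrilines, a latent strict dominance order with the focal placed exactly
mid-hierarchy (rank $\lceil n/2 \rceil$ = 42 of 83), and two 4-week
phases. Dyadic event counts are independent Poisson draws per behaviour
layer; Poisson is the simplest law consistent with count-valued edge
weights, and no overdispersion is added by default. Direction within a
dyad follows the hierarchy for agonistic layers — the higher-ranked member
acts with probability $\mathrm{logistic}(s \cdot \text{rank gap})$, with
steepness $s = 0.15$ per rank unit by default — and is reversed for
peaceful SBTs, which flow up-hierarchy from the subordinate signaller.
Affiliative layers are rank-blind but kin-biased: within-matriline dyads
have their rates multiplied by `kin_multiplier` (default 5).

Default per-dyad-per-phase rates (aggression 0.25, displacement 0.25,
SBT 0.07, grooming 0.22, huddling 0.45, proximity 0.45) were calibrated
once so that per-individual strengths land in the observed order of
magnitude for a mid-ranked female — roughly 10 decided aggressive events
and 12 grooming bouts received and near 50 huddling/proximity
associations per phase — and so the group change-score spreads match the
published scale. They parameterise plausibility, not any fitted dataset.

Perturbation effects are multiplicative rate modifiers on the focal's
dyads in the experimental phase only (`effect_spec()`): received
aggression, received SBTs, grooming received/given, huddling and
proximity. All-1 effects give an exchangeable null. Seeds split
deterministically per phase (`seed * 1009 + phase-index`, mod $2^{31}-1$),
so each phase is independently reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: temporal structure within phases
(observation sessions, contagion between events, the feeder-box schedule),
overdispersion and dyad-level rate heterogeneity beyond kinship,
correlation between layers (real grooming and proximity are coupled),
rank-biased affiliation, demographic change during the study, and
observer error. It establishes that the *statistical machinery* behaves:
calibrated type-I error under the null, recovery of injected effects, and
agreement with brute-force oracles.

## Numerical conventions and degenerate inputs

- Dates are ISO-8601; phase is an explicit column, not inferred from dates.
- Undirected events keep their recorded (initiator, recipient) pair;
  direction is ignored when building undirected layers, which are
  invariant to swapping the pair.
- The z-statistic requires a positive group standard deviation and at
  least 3 individuals; degenerate distributions raise an error (or, for
  grooming balance listings, return balances without a z).
- Percentages with a zero denominator (no events received, no partners)
  are reported missing, never 0 or 100.
- Rounding for display is half-up at 2 decimals; all stored values are
  full precision.

## Problem sizes used in the tests

Unit and oracle tests run at 5-20 individuals; calibration uses 1000
simulated null studies and effect recovery 200 perturbed studies at the
default 83-adult scale; dominance recovery uses 100 steep-hierarchy
studies of 20 individuals. These sizes give Monte-Carlo standard errors
well inside the tested bounds while keeping the default suite around two
minutes.

## Limitations

The design has a single focal: the z-statistic quantifies how unusual her
change is against the group, but with $n_{\text{focal}} = 1$ it cannot
attribute the change to the manipulation as opposed to any other
individual-level shock in the same window. The dominance reduction uses
fixed-length pathway completion, not a full percolation/conductance
treatment, and deliberately excludes dynamic (Elo-style) ranking. Kinship
is matriline membership only. None of the statistics model dyad-level
non-independence; the permutation mode relaxes only the normality
assumption, not exchangeability.

## A worked example

```{r example}
params <- simulation_params(n_adults = 30, n_matrilines = 5, seed = 11)
effects <- effect_spec(aggression_in_mult = 3, sbt_in_mult = 5)
report <- run_study(run_config(sim_params = params, sim_effects = effects,
                               seed = 11))
render_table1(report)
report$ranks$rank_correlation
```
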