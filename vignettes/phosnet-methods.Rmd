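---
title: "Methods: temporal phosphosignaling network reconstruction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal phosphosignaling network reconstruction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnet)
```

# The model

`phosnet` reconstructs how a phosphorylation signal propagates from a
stimulated receptor through a kinase network, and scores the reconstruction
against independent functional data. The pipeline has a fixed logical order
— preprocess, extract, synthesize, compare, validate, randomize — and each
stage is an exported function, so any stage can be run on real data in the
documented file formats or on synthetic data with planted ground truth.

## Significance scoring and discretization

The measured quantity is a replicate-by-time matrix of phosphorylation fold
changes per protein, normalized so that every replicate equals exactly 1 at
time 0. For each later time point two paired Student's t-tests are computed:
against the baseline column ("firstscores") and against the preceding column
("prevscores"); the statistic is `mean(d) / (sd(d)/sqrt(n))` on `n - 1`
degrees of freedom with the sample standard deviation. Two degenerate cases
have fixed, flagged conventions: all differences zero gives p = 1 (no
evidence of change), and zero spread around a nonzero mean gives p = 0 (the
limit of the statistic). A time point is called significant when either
score is at or below the threshold (default 0.05, inclusive — the threshold
is the largest p still considered significant). The state at a significant
time point is `activated` or `inhibited` according to whether the mean fold
change lies above or below the reference point's mean, taking the baseline
as reference when the firstscore fired (and the previous point otherwise);
time 0 is always `inactive`. No multiple-testing correction is applied, by
design: each protein's profile is read as a standalone time course, which
means roughly 5% of null tests fire, a property the synthetic study design
takes seriously (see below).

Protein prizes are `max(0, -log10(min p))`, minimized over both score types
and all time points, capped at 10 (the value assigned when some p-value is
exactly 0, as happens in noiseless data). The formula is monotone in
evidence — lowering any p-value can only raise the prize — which is the only
property downstream extraction relies on.

## Prize-collecting subnetwork extraction

The background interactome has an undirected protein–protein layer with
confidence weights in (0, 1] and a directed, optionally signed
kinase–substrate layer. For extraction both layers are projected to an
undirected graph with edge cost `1 - confidence`. The objective is the
standard prize-collecting Steiner formulation: minimize the `edge_reliability`
(β)-weighted sum of excluded prizes plus the summed cost of included edges;
with the default degree penalty g = 0 there is no degree term, and with one
source and a single tree the dummy edge (weight ω = 10) offsets every
candidate equally, so it never changes the optimum. Defaults (ω = 10,
β = 10, g = 0, 100 randomized-prize runs) follow the common parameterization
of public PCSF pipelines for this data type.

The solver is a documented heuristic, not an exact or message-passing
implementation: terminals are selected greedily by `β·prize − cheapest path
cost`, the selection is improved by single-terminal exchanges scored on the
shortest-path metric closure, and the selected terminals are realized as a
closure minimum spanning tree expanded back to graph edges with the classic
Steiner refinement (MST of the induced subgraph, non-terminal leaves
pruned). Each of the 100 runs jitters prizes multiplicatively by a uniform
±10% (`noise_scale`); edges kept are those appearing in at least half the
runs (`inclusion_frequency = 0.5`), pruned to the source-connected
component. On instances of up to 12 nodes an exhaustive solver
(`pcsf_exhaustive`) provides the exact optimum for testing; the test suite
holds the heuristic within 5% of it.

## Temporal pathway synthesis

This is the package's core. Every undirected subnetwork edge {u, v} yields
up to four signed directed candidates, restricted by the partial model: a
prior `u -> v` without the reverse forbids the `v -> u` orientation, and a
signed prior forbids the opposite sign for that direction. A simple path
from the source is *valid* when

1. the first-change times of its measured nodes are non-decreasing along
   the path,
2. its terminal node is measured and changes, and
3. at every measured node the cumulative product of edge signs from the
   source equals the direction of that node's first observed change.

Unmeasured intermediates impose no timing constraint but contribute their
edge sign to the product. Two boundary semantics are fixed here because the
constraint system itself leaves them open: measured nodes that never change
cannot lie on a valid path (they have no change direction for rule 3 to
check), and unmeasured nodes cannot terminate paths (a path must end in an
explained observation). A node whose only significant evidence is a
prevscore still gets its first change at the earliest time either score
fires.

The summary network is the union of all valid paths of at most
`max_path_len` edges (default 8 — a bound on enumeration depth, documented
as a fidelity limit; signaling cascades of interest are shorter). Every
used edge is emitted with its direction; it carries a sign only when all
valid paths through that node pair agree on a single (direction, sign)
pair. When both orientations occur, both directed edges are emitted,
unsigned. Consolidation is a union and therefore order-independent; output
files sort edges lexicographically for byte-stable reproduction. The
enumeration is a depth-first search with incremental pruning of the three
rules; `brute_force_summary` independently recomputes the result on
instances of up to 12 nodes by enumerating every simple path and every sign
assignment and filtering with `is_valid_path`, and the acceptance suite
checks exact agreement on 100 random instances.

Activity windows report, per node and time point, the admissible states:
measured nodes take exactly their discretized profile, the source is
activated at time 0, and an unmeasured node is admissible as activated
(inhibited) from the first-change time of the nearest measured node
upstream of it on any valid path with positive (negative) cumulative sign —
`inactive` is always admissible for unmeasured nodes, since the summary
never forces a relay to be used. Nodes on no valid path are unconstrained.

## Comparison and validation

Kinase–kinase subnetworks keep directed edges with both endpoints in the
kinase set. Overlap percentages are deliberately asymmetric, matching how
such comparisons are reported: node overlap relative to the *functional*
model's kinases, edge overlap relative to the *phospho*-derived network's
edges; empty denominators give NA, never 0.

The network validation arm computes, per compound, the cumulative
inhibition `Σ (100 − residual activity)` over network kinases present in
the biochemical matrix (kinases absent are skipped; no clamping by default,
so residuals above 100 subtract — `clamp_negative` provides the documented
alternative). The perturbation cutoff is
`network_fraction × n × inhibition_threshold` (default 0.25 · n · 50 =
12.5 points per network kinase) and the call is strict (`>`). Measured
perturbation uses a two-sample Student's t-test (equal variances, unpaired
— screen replicates are not paired across conditions) at p < 0.05, or
unanimity: every replicate beyond ±10% AUC change relative to the mean DMSO
control, in a consistent direction. The functional arm calls a kinase
active at time t when any of its pathway activity intervals intersects the
closed window [t − 5, t + 5] minutes, and compares against the phospho
call (p < 0.05 against the no-change value, or all replicates at or beyond
±20% fold change — bounds inclusive). Both arms report accuracy as
precision over positive predictions, with the full confusion counts
attached; instances the model does not predict are abstentions.

## Randomization nulls

The network-arm null shuffles node labels of the subnetwork and the partial
model (uniform permutations over each network's own node set — a pure
relabeling that preserves the degree structure exactly), shuffles the
fold-change values globally across all proteins and time points, shuffles
the two score sets the same way independently of the data, and re-runs the
synthesis and validation with the source designation unchanged. Global value
shuffling is the most destructive and hence most conservative choice for the
ambiguous instruction "shuffle the values"; a per-protein variant is
available. The functional-arm null replaces the background with a directed
configuration-model draw (exact in/out degree sequences pre-collapse;
self-loops and duplicate edges then removed, the documented convention, with
the pre-collapse multigraph retained for auditing), shuffles kinase labels,
re-samples weakening/strengthening kinases per time point with the true
model's per-time probabilities from the kinase pool (300 in the real-data
configuration), assigns selected kinases uniformly to one of 36 clusters,
and rebuilds per-cluster networks from all shortest paths between
same-cluster kinases (all tied shortest paths are kept — tie-breaking would
make the null depend on traversal order; unreachable pairs are counted and
skipped). Each ensemble runs 100 iterations by default; iterations whose
networks predict nothing are recorded as undefined, never silently dropped.
The summary reports mean, spread, percentiles and the empirical p-value
(fraction of defined null accuracies at or above the true one).

# The synthetic study design

The generator plants a complete ground truth so that every claim the tests
make is checkable: a signed cascade rooted at the receptor node `SRC`, the
activation time of every cascade member, the barrier kinases coupled to the
permeability phenotype, and the compound classes of the inhibitor panel.
Defaults mirror the real study conditions this pipeline addresses: 28
measured proteins on the nine-point grid 0–360 minutes, 3 biological
replicates, 29 screened compounds, lognormal replicate noise with CV 0.1 (a
typical densitometry replicate CV), sustained step responses
(`activation_amplitude` 2.5, `inhibition_amplitude` 0.4) — a step rather
than a pulse makes "first significant change" unambiguous for recovery
tests, and fold changes are ratio data, hence multiplicative, strictly
positive noise with mean exactly 1 (no drift, so bystanders stay centered
on 1 at any replicate count).

Several structural choices make the planted signal *identifiable*, and they
are choices about the simulated biology, stated here so their consequences
are clear:

* **A curated backbone.** The interactome carries a high-confidence
  (≥ 0.995) tree of `cascade_size` nodes rooted at the receptor; all other
  edges have confidence at most 0.9, and peripheral nodes attach to the
  backbone through single mid-confidence (0.85–0.9) edges. Canonical
  pathway edges being the best-curated part of interaction databases is
  realistic; the quantitative effect is that any backbone path is cheaper
  than any single non-backbone edge, so prize-based extraction provably
  keeps every cascade edge at zero noise, for every seed — noiseless
  recovery (recall 1.0, no sign errors) is structural, not statistical.
* **Fast receptor-proximal kinetics.** Every cascade member activates by
  the first post-stimulation sample (5 minutes). Thrombin-receptor
  signaling is fast, and the uncorrected per-test α = 0.05 makes slow
  cascades fragile in an instructive way: a protein activating at 360
  minutes offers fourteen pre-activation tests, so about half such proteins
  acquire a false earlier "first change" that severs their subtree from the
  valid paths. With no pre-activation samples that failure mode cannot
  occur. The temporal-ordering machinery is exercised instead by the
  randomized-profile instances of the unit and acceptance tests.
* **A kinase-rich panel with informative bystanders.** The measured set is
  the 11 cascade proteins plus 8 unresponsive bystander kinases and 9
  unresponsive effector proteins. Bystander kinases carry signed
  kinase-substrate priors pointing *into* the backbone (upstream
  regulators), so the partial model forbids valid paths from terminating at
  them: the true summary's kinase set is exactly the recovered cascade
  kinases. Under the label-shuffling null, those same bystander labels land
  freely, which is what lets random networks be told apart.
* **Inhibitor polypharmacology.** Compounds cycle through three classes
  (10 barrier-targeted, 10 off-target, 9 inactive). Barrier-targeted
  compounds inhibit each barrier kinase with probability 0.75 at 70–95%
  inhibition; each inhibited barrier kinase (at ≥ 50%) shifts the expected
  permeability AUC by `barrier_effect` = 5%, the cumulative-inhibition
  logic mirrored into the phenotype. Off-target compounds strongly inhibit
  kinases outside the measured panel and carry sub-threshold liabilities —
  two ~39% and one ~14.5% hits on barrier kinases, and ~27% hits with
  probability 0.5 on bystander kinases — all strictly below the 50%
  coupling threshold, so they never move the phenotype. Their liabilities
  are calibrated to exceed the 12.5-points-per-kinase cutoff of small or
  mislabeled random networks while summing below the cutoff of the full
  true network, which is what gives the randomization ensembles a
  recoverable separation signal at every network size.

What the generator does **not** emulate: mechanistic (ODE) kinetics,
western-blot imaging artifacts, missing bands, transient (pulse) responses
unless requested, feedback loops (the truth is acyclic), or compound
effects on the phenotype other than through the planted barrier kinases.
Consequently, passing tests demonstrate that the pipeline's inference and
bookkeeping are correct and that its validation logic separates signal from
randomized controls under realistic noise — not that the biological model
is identifiable on any real dataset, where responses are slower, noise is
structured, and the interactome's confidence calibration is far rougher.

# Numerical choices and problem sizes

All seeds flow from one configuration seed through fixed offsets (stage
seeds are `seed · 100 + stage index`), so identical configurations produce
byte-identical outputs. Ties in the extraction heuristic break by sorted
node order; summary edges sort lexicographically. The test suite runs the
synthesis oracle on instances of 5–12 nodes, the extraction oracle on 6–9
node instances, 100-iteration null ensembles once at the default study
size, and 50-seed recovery batches at noise CV 0.2; the acceptance script
repeats these at 100 oracle instances, 50 noisy seeds and both
100-iteration ensembles. These sizes were chosen as the smallest at which
the statistical claims stabilize.

# Known limitations

* The PCSF heuristic matches the exhaustive optimum on small instances but
  carries no approximation guarantee beyond the classic Steiner bound; very
  flat prize landscapes can make the inclusion-frequency filter
  conservative.
* Path enumeration is exponential in the worst case; `max_path_len` bounds
  it, at the cost of missing deeper explanations in dense subnetworks.
* Sign resolution is intrinsically sparse: with few measured nodes most
  edges admit both sign assignments somewhere, and the summary honestly
  reports them unsigned (the suite verifies the signed fraction shrinks as
  coverage shrinks).
* Accuracy-as-precision ignores abstentions and misses; the full confusion
  counts are emitted for any analysis that needs them.
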