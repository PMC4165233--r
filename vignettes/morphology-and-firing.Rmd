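---
title: "How basal dendritic morphology shapes the firing pattern of a model pyramidal cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How basal dendritic morphology shapes the firing pattern of a model pyramidal cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Layer V pyramidal neurons respond to a sustained somatic current step in
one of two characteristic ways: *regular spiking* (RS), a train of evenly
spaced single action potentials, or *intrinsic bursting* (IB), an initial
cluster of closely spaced spikes.  The same conductance repertoire can
produce either pattern, which raises the question this package is built
around: **how much of the RS/IB decision is carried by dendritic
morphology alone?**  dendrofire lets you hold the channel complement and
the stimulus protocol fixed, swap dendritic trees in and out of a
reference cell, and measure how the firing pattern follows the tree.

```{r setup}
library(dendrofire)
```

## Morphologies and surgery

Morphologies are standard 7-column SWC point trees (`read_swc()`,
`write_swc()`, `as_morphology()`), partitioned into unbranched *sections*.
Two surgical operations make controlled experiments possible:

* `graft(soma_donor, basal_donor, apical_donor)` builds a chimeric cell
  from a fixed soma, one cell's basal trees and another's apical tree.
  Donor subtrees are only translated, never scaled or rotated, so every
  donor morphometric is conserved exactly.
* `split_section(m, section_id, fraction)` inserts a section boundary
  without changing geometry; total length, volume and electrotonic path
  length are invariant.

Per-tree morphometrics follow the section decomposition: total length,
cylinder volume, median section diameter, branch number (for a binary
tree with $T$ tips, $2T-1$), and the **mean electrotonic path length**
(MEP).  Each section of radius $b$ contributes a dimensionless length
$\Lambda = l/\lambda$ with $\lambda = \sqrt{b\,r_m/(2 r_a)}$, and MEP is
the mean of the tip-to-root sums over all terminals.  MEP deliberately
uses fixed constants ($r_m$ = 30 kΩ·cm², $r_a$ = 210 Ω·cm): it is a
morphological summary, not a simulation readout.  A radius-1-µm cable of
one length constant (≈845 µm) therefore has MEP exactly 1, which the
`fixture_suite()$stick` fixture encodes as a built-in oracle.

One diameter convention matters for reproducibility: a section's
attachment point (the fork or soma point it departs from) belongs to the
*parent* branch, so the attachment segment always contributes at the
child-side radius.  With this rule, volume and MEP of trees whose radius
is constant within each branch are exactly invariant under
`split_section()`.

## The cell model

`build_cell_spec()` binds a morphology to a passive profile and a channel
configuration; `discretize()` cuts it into compartments (≤ 20 µm by
default) with exact frustum areas and axial resistances.

Passive membrane: $R_a$ = 210 Ω·cm, $C_m$ = 1.2 µF/cm², rest −66 mV.
$R_m$ is 30 kΩ·cm² in soma and axon and falls sigmoidally with path
distance $x$ toward half that value in the dendrites:
$R_m^{basal}(x) = 30 - 15/(1+e^{(10-x)/5})$ and
$R_m^{apical}(x) = 30 - 15/(1+e^{(300-x)/50})$ (kΩ·cm²).  The membrane
time constant at the soma is $R_m C_m$ = 36 ms.

Active membrane: twelve Hodgkin–Huxley-style currents (fast and
persistent Na⁺; delayed-rectifier, A-type and slowly inactivating K⁺;
fast and slow Ca²⁺-activated K⁺; h-current; and T-, N-, R- and L-type
Ca²⁺ currents) with a single-pool Ca²⁺ dynamics per compartment.  The
shipped kinetics and densities are this package's own defaults.  They
satisfy the qualitative ordering constraints of the model class —
Na⁺ densest in the axon, K⁺ currents weaker apically than somatically,
AHP currents somatic, apical h-current rising sigmoidally to ten times
the somatic density — and are checked by `validate_channel_config()`.

The burst generator is deliberately dendritic.  R-type Ca²⁺ conductance
in the basal membrane supports a local Ca²⁺ electrogenesis that re-excites
the soma a few milliseconds after the first spike.  Whether that reply
arrives as a burst doublet depends on the basal load: a small, thin basal
tree focuses the depolarization and bursts; a large tree dilutes it and
the cell relaxes into regular spiking.  This is the mechanistic reading
of the morphology–firing link the package is designed to expose, and it
is robust across the stimulus amplitudes the normalization produces.

Integration is backward Euler with a tree-ordered direct solve (Hines
ordering) and exact exponential gate updates, implemented in C++.  We
chose pure backward Euler over a Crank–Nicolson hybrid: it is
unconditionally stable, damps rather than rings on spike upstrokes at
dt = 0.025 ms, and makes every trace bit-reproducible.  A 200 ms settle
period precedes every protocol.

## The measurement protocol

`firing_response()` runs the full protocol on one cell:

1. measure somatic input resistance with a −0.1 nA, 500 ms pulse;
2. scale the reference 0.35 nA step by the *control* cell's input
   resistance, $I = 0.35\,R_{in}^{ctrl}/R_{in}^{cell}$, so every cell
   receives the same expected steady depolarization ("equal-dv");
3. apply the 600 ms step, detect spikes as interpolated upward 0 mV
   crossings (2 ms refractory), and classify: IB if the first interspike
   interval is < 20 ms, RS if ≥ 20 ms, Q (quiescent) below two spikes.

The control cell is the graft of the mid-sized `basal_control` fixture
with the `apical_simple` fixture (input resistance ≈ 130 MΩ).  Anchoring
the normalization to one fixed cell is what makes categories comparable
across morphologies.

```{r, eval = FALSE}
fx <- fixture_suite()
control <- graft(fx$soma_only, fx$basal_control, fx$apical_simple)
rin_ctrl <- measure_input_resistance(discretize(build_cell_spec(control)))

cell <- graft(fx$soma_only, fx$basal3, fx$apical_complex)
firing_response(cell, rin_control = rin_ctrl)
```

The cleanest demonstration of the headline direction is
`basal_load_ladder()`: five cells differing only in the number of
identical 250 µm basal stems.  First interspike intervals rise
monotonically with basal load and cross the RS/IB boundary at the top
rung.

## Population analysis

`run_grid()` crosses every basal donor with every apical donor on the
standard soma and returns a tidy `grid_result`; per-cell failures are
recorded, never fatal.  Downstream:

* `basal_profile()` — majority vote across a basal tree's row: RS if
  strictly more than half its combinations fired RS.
* `mann_whitney()` — two-sided rank-sum comparison of a feature across
  profiles (exact null for small tie-free samples, normal approximation
  with tie correction otherwise), wrapping `stats::wilcox.test()`.
* `bayes_evaluate()` — the balanced classifier loop: downsample the
  larger class, split 80/20, fit one-dimensional Gaussian
  class-conditional densities on training data only, score
  sensitivity/specificity/accuracy on held-out cells, repeat 10 times
  with recorded seeds.  Positive class is IB; exact posterior ties go to
  IB (documented constants).
* `feature_correlation()` — pairwise Pearson correlations of the size
  features.

`run_pipeline(run_config(...))` chains everything — generate a two-class
synthetic population, featurize, simulate the grid, profile, test,
classify — and writes `features.tsv`, `grid.tsv`, `labels.tsv`,
`report.json` and a checksummed manifest.  Artifacts contain no
timestamps: one config + seed reproduces every file byte-for-byte.

## Synthetic populations

Because real reconstructions cannot be bundled, `generate_tree()` grows
binary trees from a `tree_recipe` (stems, bifurcation probability,
segment lengths, stem diameter, taper), deterministically per seed.
`population_recipe()` defines the two study classes: an RS-like class of
longer, bushier, slightly thicker basal trees and an IB-like class of
shorter, sparser, thinner ones (median total length roughly 1.7 mm vs
1.1 mm).  Realized class medians preserve the recipe ordering for total
length, branch number and diameter, so ground-truth recovery is testable
end to end.

## Numerical choices and limitations

* Backward Euler is first-order in time; at dt = 0.025 ms the RS/IB
  classification and first-ISI values are converged for this model, but
  individual spike times shift by fractions of a millisecond versus finer
  steps.
* The soma is a single isopotential compartment whose area equals the
  reconstructed somatic surface; somatic voltage gradients are ignored.
* MEP uses fixed electrotonic constants even though the simulated
  membrane resistance is position-dependent; it is a morphology metric by
  design.
* The balanced classifier needs at least two cells per class after
  balancing; with the small populations used in examples this is a real
  constraint, and degenerate splits are reported (not silently patched)
  in `report.json`.
* All statistics are one-dimensional by design; joint multi-feature
  classification is out of scope.
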