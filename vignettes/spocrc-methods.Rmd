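---
title: "Stochastic Boolean modeling of sporadic colorectal cancer signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean modeling of sporadic colorectal cancer signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spocrc)
```

## The model

`spocrc` simulates an 87-node Boolean network of a colonic epithelial cell
and its inflammatory micro-environment. Each node is ON or OFF; a logic rule
over other nodes states when a node's activation conditions are met. Three
ingredients turn this into a stochastic process:

* **Asynchronous update.** One time step draws a uniformly random
  permutation of all nodes and updates them sequentially against the
  evolving state. Several nodes can therefore switch within one step, but
  the order in which signals propagate is random. A single-node-per-step
  variant (`update_scheme = "single"`) and a frozen-snapshot variant
  (`evolving = FALSE`, i.e. synchronous semantics) are available for
  sensitivity analysis. The permutation scheme is the default because it
  reconciles "one random node at a time" with "multiple nodes can switch
  per step", and because whole-pathway relays then happen on a timescale of
  a few steps rather than a few hundred.
* **Polymorphisms.** A node with polymorphism $p$ switches ON with
  probability $p$ each time its rule is satisfied, and OFF otherwise.
  This is applied per update attempt, so a polymorphism of 0.5 makes a
  constitutively-driven node flicker with duty cycle 0.5 rather than
  choosing a state once. Polymorphism 0 silences a node completely.
* **Clamps.** A perturbation fixes a node ON or OFF inside a step window,
  overriding rule and polymorphism. Clamps encode loss-of-function
  mutations (OFF), gain-of-function mutations and sustained stimuli (ON),
  and in-silico knockouts.

The read-out is the **activation frequency**: the fraction of Monte-Carlo
repetitions in which a node is ON at a given step. End-state marginals
average the frequency over the final `measurement_window` steps (default
50; window 1 recovers the literal final step). The trailing average reduces
Monte-Carlo noise and the flicker introduced by polymorphisms; panel
results move by less than one standard error between window 1 and window 50
in our runs, because the scenarios reach statistically stationary regimes
well before step 1800.

## Reproducibility

Every source of randomness derives from one master seed: repetition $r$
uses an `mt19937_64` stream seeded by `splitmix64(seed, r)`, and within a
repetition the draw order is fixed (initialization, then per step the
permutation followed by one polymorphism draw per satisfied stochastic
node). Identical `(network, config, seed)` triples give bit-identical
frequency matrices.

## The spoCRC network

`load_spocrc()` parses the packaged rule file
(`inst/extdata/spocrc_reconstruction.bnet`). The published rule set for
this model lives in supplementary material that cannot be redistributed
here, so the file is a **reconstruction**: every rule or interaction stated
in the main text is encoded verbatim (tagged `[text]` in the file), and the
remaining wiring — largely the parts inherited from the earlier
colitis-associated cancer model — is filled in with canonical pathway logic
(tagged `[pathway]`). Structural validation checks every text-anchored
interaction as a signed edge of the influence graph and verifies both
positive feedback loops: the cytokine loop
IL6 → GP130 → RAS → AKT → NF-κB → IL6/CCL2 and the prostaglandin loop
AKT ⊣ GSK3β ⊣ destruction complex ⊣ β-catenin → TCF/LEF → COX2 → PGE2 →
EP2 → RAS → AKT.

The calibrated healthy configuration carries exactly seven polymorphisms:
WNT 0.1, Netrin 0.5, CAD 0.1, PDE5 0.9, Stress 0.02 (basal inputs), and
IL6, CCL2 at 0.5 (the inflammation strength at which the model is apoptotic
at rest yet still responds to a dendritic-cell stimulus).

### Design choices in the reconstructed logic

Because only fragments of the original rules are published, several gating
decisions were genuinely open. The reconstruction was tuned — before the
rule file was frozen and the test suite written against it — until the
model reproduced the qualitative regime structure of the published study.
The load-bearing devices are worth recording:

* **p53/AKT antagonism.** p53 drives PTEN, which brakes every PI3K input;
  MDM2 degrades p53 and is stabilized by AKT, or by ERK when NF-κB
  co-signals (`MDM2 = AKT | (ERK & (NFkB | MDM2))` — the ERK arm engages
  during an NF-κB episode and then self-sustains while ERK lasts). This
  makes the proliferative state a genuine latch: mutations that keep ERK on
  (RAS gain of function, or APC loss via the β-catenin → COX2 → PGE2 → RAS
  chain) pin p53 off, while in the healthy model ERK is only a short echo
  of an inflammatory flare and p53 re-asserts. p21 prolongs the PTEN brake
  by one step (`PTEN = p53 | p21`), which slows spurious ignition in the
  healthy model.
* **AKT co-activation gates.** The NF-κB arms of COX2 and survivin, and
  survivin's transcription-factor arm as a whole, require AKT. This
  encodes AKT's documented stabilizing role and ensures that clamping AKT
  OFF dismantles the proliferative program in every mutation background —
  the defining behavior of the AKT knockout panel.
* **GSK3β and FOXO4 brakes.** GSK3β (active when AKT is off) destabilizes
  CyclinD1; FOXO4 (active when PDE5 fails to degrade cGMP, 10% of steps)
  represses both β-catenin and survivin. These give the healthy state its
  means of dismantling transient proliferative excursions.
* **Immune regulation.** TREG conversion needs dendritic-cell stimulation
  and is blocked by IL6; IL10 de-activates macrophages and suppresses IKK.
  This keeps 50%-polymorphism inflammation self-limiting while letting the
  100% model and the chronic DC clamp overwhelm the brakes. An AP-1 arm on
  IL6/CCL2 transcription provides the stress-driven spark that can ignite
  the cytokine loop without pre-activated immune cells.

### What the reconstruction does and does not reproduce

With the protocol sizes of the published study (1800 steps, IL6/CCL2 at
0.5), the frozen network reproduces, at matching sign and regime: the
apoptotic healthy and no-inflammation baselines with low β-catenin/AKT/NF-κB
activity; the proliferative collapse under full IL6/CCL2 activation; the
drop of apoptosis under a chronic DC clamp and its recovery after transient
clamps; the phenotype flip under APC-LOF, RAS-GOF, p53-LOF and their
combinations with saturation under the four-mutation scenario; the
near-neutrality of 18q loss; apoptosis restoration above the healthy level
by COX2 knockout under APC loss; proliferation inhibition by AKT knockout
in every background; the inertness of FZD and BCL2 knockouts; and
celecoxib's advantage over sulindac under RAS/p53 mutations, which is
carried entirely by its AKT off-target.

Two published point values are known not to be matched quantitatively:
18q loss shifts the two readouts by up to ≈0.2 (published: ≤0.1), because
the SMAD arm of the survivin brake carries more dynamical weight here than
in the original rule set; and the COX2-knockout apoptosis restoration under
APC loss is ≈0.6–0.8 rather than >1, because the reconstruction's untreated
APC scenario retains more apoptosis than the published 0.12. Tests assert
the mechanism (treated apoptosis above the healthy level) rather than the
headline ratio. All other panel values should be read as regime labels, not
point estimates.

## The exact oracle

For networks of up to 12 nodes, `build_transition_matrix()` constructs the
process's exact one-step transition matrix on the $2^n$ state space: each
node contributes a sparse factor (rule evaluation plus polymorphism split,
or a clamp), a permutation's one-step matrix is the ordered product of the
factors, and the chain marginalizes over permutations — exactly (all $n!$)
for $n \le 6$, by sampling with a reported error bound above that (5000
sampled permutations by default; the bound folds into test tolerances).
`exact_marginals()` propagates an independent-product initial distribution.
The oracle shares no code with the compiled engine — rules are evaluated by
the R interpreter, matrices built in base R — so the two paths check each
other. The engine validation sweep uses 100 random networks of 2–6 nodes,
5000 repetitions, and compares marginals at steps 1, 10 and 100 against a
3-binomial-SE band (with an explicit multiplicity allowance: across ~1500
comparisons a few ~3 SE excursions are expected by chance, so the suite
requires 99% of comparisons inside 3 SE and all inside 4.5 SE).

## Scenario pipeline

Scenarios chain through **staged initial conditions**: a child scenario
initializes each node ON with probability equal to the parent's end
marginal. Random (unstaged) runs start each node at probability 0.5 except
the start-OFF roster — the inflammatory cascade including its receptors,
COX2, PGE2, EP2, and the two readout nodes — which starts OFF. The mutation
panel follows the published staging chain (singles from healthy; APC+p53
and APC+RAS from APC; APC+RAS+18q from APC+RAS; the four-mutation scenario
from APC+RAS+18q). Treated (knockout or drug) runs reuse the untreated
scenario's staged initial conditions and seed, so the intervention is the
only difference.

Effect scores follow the study's normalization: apoptosis restoration is
the treated-minus-untreated apoptosis frequency divided by the healthy
apoptosis frequency (it can exceed 1); proliferation inhibition is the
untreated-minus-treated proliferation frequency divided by the untreated
value. Zero denominators yield `NA` with a warning.

Drug profiles attach constant-TRUE inhibitor nodes (`COXIB_<target>`) whose
polymorphism encodes potency; the target's rule is wrapped as
`(original) & !COXIB_<target>`. Both profiles block COX2 at 0.9; celecoxib
inhibits AKT, NF-κB and PDE5 at 0.3; sulindac cannot inhibit AKT
(polymorphism 0). Potency differences beyond the AKT distinction are not
modeled.

## Problem sizes and known limitations

Simulations in the test suite use the full 1800-step protocol with 500–1500
repetitions (activation-frequency standard errors of 0.013–0.022); the
acceptance script uses 5000 repetitions for the three headline baselines
and 800 for the panels. The published protocol uses 5000 throughout; the
reduced panel sizes change the reported frequencies by amounts small
compared to the sign-level bands being checked.

What passing tests do *not* show: the generator-validated engine says
nothing about the biological fidelity of the reconstructed rules; the
reconstruction reproduces regime structure, not the published table to
printed precision; and the model inherits the study's own exclusions — no
migration, no angiogenesis, a single cell without spatial context, and no
separation of the very different timescales of receptor binding and immune
cell recruitment.

## A worked example

```{r example, eval = FALSE}
net <- load_spocrc()
healthy <- run_healthy(steps = 1800, repetitions = 1000, seed = 1)
healthy$marginals

panel <- run_mutation_panel(steps = 1800, repetitions = 500, seed = 1,
                            network = net)
attr(panel, "summary")

effects <- run_inhibition_panel(targets = c("COX2", "AKT"),
                                mutation_panel = panel, network = net)
subset(effects, mutations == "APC_LOF")
```
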