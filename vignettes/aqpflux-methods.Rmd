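---
title: "Models and methods behind aqpflux"
author: "aqpflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aqpflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpflux)
```

aqpflux analyses the functional diversification of aquaglyceroporin
(Aqp10) paralogs from three directions at once: channel function measured
in *Xenopus* oocytes, solute selectivity predicted from the
aromatic/arginine (ar/R) constriction of the pore, and the selective
regime and timing of the underlying gene duplications.  This vignette
explains the models, their assumptions, the tunable parameters, and the
choices made where the design was genuinely open.

## 1. Permeability from swelling kinetics

### The estimators

An oocyte of initial volume $V_0$ (cm³) and surface area $S$ (cm²) is
transferred into a bath with an osmotic or solute gradient and filmed;
the observable is the relative volume $V/V_0$ over time.  The package
implements the two standard initial-rate estimators

$$P_\mathrm{water} = \frac{V_0 \, \mathrm{d}(V/V_0)/\mathrm{d}t}
                          {S\, V_w\, (\mathrm{osm_{in}} - \mathrm{osm_{out}})},
\qquad
P_\mathrm{solute} = \mathrm{osm_{tot}}\,
                    \frac{V_0\, \mathrm{d}(V/V_0)/\mathrm{d}t}
                         {S\, (\mathrm{sol_{out}} - \mathrm{sol_{in}})},$$

with $V_w = 18$ cm³/mol the molar volume of water.  Internally everything
is in cm, s and mol/cm³; the constructors accept bench units under the
dilute-solution identification 1 mOsmol/kg ≈ 1 mM ≈ $10^{-6}$ mol/cm³
(1 kg of solvent ≈ 1 L of solution).  Geometry comes from an assumed
sphere: $V_0 = \pi d^3/6$, $S = \pi d^2$, so $V_0/S = d/6$.  $S$ is held
at its initial value during estimation; the simulator can optionally grow
it spherically to quantify the resulting model-mismatch bias.

### The slope, its window, and why the defaults look the way they do

The derivative is estimated by an ordinary least-squares fit of $V/V_0$
against time over a window starting at $t = 0$.  The default window is
**the first 60 s or the first 20 % of the trace, whichever is shorter**
(`defaultFitWindow()`), and it is always configurable.  The window trades
two errors against each other:

* *Dilution nonlinearity.*  As water enters, the internal osmolyte pool
  dilutes and the driving gradient decays at a relative rate of about
  $c_\mathrm{in}\,(S/V_0)\,P_w V_w / g$ per second, so an OLS slope over
  a window $w$ underestimates the initial rate by roughly half that rate
  times $w$.  At the largest water permeability the package is designed
  for ($2\times10^{-2}$ cm/s, a strongly expressing oocyte) this bias is
  ≈ 0.18 %/s, i.e. ≈ 4 % over the default 24 s window of a 120 s trace.
* *Measurement noise.*  i.i.d. noise of sd $\sigma$ per sample gives a
  slope standard error of $\sigma/\sqrt{n_\mathrm{pts} w^2/12}$; short
  windows amplify it.

A 120 s water trace sampled at 100 Hz (the simulator default; modern
camera recordings are comfortably in this range) keeps both terms below
5 % across $P_\mathrm{water} \in [10^{-3}, 2\times10^{-2}]$ cm/s.
Solute traces default to 600 s (fit window 60 s) because solute fluxes
are 10³-fold smaller.  The estimator-recovery tests and the acceptance
script run exactly these sizes.

### The forward model, and a timescale warning about the solute formula

`simulateSwelling()` integrates, with a classical fixed-step RK4 scheme,

$$\frac{\mathrm{d}V}{\mathrm{d}t} = P_w S V_w
   \left(\frac{n_\mathrm{osm}}{V} - \mathrm{osm_{out}}\right), \qquad
  \frac{\mathrm{d}n_\mathrm{sol}}{\mathrm{d}t} = P_s S
   \left(\mathrm{sol_{out}} - \frac{n_\mathrm{sol}}{V}\right),$$

where $n_\mathrm{osm}$ counts impermeant internal osmolytes plus absorbed
solute.  Halving the default step (0.01 s) changes the final volume by
less than $10^{-6}$, which the suite asserts.

The published $P_\mathrm{solute}$ formula presumes that water equilibrates
much faster than the solute enters, so that volume is slaved to solute
content ($\mathrm{osm_{tot}}\,\mathrm{d}V/\mathrm{d}t =
\mathrm{d}n_\mathrm{sol}/\mathrm{d}t$).  With a *finite* realistic
$P_w \sim 10^{-2}$ cm/s that limit is approached with time constant
$\tau = (V/S)/(P_w V_w\, \mathrm{osm}) \approx 4$–$5$ min for a 1.2 mm
oocyte — not fast at all relative to an initial-rate window.  The
simulator therefore supports `truePWater = Inf`, the water-equilibrated
limit, and uses it as the **solute-mode default**: it is exactly the
regime the estimator is derived for, so estimator validation is not
confounded by a bias the estimator cannot see.  Passing a finite
`truePWater` quantifies that water-limitation bias explicitly, which is
the honest way to explore it.

### Group statistics

`compareGroups()` runs one-way ANOVA across constructs and then either
Holm–Šidák (step-down Šidák on pooled-variance *t* statistics, each
construct vs the control), Dunnett (via **multcomp**), or Tukey HSD (all
pairs).  Significance tiers mirror the usual figure legends
(0.05, 0.01, 0.001, 0.0001).  Constant data are flagged rather than fed
to a degenerate F test, and adjusted p-values are never smaller than the
raw ones (asserted property).

## 2. The ar/R selectivity filter

The four constriction residues are located by mapping 1-based positions
in the *ungapped* reference sequence to alignment columns
(`mapFilterColumns()`), so the spec of a filter travels with one
well-annotated sequence rather than with a particular alignment.  The
shipped default anchor is AanAqp10.2b1 with position 3 at residue 205
(the residue whose Y→G substitution switches selectivity); positions 1, 2
and 4 default to 63, 201 and 211 — recorded in `filterSpecDefault()` and
in every fixture manifest rather than hard-coded, because only position 3
is fixed by the mutant nomenclature.  Override them when annotating real
alignments against a structural model.

The classification rule is deliberately minimal: **narrow** (water +
glycerol only) iff positions 1 *and* 3 are aromatic (F, Y, W), else
**broad**.  Histidine is excluded from the aromatic set — it does not
occur in Aqp10 filters, and the contrast that matters is bulky aromatic
vs small (A/G/S).  The call provably depends only on positions 1 and 3;
a property test permutes positions 2 and 4 to confirm.  Gaps at filter
columns yield an explicit warning and an unclassifiable (NA) call.

## 3. Nei–Gojobori dN/dS

`ng86Pair()` implements the NG86 counting scheme with its standard
conventions:

* *Sites.*  At each codon position the synonymous fraction is the number
  of synonymous single-nucleotide changes divided by the number of
  *valid* changes, where changes creating a stop codon are excluded from
  the denominator.  Each position contributes one site, so $S + N = 3
  \times$ (codons compared); per-pair sites are averaged between the two
  sequences.
* *Differences.*  Codons differing at $k$ positions are averaged over all
  $k!$ mutational pathways, excluding pathways that pass through a stop
  codon.  (If every pathway were blocked — a case that does not arise for
  the standard code, which the oracle test confirms — all pathways would
  be used with stop steps counted as nonsynonymous.)
* *Exclusions.*  Codons containing a stop, gap or ambiguous base in
  either sequence are dropped.
* *Correction.*  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ applied to
  $p_S$ and $p_N$; $p \ge 0.75$ raises a saturation error naming the
  offending pair.

All 61 × 61 codon-pair quantities are precomputed once and checked
exactly against an independent brute-force enumeration in the test suite.
`groupMeanDnDs()` averages the pairwise values over all cross-group pairs
(the MEGA "mean distance between groups"; within-group diversity is *not*
netted off) and attaches bootstrap standard errors from codon-site
resampling (same resampled sites for every sequence; 500 replicates by
default, explicit seed required).  Frame-preserving gap handling is a
separate, testable step: `removeGapCodons()` deletes a codon
column-triplet for all sequences whenever any sequence is gapped in it.

## 4. Trees, likelihoods, ancestors

Distance trees use `ape::nj` behind `njTree()`, with any negative branch
clamped to zero and the deficit moved to its sister branch so path
lengths through the pair are preserved.  Likelihood evaluation
(`treeLogLik()`) is Felsenstein pruning with site-pattern compression,
per-node rescaling, and uniform rates, under JC69, K2P or TN93; rate
matrices are normalized to one expected substitution per site and
exponentiated through the symmetrized eigendecomposition.  TN93
parameters are fitted on a fixed topology by empirical base frequencies
plus Nelder–Mead ML over the two transition/transversion ratios
(relative tolerance $10^{-8}$).

`ancestralStates()` computes *marginal* posteriors: a postorder (down)
pass for within-clade partials and a preorder (up) pass for the rest of
the tree, multiplied and normalized per site.  The most probable base is
reported per site, with ties broken by the fixed order A < C < G < T and
flagged.  Reconstruction of the ancestor of the eel paralogs ("N20" in
the group-contrast fixtures) roots the tree on the outgroup and
reconstructs at the ingroup MRCA; on 522-position simulations the
reconstructed root is ≳ 99 % identical to the truth, which is why
group-vs-ancestor dN/dS works at all.  Only the most-probable-sequence
mode feeds downstream distances; posterior-weighted distances were
considered and rejected for the default because the bootstrap SE already
carries the sampling uncertainty and mixing two uncertainty propagation
schemes makes the estimate harder to interpret.

## 5. Clock dating

`dateTree()` is a two-step approximation of relative-rate dating:

1. **Mean-path ultrametricization** — each internal node's relative depth
   is the mean path length to the leaves below it, reconciled so a parent
   is never shallower than a child (already-ultrametric trees are a fixed
   point);
2. **Linear calibration** — all depths are scaled so the MRCA of a named
   tip pair sits exactly at the calibration age (e.g. 175 Mya for the
   Elopiformes/Anguilliformes split).  Scaling is provably linear
   (doubling the calibration age doubles every node age).

This is *not* the full relative-rate framework: there is no per-branch
rate model, no confidence interval, and a single calibration.  Strict
clock simulations at ~1000 codons are recovered with a median absolute
relative age error below 10 %, and against rate-heterogeneous reality the
two dated duplication ages in the synthetic study emulation should be
read with a ±20 % band.  Root placement matters more than it looks:
rooting *at* the outgroup's attachment node distorts every relative
depth, so `rootOnOutgroup()` roots on the outgroup *edge* at the point
where mean root-to-leaf depth is equal on both sides.

## 6. The synthetic study

`makeFixtureSuite()` emulates the statistical structure of the real
study, with all ground truth in a manifest:

* a 10-sequence protein alignment carrying the published filter pattern —
  F,S,A,R (broad Aqp10.1a), F,G,Y,R (narrow Aqp10.2b/2b1), F,G,G,R
  (broad eel 2b2/2b3) — including a private insertion so column mapping
  is exercised across gaps;
* noisy swelling traces (sd 0.005 on $V/V_0$, three oocytes per construct
  and assay) for six constructs plus water-injected controls under the
  hypoosmotic and 180 mM glycerol/urea/boric-acid designs, with
  permeability truths spanning control ($10^{-3}$ cm/s water) to strong
  expression ($1.5\times10^{-2}$);
* a two-group codon alignment (174 codons ≙ 522 positions) evolved on an
  eel-like tree with $\omega = 0.06$ inside the Y-retaining clade and
  $\omega = 0.51$ inside the G clade, plus a conger outgroup;
* a strict-clock alignment (325 codons ≙ ~976 positions) on a dated tree
  with duplication nodes at 16.2 and 3.2 Mya and the calibration split at
  175 Mya, at $1.5\times10^{-3}$ substitutions/site/My — high enough that
  the 3.2 My node is resolvable at this alignment length at all.

The codon simulator is Gillespie-style: candidate mutations arrive as a
Poisson process (branch length = expected candidate mutations per
nucleotide site), transitions $\kappa$-fold more likely than each
transversion, candidates creating stops rejected, nonsynonymous
candidates accepted with probability $\omega$; true event counts per
branch are recorded.  Rejection of stops was chosen over conditioned rate
matrices because it is simple and exact for the properties being tested.
The default $\kappa = 2$ reflects typical nuclear-gene transition bias.
One consequence is worth stating plainly: NG86 counts sites assuming
unbiased mutation, so on $\kappa > 1$ data it *systematically*
underestimates $\omega$ (transition-rich synonymous changes inflate $p_S$
per unweighted site).  The dN/dS *calibration* checks therefore simulate
at $\kappa = 1$, isolating estimator error from this known model
mismatch, while ordering robustness is additionally exercised at
$\kappa = 2$ — the fixture bundle and the clock analyses all run at
$\kappa = 2$.

What the generators do **not** emulate: among-site rate heterogeneity,
indels and alignment error, codon-usage and GC bias, oocyte-to-oocyte
geometry variation, correlated (non-i.i.d.) measurement noise, unstirred
layers, and boric-acid speciation chemistry.  Green tests demonstrate
estimator correctness under the stated models, not robustness to
everything real data can do.

## 7. Numerical and interface conventions

* Coordinates are 0-based half-open internally (dot-plot anchors,
  amplicon spans); 1-based only in human-facing tables (filter columns).
* Identity percentages keep full precision; round for reporting.
* Restriction digestion cuts at *every* IUPAC match on the top strand,
  overlapping sites included; fragment lengths always sum to the input
  length.  In-silico PCR uses exact primer matching (the study's primers
  match both paralogs at 100 %), warns on multiple products, and
  amplicons always equal the template slice.
* RNG: every stochastic routine requires an explicit seed and restores
  the caller's RNG state; pipeline manifests record seeds, parameters,
  package version and input/output checksums, and identical configs give
  identical manifests.
* Problem sizes in the shipped tests (500-codon contrasts at 100 seeds,
  1000-codon clock recovery at 5 seeds, 10-oocyte noisy groups) were
  chosen so each check's own Monte-Carlo error is small relative to the
  bound it asserts.

## 8. Known limitations

Topology inference is NJ-based (no full ML tree search with NNI/SPR);
codon-model ML estimation of $\omega$ (GY94-style) is out of scope — NG86
is the implemented and validated counting method; clock dating is the
single-calibration approximation described above; and the solute
estimator inherits the water-equilibration assumption of its published
formula.  Reproducing the printed values of the motivating study requires
its original sequence accessions and supplementary alignment, which the
package does not download; the synthetic emulation reproduces the
*pattern* (a ~9-fold dN contrast at comparable dS, recent duplication
ages, the broad/narrow filter table) with known ground truth instead.
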