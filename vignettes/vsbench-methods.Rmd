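---
title: "Methods: benchmark construction, conformer selection, and kinetics models in vsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark construction, conformer selection, and kinetics models in vsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsbench)
```

# Scope

`vsbench` implements the desk-side computational machinery of a
structure-based virtual-screening campaign against a flexible enzyme target:
building a property-matched decoy benchmark, validating receptor models by
early-recognition enrichment, selecting receptor conformations from a
trajectory, combining two docking programs' hit lists, and fitting the
dose–response and enzyme-inhibition models used to characterize confirmed
hits. Docking itself is deliberately out of scope: every stage consumes
scores or structures through explicit interfaces (CSV tables, provider
functions), so proprietary engines can be plugged in where available and
seeded synthetic generators stand in for them everywhere else.

# Property-matched decoy selection

## The decoy score

A decoy is a presumed-inactive molecule that mimics an active's
physicochemical profile while differing structurally, so that a docking
program cannot separate actives from decoys on bulk properties alone. For an
active $a$ and candidate $c$ the selection key is

$$\mathrm{score}(a, c) \;=\; \Delta PK(a, c) \;+\; \lvert \mathrm{combo}(a, c) - 2 \rvert,$$

where $\Delta PK$ sums absolute differences over seven descriptors
(H-bond acceptors, H-bond donors, logS, SlogP, molecular weight, rotatable
bonds, TPSA) and $\mathrm{combo} \in [0, 2]$ is a shape + pharmacophore
similarity whose maximum 2 denotes identical structure. Both terms are
oriented so that smaller is a better mimic; a candidate identical to the
active scores exactly 0.

Two conventions were genuinely open and are both exposed:

* **Raw vs. scaled $\Delta PK$** (`delta_mode`). The descriptors carry
  incommensurate units (Da, Å², counts), so the raw sum is dominated by
  molecular weight and TPSA. The default is the literal raw sum; `scaled`
  divides each term by a user-supplied or pool-MAD scale
  ([pool_descriptor_scales()]) for unit-free matching.
* **Descriptor provenance.** logS and SlogP are model-dependent, so the
  package never computes descriptors internally: a provider object supplies
  them, either a lookup of precomputed values
  ([table_descriptor_provider()]) or the bundled openbabel adapter
  ([openbabel_descriptor_provider()]), which estimates logS with the ESOL
  regression (Delaney 2004, *J. Chem. Inf. Comput. Sci.* 44:1000–1005) from
  logP, molecular weight, rotatable bonds and aromatic proportion. The
  provider records its model choices in `$info`.

## Iterative selection with pool removal

[select_decoys()] processes actives in pool order (a recorded, configurable
permutation): all remaining candidates are scored, ranked ascending, the top
`quota` (default 20) assigned, and **removed** from the candidate pool
before the next active. Removal makes decoy sets disjoint by construction,
which is why a run with $n$ actives and quota $q$ on a sufficiently large
pool yields exactly $nq$ distinct decoys. The procedure is order-sensitive —
an early active can take candidates a later active would have ranked higher
— which is inherent to the iterate-and-remove design; the processing order
is therefore stored in the result. Ties on the score are broken by
lexicographic candidate id so runs are reproducible across platforms.

# The USR-style comboscore reference provider

The original campaign scored 3D similarity with a proprietary overlay
program. Decoy selection, however, consumes only a scalar in $[0,2]$, so the
package defines the provider contract (any function
`(active, candidate) -> [0, 2]`) and bundles a self-contained alignment-free
reference:

* **Shape**: the classic 12-descriptor USR construction — for the centroid,
  the atom closest to it, the atom farthest from it, and the atom farthest
  from that atom, the distance distribution to all atoms is summarized by
  mean, standard deviation, and signed cube root of the third central moment
  (population moments, all in Å, so a single atom gives the zero vector).
  Two clouds compare as $1 / (1 + \bar{\ell}_1)$ with $\bar{\ell}_1$ the
  mean absolute moment difference.
* **Color**: the same construction restricted to atoms of each pharmacophore
  feature type (donor, acceptor, anion, cation, aromatic, hydrophobe),
  averaged over the types present in either molecule, with a type present in
  only one contributing 0.

Both terms are rigid-motion invariant and symmetric, total $\in [0, 2]$,
and self-comparison gives exactly 2. The reference provider operates on the
single conformer stored in each record (recorded in its `$info`); it does
not attempt to reproduce any particular overlay program's numbers, only the
contract. [usr_combo_provider()] caches moments per molecule id, which makes
pool-scale selection linear in pool size — and means a provider instance
must not be reused across pools that recycle ids.

# Enrichment evaluation

[recovery_curve()] ranks ligands ascending by score (docking convention:
lower is better) and records the fraction of actives recovered after each
ranked ligand. Ties receive average ranks, so the curve is independent of
input order and invariant under strictly monotone score transforms.
[auc_at_fraction()] integrates the piecewise-linear curve over $[0, x]$ by
the trapezoid rule; $x = 0.1$ corresponds to the common "top 10% of the
database" analysis window. The default reports the **raw** truncated area
(range $[0, x]$; a random ranking gives $x^2/2$ in expectation, i.e. 0.005
at $x = 0.1$), because that scale is what screening reports conventionally
print alongside recovery counts; `normalize = "ideal"` divides by the best
achievable area for the same number of actives, library size and cutoff,
giving 1 for a perfect ranking. [retrieved_at_fraction()] counts actives
with rank at most $\lceil x N \rceil$.

Receptor-ensemble tables aggregate with the per-ligand **best** (minimum)
score over the selected models — the rule a pose-retaining workflow
effectively applies — with `mean` as a configuration hook. Duplicate
ionization/tautomer states of one parent compound are collapsed by
arithmetic mean ([average_duplicate_scores()]). Two programs' hit lists are
combined by mean-rank (Borda) consensus ([consensus_rank()]), the
minimal-assumption combination rule; remaining ties order lexicographically
by ligand id.

# Conformer selection from a trajectory

[kabsch_superpose()] computes the closed-form optimal rigid superposition
via SVD of the cross-covariance matrix with the usual reflection correction
(determinant forced to $+1$); collinear point sets are rejected because the
rotation is not unique. [rmsd_matrix()] first superposes every frame onto
frame 1 (optionally on a superposition mask such as backbone atoms), then
computes plain pairwise RMSD on an analysis mask — e.g. the heavy atoms
within 10 Å of the binding pocket, built by [pocket_mask()]. Masked analysis
after a single global fit matches the trajectory-analysis convention and
keeps the matrix consistent with a fixed laboratory frame.

[gromos_cluster()] is the iterative neighbor-counting algorithm: among
unassigned frames, the frame with the most neighbors within the cutoff
(distance $\le$ cutoff; ties to the lowest frame index) becomes a centroid,
its neighborhood forms a cluster and is removed, and the step repeats. The
output is always a partition. [select_centroids()] takes the centroids of
the most populated clusters (default 5), with size ties resolved by earliest
centroid; an `extra_frames` argument appends conformations chosen on other
grounds (e.g. unusual solvent exposure), since such criteria are outside
this module's scope.

# Kinetics models

Two models, both fitted by unweighted nonlinear least squares with
Levenberg–Marquardt (minpack.lm), positive parameters log-parameterized so
positivity holds by construction, and delta-method standard errors for the
back-transformed parameters:

* **Dose–response (4PL)**:
  $y = \mathrm{Bottom} + (\mathrm{Top} - \mathrm{Bottom}) /
  (1 + 10^{(\log_{10} IC_{50} - \log_{10} c)\,h})$.
  The Hill slope is free by default (`hill_mode = "variable"`), with a
  `fixed_1` variant, the two standard GraphPad forms. Starting values come
  from the data (plateaus from the response extremes, $IC_{50}$ from the
  concentration nearest the half-range). Because swapping the plateaus and
  negating $h$ is an exact reparameterization of the same curve, fits are
  normalized post hoc to $\mathrm{Top} \ge \mathrm{Bottom}$. The fit
  requires at least 5 distinct concentrations spanning 2 log units —
  anything less cannot constrain two plateaus and a midpoint.
* **Uncompetitive inhibition**:
  $v = V_{max} S / (K_m + S(1 + I/\alpha K_i))$, fitted jointly over all
  (substrate, inhibitor) observations; at $I = 0$ it reduces to
  Michaelis–Menten, which is why inhibitor-free rows anchor $V_{max}$ and
  $K_m$ (their absence triggers a weak-identifiability warning, not an
  error). A **mixed-model** variant
  $v = V_{max} S / (K_m(1 + I/K_i) + S(1 + I/\alpha K_i))$ is provided
  because an allosteric inhibitor's phenomenology may be described as
  non-competitive (the mixed model with $K_i = \alpha K_i$) even when the
  uncompetitive special case fits the data; the package supplies both and
  leaves model choice to residual comparison rather than deciding the
  mechanism.

# Synthetic data: what it emulates and what it does not

The generators produce inputs with the statistical structure the analysis
assumes, deterministically per seed (each runs in a private RNG scope and
restores the caller's stream):

* [gen_pool()] draws descriptors uniformly from drug-like windows
  (MW 150–550 Da, TPSA 20–140 Å², counts 0–10, logS −6–0, SlogP −1–5) and
  atom clouds from an isotropic Gaussian (σ = 3 Å) with Bernoulli feature
  tags. A `mimic_fraction` (default 0.3) of candidates are perturbed copies
  of actives — small descriptor noise, 0.1 Å coordinate jitter, identical
  tags — planting exactly the "property mimic" structure decoy selection is
  supposed to find. The defaults (11 actives, 500 candidates) reproduce the
  scale of a small validation benchmark: 11 actives × quota 20 = 220
  decoys from a pool that comfortably covers the demand.
* [gen_screen()] draws one latent score per ligand (actives
  $\mathcal{N}(\mu_a, \sigma_a)$, decoys $\mathcal{N}(\mu_d, \sigma_d)$;
  defaults $-9$ vs $-6.5$, σ = 1, i.e. a clearly separable screen) and adds
  per-model Normal jitter (σ = 0.5) for each of 7 receptor models of a
  231-ligand screen. Setting $\mu_a = \mu_d$ yields the null screen used
  for AUC calibration. [gen_variant_scores()] emulates ligand-preparation
  expansion: 500 docked states over 115 parent compounds by default.
* [gen_conformers()] plants cluster structure by displacing every atom of a
  base geometry independently per blob (σ = `separation`, default 2 Å), so
  blobs differ in internal geometry rather than by a rigid motion, and
  jitters frames within blobs (σ = 0.1 Å). At these defaults within-blob
  RMSD (≈ σ√6 ≈ 0.25 Å before fitting) sits well below the 0.75 Å
  clustering cutoff and between-blob RMSD (≈ 5 Å) well above it.

None of this imitates real chemistry: synthetic records carry no SMILES, the
descriptor marginals are independent where real descriptors are strongly
correlated (MW with rotatable bonds, logP with logS), score distributions
are Gaussian where real docking scores are heavy-tailed, and conformer
variation is isotropic where real side-chain motion is concerted. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and recover planted structure — not that any particular real screen would
enrich.

# Numerical choices and problem sizes

* Score ties in selection break lexicographically by candidate id; rank ties
  in enrichment use average ranks; gromos neighbor ties take the lowest
  frame index. All three make results permutation-independent.
* Rigid-motion invariance of the USR moments holds to 1e−9 (double-precision
  SVD and sums); Kabsch recovery of exact rigid copies is asserted at the
  same tolerance.
* Noiseless kinetic fits recover generating parameters to 1e−6 relative;
  Monte-Carlo recovery studies in the test suite use 200 replicates at 3%
  Gaussian noise, and enrichment calibration uses 500 null screens of
  231 ligands — sizes chosen so the full suite exercises every stochastic
  claim while remaining a sub-minute default run.
* Degenerate inputs fail loudly: empty atom clouds, untagged clouds passed
  to the color term, collinear geometries, non-symmetric RMSD matrices,
  mismatched consensus ligand sets (reported with the symmetric
  difference), candidate exhaustion (configurable error or partial
  assignment with warning).

# Known limitations

* The reference comboscore is a surrogate: it preserves the contract
  (bounds, symmetry, rigid invariance, maximum at identity), not any overlay
  program's values; selections driven by a real engine will differ.
* Raw $\Delta PK$ mixes units; use `scaled` mode when descriptor ranges
  differ strongly from the defaults' drug-like windows.
* The enrichment module evaluates rankings; it performs no docking and no
  pose analysis, and printed per-model AUC values from engine-driven screens
  are not comparable to synthetic-screen AUCs.
* Solvent-accessible surface area is not computed; conformations selected on
  SASA grounds enter [select_centroids()] only as explicit extra frames.
* The mask recipe for "residues within 10 Å of the pocket" operates on
  atoms; mapping atoms to residues is the caller's responsibility, keeping
  the module independent of any one structure format's residue model.
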