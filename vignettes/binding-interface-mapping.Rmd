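---
title: "Mapping a peptide-receptor interface from NMR titrations, ITC and ensemble statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a peptide-receptor interface from NMR titrations, ITC and ensemble statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmap)
```

## Scope and model

`bindmap` implements the quantitative pipeline used to characterise how a
small disulfide-rich peptide — the worked system throughout is chlorotoxin
(ClTx), a 36-residue scorpion toxin with four disulfides — engages the b1
domain of neuropilin-1 (NRP1-b1). The pipeline has four quantitative legs,
each a module of the package:

1. **CSP titration mapping** (`analyze_titration()` and friends): amide
   chemical-shift perturbations and intensity losses across an HSQC
   titration locate the binding interface; a competitor point tests whether
   a second ligand displaces the peptide from the same site.
2. **Binding equilibria** (`bound_fraction_1to1()`,
   `competitive_equilibrium()`): exact single-site 1:1 and one-site,
   two-ligand solvers shared by the NMR and ITC legs, plus the
   thermodynamic identities `dG = RT ln Kd` and `-TdS = dG - dH`.
3. **ITC simulation and fitting** (`simulate_thermogram()`,
   `fit_thermogram()`): forward model and weighted least-squares refit of
   per-injection normalized heats under a discrete injection schedule, for
   direct and competitor-pre-loaded (displacement) experiments.
4. **Structure-ensemble statistics and docking restraints**
   (`mean_coordinate_rmsd()`, `detect_disulfides()`, `find_patches()`,
   `cltx_nrp1_restraints()`, `write_tbl()`): precision statistics of a
   multi-model NMR ensemble, identification of the toxin's charged and
   hydrophobic surface patches, and derivation/export of docking restraints
   from the CSP map.

A seeded synthetic-data generator (`make_titration_fixture()`,
`make_thermogram_fixture()`, `make_toy_ensemble()`) produces every input the
pipeline consumes with known ground truth, so the whole chain is testable
without any deposited data.

## Fast-exchange CSP analysis

Under fast exchange the observed peak position is the population-weighted
average of the free and bound states, so the combined shift change at a
titration point is `d_obs = f_bound * d_max` per residue. The combined CSP
uses the conventional quadrature weighting

```
d = sqrt(dH^2 + (alpha * dN)^2)
```

with `alpha = 0.2` by default. The 15N scaling factor is the one
free parameter of the metric; 0.2 is the field's usual choice reflecting
the ~5-fold wider 15N shift range, and it is exposed as `alpha=` everywhere
rather than hard-coded. Glycine-specific scaling is deliberately not
applied: the interface sets this package targets include several glycines
and a uniform weight keeps the threshold rule interpretable.

Significance uses the plain mu/sigma rule: the mean and sample standard
deviation (n-1) of the scored change over **all** residues, with no
trimming or iterative exclusion, flagging residues above `mu + sigma`. In
shift mode the score is the CSP itself; in intensity mode it is the
attenuation `1 - I/I0`, so a peak broadened beyond detection (ratio 0)
scores 1 and remains flaggable. The scored point is the final
competitor-free titration point — the most perturbed spectrum — while the
intermediate ladder points feed only the Kd fit. Both choices are
configuration with these defaults because no single convention is
universal.

`fit_kd_from_shifts()` profiles out the per-residue `d_max` (for a trial Kd
the least-squares amplitude is closed-form), leaving a one-dimensional
search on log Kd. This makes the global fit deterministic and fast, and on
noiseless synthetic data it recovers the generating Kd to well under 1%
across the 10-500 uM range sampled by the titration ladder.

Displacement is quantified by `competition_recovery()`: per-residue
recovery `1 - csp(competitor)/csp(receptor-only)` clipped to [0, 1], and a
verdict of `"recovered"` when the mean CSP of the previously flagged
residues falls back below the significance threshold. The observed recovery
is cross-checked against the occupancy predicted by
`competitive_equilibrium()` at the stated concentrations: at 55 uM peptide,
125 uM receptor, 413 uM of a 7.9 uM-Kd competitor, the peptide's predicted
occupancy is ~5% of its competitor-free value, consistent with a fully
recovered spectrum.

## Equilibrium solvers

The 1:1 bound fraction uses the quadratic's physical root in the
cancellation-safe form `2PL/(b + sqrt(b^2 - 4PL))`; the competitive case is
solved by monotone bracketing on free receptor followed by Newton polish,
because the mass-balance function is strictly increasing and the bracket
`(0, N*P_tot]` always contains exactly one root — robust across the twelve
orders of magnitude of concentration the test suite throws at it, unlike
the raw cubic formula. Convergence is enforced at a relative mass-balance
residual below 1e-9 (typically ~1e-15). Stoichiometry enters as the
effective site concentration `N * P_tot`; the standard state of
`dG = RT ln Kd` is the implicit 1 M, with `R = 1.987204e-3` kcal/(mol K)
and a default temperature of 305.15 K (the 32 C of the calorimetry).

## ITC model

Concentrations follow the standard single-cell perfusion treatment: after a
cumulative injected volume `v` into a cell of volume `V0`, cell-loaded
species sit at `C0 (1 - v/2V0)/(1 + v/2V0)` and the syringe species at
`Cs (v/V0)/(1 + v/2V0)`. The cumulative binding heat is
`Q = V0 (dH_A [PA] + dH_B [PB])` and the observed heat of injection `i` is

```
h_i = Q_i - Q_{i-1} + (dV_i / V0) * (Q_i + Q_{i-1}) / 2
```

normalized per mole of injectant. The default schedule is the study's: an
800 uM syringe titrated into a 40 uM cell as one 0.4 uL pre-injection
(updates concentrations, excluded from fitting) plus twelve 3.22 uL
injections, in a 200 uL cell — a typical low-volume-calorimeter cell size,
configurable and recorded with the schedule.

`fit_thermogram()` fits (Kd, dH, baseline) with N fixed at 1.0, Kd on the
log scale, via Levenberg-Marquardt. Start values are deterministic (dH from
the first fitted injection relative to the last, Kd from the cell
concentration at mid-titration, baseline from the final injection), so
identical inputs always reproduce identical fits. The constant baseline
absorbs heats of dilution; no separate blank titration is modelled. Even at
the weak-binding end (c = N[cell]/Kd ~ 0.28 for the 143.3 uM ligand) the
noiseless round trip is exact to numerical precision, and a 200-replicate
study at 2% heat noise recovers the median Kd of the tight ligand within a
few percent.

### Competition and the suppression metric

A displacement experiment pre-loads the cell with competitor; the solver
then tracks both complexes. Two honest subtleties:

* **The residual endotherm.** Diluting a nearly saturated
  competitor-receptor complex releases a small, nearly constant endothermic
  heat each injection (the complex re-equilibrates at lower concentration).
  With 200 uM of the tight competitor in the cell this plateau is about
  +0.1 kcal/mol — small, but not zero, and it is a *constant offset*, not a
  binding isotherm. The package therefore defines binding-signal
  suppression on baseline-corrected heats: `suppression_ratio()` removes
  each trace's post-saturation plateau (median of the last three
  injections) before comparing amplitudes, consistent with the
  constant-offset treatment of dilution heats used in fitting. Under the
  study's conditions the weak ligand's binding signal is suppressed to ~3%
  of the competitor-free titration (the raw, offset-including ratio is
  ~23%, essentially all of it the dilution endotherm; both numbers are
  reported by the function).
* **Identifiability.** Fitting the suppressed weak-ligand trace is
  ill-conditioned — it is a near-flat line, and (Kd, dH, baseline) trade
  off. The identifiable displacement design, fitting the tight ligand as it
  displaces a weak pre-bound one, is exact in round trips and is what the
  competitive-fit tests exercise. The blocked direction is assessed as a
  forward simulation plus suppression check, which is how the underlying
  experiment is interpreted.

## Ensemble statistics

Superposition is the Kabsch SVD solution constrained to a proper rotation;
`mean_coordinate_rmsd()` iterates superposition onto the running mean
(initial reference: model 1) until the mean moves less than 1e-6 A, then
reports the per-model RMSDs to the converged mean as mean +/- sample sd —
the convention of NMR refinement-statistics tables. The backbone selection
is N, CA, C, O and "heavy" means all non-hydrogen; both are configurable
because published tables rarely state their atom sets, and for the same
reason the heavy-atom statistic can be computed with the fit performed on
either selection.

Disulfides are detected as mutual-nearest SG-SG contacts below 2.5 A
(covalent S-S is ~2.05 A; the margin absorbs coordinate noise); an SG with
two sub-cutoff partners and no mutual match is reported as ambiguous rather
than assigned. Connectivities are also expressed as the ordinal cystine
framework (ClTx: Cys2-Cys19, Cys5-Cys28, Cys16-Cys33, Cys20-Cys35, i.e.
1-4,2-6,3-7,5-8).

Surface patches are single-linkage clusters (cutoff 10 A) of representative
side-chain points: the terminal charged atoms CZ/NZ for Arg/Lys, side-chain
centroids otherwise. Only the resulting memberships, not the clustering
rule, are constrained by observation, so the rule is deliberately the
simplest one that is monotone under merging; the hydrophobic class defaults
to {F, T, H} — the residue types forming the toxin's weakly hydrophobic
face — and is configurable. On ClTx this yields the two basic patches
{R14, K15, K23} and {R25, K27, R36} and the hydrophobic patch
{F6, T7, T8, H10}.

Restraint bookkeeping bins distance restraints by sequence separation
(intra 0, sequential 1, medium 2-4, long >= 5); restraints-per-residue
counts distance + disulfide + dihedral restraints over the sequence length
(533 + 12 + 57 over 36 residues gives 16.7).

## Docking restraints

`cltx_nrp1_restraints()` returns the three unambiguous restraints that
anchor the toxin's C-terminal arginine in the receptor's conserved
carboxylate-binding pocket — Arg36 carbonyl C to Trp301 NE1 (4.0-5.5 A),
Arg36 CZ to residue 319 CG (5.0-7.0 A), Lys27 NZ to residue 319 CG — plus
the flexible segments 24-28 and 35-36 (the stretches whose perturbed
glycine/cysteine amides suggest conformational exchange). The Lys27
restraint has no published bounds; the default 3.0-5.0 A is a
salt-bridge-compatible range, exposed as `k27_bounds=` and recorded in the
output. The receptor residue at 319 is referred to inconsistently as
aspartate or glutamate in the source material; the package keys the
restraint on residue *number* 319 with atom CG and does not validate the
residue type. Restraints are written in CNS `assign` syntax with
`d = (lower+upper)/2` and symmetric half-widths at two decimals, and the
writer/parser pair round-trips byte-identically.

Active residues for ambiguous restraints are the flagged residues passing a
surface-exposure proxy — fewer than 35 heavy atoms within 8 A of the
side-chain centroid — chosen as a cheap, monotone surrogate for solvent
accessibility that needs no SASA machinery; passive residues are the
exposed +/-2 sequence neighbours of active residues.

## Synthetic data: what it does and does not emulate

The titration generator implements exactly the fast-exchange forward model
the analysis assumes: shifts move linearly with bound fraction toward a
per-residue `d_max`, intensities attenuate as `I0 (1 - f (1 - beta))` with
a per-residue residual factor `beta`, shift noise is additive Gaussian
(0.003 ppm 1H / 0.015 ppm 15N), intensity noise multiplicative log-normal
(2%), and peaks below 5% of their reference intensity vanish. Defaults are
the study conditions: 55 uM observed peptide, receptor ladder
0/21/34/45/57/95/125 uM, Kd 143.3 uM, competitor point at 413 uM with Kd
7.9 uM, shift interface {2,20,21,23,25,26,28,29,34} and intensity interface
{2,25,26,27,28,35,36}; maximal shift amplitudes (1H 0.28-0.34 ppm, 15N
1.3-1.6 ppm) and broadening factors (beta 0.10-0.25) are drawn per residue
in ranges chosen once as typical of a weak but specific peptide-domain
interaction. Prolines (4, 31) and the N-terminal residue carry no
observable amide and are absent, leaving 33 scored residues.

What passing these tests shows is that the analysis recovers a known
fast-exchange ground truth under realistic noise; what it cannot show is
robustness to what real spectra add — peak overlap, intermediate-exchange
lineshapes, titration-dependent referencing drift, assignment errors. The
toy coordinate ensemble likewise realises only the engineered features the
operators measure (disulfide geometry, patch layout, backbone continuity);
it is not a physically plausible fold, and ensemble statistics on it test
the algorithms, not NMR structure quality.

All generators are pure functions of (parameters, seed) via a single RNG
scope, so manifests regenerate byte-identical files.

## Numerical choices and problem sizes

Superposition tolerates down to 3 non-collinear atom pairs and rejects
degenerate geometry via the covariance spectrum; the mean-coordinate
iteration caps at 100 rounds (it converges in 2-3 on real-scale spreads).
The equilibrium solvers are exercised property-style on thousands of random
parameter draws per run; the ITC round-trip sweep covers c in [0.1, 1000]
over 20 seeded draws, and the noisy-replicate study uses 200 seeds at 2%
noise — sizes picked so the full suite stays interactive (~30 s) while
every stochastic claim is still estimated from a real ensemble. Mass
calculations carry 100% isotope enrichment for 15N/13C labelling and treat
"deamidated" peptide as the free-acid C-terminus (the amide form is a
flag); monoisotopic and average conventions are both reported by
`mass_report()` because printed "calculated masses" often omit the
convention — for 15N-labelled, fully oxidised, free-acid ClTx the
monoisotopic value (4045.39 Da) is the one matching the MALDI measurement
of the labelled toxin, while the average value lands ~3 Da higher.

## Known limitations

No slow/intermediate-exchange lineshape modelling; no multi-site or
cooperative binding; no heat-capacity analysis; no SASA, no docking
execution or pose scoring; restraint statistics do not reproduce
stereochemical quality metrics. The interface of the package is its R
functions; file formats (Sparky-style peak lists, thermogram CSV,
multi-model PDB, CNS tbl, TSV restraint lists) are the exchange points with
the rest of a structural-biology toolchain.
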