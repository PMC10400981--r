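---
title: "Methods: models, parameters and numerical choices in hemewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in hemewire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemewire)
```

`hemewire` models a family of de novo four-helix heme maquettes: a diheme
antiparallel bundle, its monoheme derivative, and an extended tetraheme
"molecular wire" built by splicing the helix sequence. The package covers
five stages — parametric backbone construction, heme placement and geometric
measurement, electron-transfer rate estimation, electrostatic prediction of
midpoint potentials, and fitting of potentiometric and tight-binding data —
plus seeded synthetic-data generators so every fitter can be validated in
closed loop. This vignette records the modelling assumptions, the meaning
and defaults of every physical parameter, and the numerical design
decisions, so that results can be interpreted without reading the source.

## 1. Parametric coiled-coil construction

Backbones are ideal Crick coiled coils: a minor helix of radius $r_1$ and
angular frequency $\omega_1$ wound around a superhelical path of radius
$r_0$, frequency $\omega_0$ and axial rise $d$ per residue. `build_helix()`
evaluates the standard parameterisation; `fit_crick_params()` inverts it by
Levenberg–Marquardt least squares with a multistart over the minor-helix
phase (the only parameter with a genuinely multimodal error surface), and
reports the residual coordinate RMSD. Inputs that a coiled coil cannot
describe (residual RMSD above 1.5 Å) are rejected rather than returned with
a misleading parameter set, and a near-zero fitted supercoiling frequency is
flagged `ill_determined` because $r_0$ then degenerates into an arbitrary
lateral offset.

Defaults (`crick_params()`): $r_0 = 7.6$ Å, $\omega_0 = -2.85$°/res
(left-handed), $r_1 = 2.26$ Å, $\omega_1 = 102.857$°/res (the 7/2 heptad
value), $d = 1.51$ Å/res. These are canonical values for antiparallel
four-helix coiled coils, chosen once as the package's idealisation; they are
deliberately not tuned to reproduce any particular deposited structure. The
validator enforces $r_1 \in [1.5, 3]$ Å, $|\omega_1| \in [95, 110]$°/res and
$d \in [1.0, 1.6]$ Å/res — outside these windows the "helix" is not an
alpha-helical backbone and downstream geometry would be meaningless.

The 25-residue reference sequence (`base_helix_sequence()`) is likewise a
package-internal idealisation, not a published sequence: heptad register
starting at `a`, a core-facing ligating histidine at position 8, the
"keystone" threonine at position 19, an arginine at position 6 and a core
methionine at position 23. The packing variant replaces the histidine with
leucine. `assemble_bundle()` places four equal-length helices at superhelix
phases 0/90/180/270° with alternating up/down orientation (pseudo-D2);
down-running helices are obtained by a proper 180° rotation so chirality is
preserved. Loop sequences (`TSN`, `GSVSP`, `TSN`) are carried as annotations
that extend the global residue numbering; loop coordinates are not modelled.

## 2. Helix splicing

`splice_helix()` extends the 25-mer by sequence repetition, trimming
`junction_trim` residues from each side of every junction. The resulting
repeat period must keep successive histidines an integral number of heptads
apart; with the default trim of 2 the period is 21 residues (three heptads)
and two repeats give the 46-residue wire helix. Any trim whose period is not
a multiple of 7 is rejected with a registry error, because the spliced
histidines would face different core environments.

## 3. Heme placement and geometric measurements

Hemes are placed rigidly for each opposing histidine pair: Fe at the
midpoint of the two Cα positions, heme normal along the inter-His axis,
model Nε atoms at $\pm 2.1$ Å from Fe (the bis-His coordination distance),
and the heme plane containing the bundle axis. The idealised planar template
holds Fe plus the 28-atom conjugated set (4 pyrrole N, 16 ring C, 4 meso C,
4 vinyl C with PDB HEM names); propionates and methyls are excluded because
edge-to-edge electron-transfer distances are defined on the conjugated
system only. Placement is refused when the designated residues are not both
histidine, when their axial registry differs by more than 2.5 Å, or when the
pseudo-Cβ separation falls outside 8–14 Å (the span a bis-His heme can
bridge).

`edge_to_edge()` is the minimum pairwise distance between two conjugated
sets; `chain_span()` the maximum distance between the first and last heme of
a chain; `keystone_distances()` the His ND1 to Thr OG1 / Asp OD1/OD2
distances in full-atom structures (Cα-only models raise a capability error
instead of silently returning nothing). `write_structure()` /
`read_structure()` round-trip models through PDB, with ligating histidines
recoverable via their Nε records.

## 4. Electron-transfer ruler

`ket()` implements the empirical nonadiabatic rate ruler for protein
interiors,
$$\log_{10} k = 15 - 0.6\,R - 3.1\,\frac{(\Delta G + \lambda)^2}{\lambda},$$
with $R$ the edge-to-edge distance in Å and energies in eV. `driving_force`
is the magnitude of the exergonic driving force ($\Delta G =
-\text{driving force}$); defaults 0.06 eV and $\lambda = 0.7$ eV are typical
interheme values. Distances below van der Waals contact (3.6 Å) are clamped
with a warning, and the endergonic direction follows detailed balance,
$\log_{10} k_{up} = \log_{10} k_{down} - |\Delta G| / 0.059$.

## 5. Electrostatic site model

Midpoint-potential prediction uses a microstate model over $N$ binary sites
(redox: occupied = reduced, charge $-1$; acid: occupied = deprotonated,
$-1$; base: occupied = protonated, $+1$):
$$G(x) = \sum_i x_i g_i + \sum_{i<j} x_i x_j W_{ij},$$
with, at 298 K, $g_i = E_{sol} - E_{m,int,i}$ (meV) for redox sites and
$g_i = \pm \ln(10)\,kT\,(pK_{a,int,i} - \text{pH})$ for acids/bases
($kT = 25.693$ meV, $\ln(10)\,kT = 59.16$ meV $\equiv$ mV per decade).
Interactions are screened Coulomb terms,
$W_{ij} = 14399.645\,q_i q_j / (\varepsilon\,r_{ij})$ meV, with a uniform
protein dielectric $\varepsilon = 20$ — the single-dielectric stand-in for a
two-dielectric molecular-surface treatment; the solvent value (80) is
carried as metadata, and an optional Debye factor $e^{-\kappa r}$,
$\kappa = \sqrt{I}/3.04$ Å$^{-1}$, handles non-zero ionic strength.
Distances under 2 Å are floored with a warning. Externally computed $g$ and
$W$ tables (e.g. from a Poisson–Boltzmann backend) can be supplied directly
or imported from TSV, replacing the built-in model without touching the
titration machinery.

Intrinsic pKa values use standard model compounds: Asp 4.0, Glu 4.4,
Arg 12.0, Lys 10.4, non-ligating His 6.3. The heme intrinsic potential
defaults to $-118$ mV vs NHE — a calibration to the measured monoheme
reference midpoint, so only *shifts* between systems sharing this
calibration are claimed predictive, never absolute potentials. Mutations on
Cα-only models place the side-chain charge at the Cα displaced 2.5 Å toward
the bundle axis; this is deliberately crude (a real carboxylate samples
rotamers), which is one reason predicted shift magnitudes for close
mutations exceed measured ones.

## 6. Titration engines and midpoint extraction

`exact_titrate()` Boltzmann-averages over all $2^N$ microstates (refused
above 20 sites: $2^{20} \times$ grid is the desk-scale ceiling) and serves
as the oracle. `mc_titrate()` runs an independent single-site-flip
Metropolis chain at each grid potential: default $10^5$ steps, first 20%
discarded as burn-in, mean occupancies with batch-mean standard errors.
Fewer than 1000 steps are refused as unreliable. The chain consumes R's RNG
stream, so a seed is mandatory and identical seeds give bitwise-identical
results. Single-site flips (rather than pair moves) are adequate for ≤ 20
weakly frustrated sites; strongly coupled systems mix more slowly, which the
validation design below accounts for.

The default grid is $-400$ to $+100$ mV in 5 mV steps at pH 8.6 (the
potentiometry buffer). `extract_em()` smooths the occupancy curve by
isotonic regression (physical monotonicity is known a priori; smoothing
suppresses MC noise without bias) and interpolates the half-occupancy
crossing; it is orientation-invariant and raises a range error suggesting
grid extension when the curve never crosses 0.5. `predict_shift()` is the
difference of extracted midpoints of variant and reference under the same
engine and grid. For a single redox site plus fixed charges the shift equals
$-\sum W/e$ exactly, which the tests exploit as a closed-form oracle.

### Validating MC against the exact oracle

The natural check "MC occupancy within 3 SE of exact at every grid point"
cannot hold literally: across thousands of grid-point comparisons some must
exceed 3 SE by chance, and because the SE is itself estimated from $B$
batch means the deviation/SE ratio follows a $t(B-1)$ distribution with
fatter tails than normal. The test suite therefore runs chains with
$B = 25$ batches and applies two thresholds sized from $t(24)$ tail
probabilities and the ~5800-comparison suite: per run at most 5% of points
beyond 3 SE (expectation 0.6%), and no point beyond 6 SE
($P(|t_{24}|{>}6) \approx 3{\times}10^{-6}$). Standard errors are floored at
the binomial SE with $n_{kept}/N$ effective samples — a single-flip chain
updates each site on at most $1/N$ of its steps, so per-site information
cannot exceed that bound (rare-flipping sites otherwise report deceptively
small batch SEs) — and at an absolute occupancy resolution of $3\times
10^{-4}$, below which differences have no physical meaning. A defective
sampler produces ratios of 20–250 against these floors, so the guard band
loses no discriminating power.

## 7. Fitting experimental-style data

`fit_redox()` fits sums of one or two $n = 1$ Nernst couples with the slope
fixed at 59.16 mV/decade (298 K): free relative weight for two couples, or
weights fixed at 0.5/0.5 in `pairs` mode — the parsimonious description of
a four-heme chain as two spectroscopically degenerate pairs. Midpoint
uncertainties come from the spread of per-replicate refits when at least two
replicates are present (robust to correlated residuals), otherwise from the
parameter covariance. Data that never approach one of the asymptotes
trigger a warning because the midpoints are then poorly identified.

`fit_kd()` fits the Morrison tight-binding bound fraction
$$\theta = \frac{P + L + K_D - \sqrt{(P + L + K_D)^2 - 4PL}}{2P}$$
with a linear signal model (scale and offset as nuisance parameters),
fitting $\ln K_D$ since the likelihood is near-Gaussian on that scale. A
profile-likelihood 95% interval is computed over a wide $\ln K_D$ grid; when
the profile stays flat down to the lower edge of the search range the lower
bound is unresolved and the result is flagged `is_upper_limit` with the
upper confidence bound reported — the correct statistical rendering of a
"$K_D <$ x" statement for an affinity far below what an isotherm at
micromolar protein can resolve. Identifiability caveat: at 3 µM sites with
2% noise on triplicate 24-point isotherms, a nanomolar $K_D$ carries
$\mathrm{sd}(\ln K_D) \approx 0.3$, so single-seed recoveries scatter
substantially around the truth; this is a property of the experiment's
information content, not of the optimizer.

## 8. Synthetic-data generators

`gen_redox_titration()` and `gen_binding_isotherm()` evaluate the exact
forward models on the study grids (potential $-400$ to $+100$ mV in 5 mV
steps; 24 ligand points from 0 to twice the site concentration) and add
i.i.d. Gaussian noise (sd 0.02, three replicates). These defaults represent
the emulated experimental conditions — optical potentiometry fractions and
normalised binding signals at typical shot-to-shot noise — and are treated
as study conditions, not tuning knobs. Seeds are mandatory; there is no
implicit randomness anywhere in the package. `gen_charge_variants()` places
Thr→Asp-style perturbing charges at chosen distances from the heme Fe,
either as non-titrating fixed charges (whose effect is exactly additive) or
as titratable acid/base sites. The generators deliberately do not model
instrument drift, baseline slopes, heteroscedastic noise or cooperative
binding; they exist to close the loop on the fitters, not to imitate raw
instrument output.

## 9. Problem sizes and limitations

Exact enumeration: ≤ 20 sites. MC titration: $10^5$ steps per grid point,
~2 s for a 10-site, 101-point curve. These ceilings are the package's own
desk-scale choices. Known limitations: backbone geometry is ideal (no
refinement, no loops in 3D); heme placement is rigid with a planar template;
the electrostatic model is single-dielectric with point charges at Fe and at
Cα-derived side-chain positions, so absolute energies are
calibration-dependent by construction; single-flip MC mixes slowly for
strongly coupled site clusters; and the fitters assume the generating noise
model (independent Gaussian). For structure-grade electrostatics, import
externally computed $g$/$W$ tables and reuse the titration and fitting
layers unchanged.
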