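---
title: "Probing structure predictors with degraded templates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing structure predictors with degraded templates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package does

Template-based structure predictors take a 3D structure as a hint alongside
the sequence channel. A direct way to ask *what the predictor actually reads
out of that hint* is to degrade the template in controlled ways — strip
side chains, move or remove the C&beta;, add coordinate noise, flatten the
fold onto its leading principal components — feed the degraded template to
the predictor, and score what comes back against the reference.
`templateprobe` implements the perturbation protocols and the full scoring
suite for that experiment, plus an idealized structure generator so that
every stage can be exercised and tested without downloading any external
data. Predictors themselves (AlphaFold-family models, diffusion samplers,
side-chain packers) are external: the pipeline only defines a minimal
shell-adapter contract for them.

The package is tidyverse-shaped: a structure is a tibble with one row per
heavy atom (`chain`, `resno`, `resname`, `atom`, `x`, `y`, `z`, ...), all
functions take that tibble first and return tibbles or scalar scores, and
result objects have `tidy()`, `glance()` and `autoplot()` methods.

## The metric suite

**Kabsch superposition.** `kabsch()` computes the proper rotation and
translation minimizing RMSD via the SVD of the 3x3 cross-covariance,
with the usual determinant correction so reflections are never returned.

**TM-score.** `tm_score()` maximizes
$\mathrm{TM} = \frac{1}{L_\mathrm{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}$
over rigid superpositions of the mapped C&alpha; pairs, with
$d_0 = \max(1.24\,(L_\mathrm{ref}-15)^{1/3} - 1.8,\; 0.5)$ Å and
normalization by the reference residue count. The search seeds
superpositions from gapless fragments of lengths $L, L/2, L/4, \dots \ge 4$
at half-length offsets; each seed is refined by re-superposing on the pairs
within a cutoff of $\max(d_0, 2)$ Å until the included set stabilizes, and
the best transform is finally polished by direct Nelder–Mead optimization of
the TM objective over the six rigid-motion parameters. Because the full-map
Kabsch fit is among the seeds and the polish can only improve the objective,
the reported score never falls below the single-superposition score. The
test suite checks the search against a brute-force multi-start optimizer on
small chains rather than against any particular binary.

**Rectified C&alpha;-RMSD.** `alpha_rmsd()` superposes the mapped C&alpha;
sets and caps each deviation at `cap` (default 5 Å) before squaring, so a
few wildly misplaced residues cannot dominate. The cap value is a package
convention, exposed as an argument; `cap = Inf` recovers the plain RMSD.

**All-atom / side-chain RMSD.** Atoms are paired by mapped residue and
identical atom name (no name remapping across residue types); the fit uses
backbone atoms; atoms present on one side only are skipped and counted.

**lDDT.** `lddt()` is superposition-free. Candidate pairs are heavy-atom
pairs *of the reference* within 15 Å and in different residues; a pair is
conserved at tolerance $t \in \{0.5, 1, 2, 4\}$ Å iff both atoms exist in
the model and the distance is reproduced within $t$. The global score
averages over pairs (not over per-residue means; both views are returned).
Missing model atoms count as non-conserved, penalizing incomplete models.
Ambiguous terminal naming (ASP, GLU, PHE, TYR rings and ARG NH) is resolved
per residue in the model's favor when `symmetry_resolution = TRUE`.
Stereochemistry gating is **off by default**: heavily perturbed templates
violate covalent geometry wholesale, and gating would empty the model. This
mirrors how such scoring is run on deliberately invalid structures.

**Stereochemistry check.** Bond lengths and angles are compared against the
same ideal-geometry constants the generator builds from (tolerance in
standard deviations, default 4, with sigma = 0.02 Å for bonds and 3 degrees
for angles), plus a severe-overlap floor of 1.5 Å between non-bonded
inter-residue heavy atoms. Ring-closure bonds and proline's ring contacts
with the preceding carbonyl (1-3/1-4 interactions through the ring
nitrogen) are covalent geometry and are exempt from the clash rule.

**&chi;-angle MAE.** Up to four side-chain torsions per residue, compared
with wrap-around at 360 degrees; for the 2-fold symmetric terminal groups
(ASP &chi;2, GLU &chi;3, PHE &chi;2, TYR &chi;2) the error is additionally
minimized over the 180-degree flip. ASN/GLN/HIS flips are chemically
distinguishable and deliberately *not* treated as symmetric.

**Burial.** A neighbor-count proxy: the number of other residues' C&beta;
(C&alpha; for glycine) within 10 Å. It avoids a solvent-accessible-surface
dependency; it is a stand-in for exposure, not a reproduction of any
particular SASA convention.

## Perturbations

* `gaussian_noise(s, sigma = 1)` adds an independent Normal(0, sigma^2)
  draw to every coordinate component, atoms in file order, x then y then z,
  from one seeded generator.
* `pca_project(s, n_components)` fits the principal axes on the structure's
  own heavy atoms (a C&alpha;-only option exists, since the atom subset
  used for the fit is a genuinely open choice), zeroes the trailing
  components, and restores the mean. Axis signs are fixed deterministically.
* `strip_sidechains(s, cbeta_mode)` keeps N, CA, C, O and handles C&beta;
  as `absent`, `origin` (a non-informative constant point (0.1, 0.1, 0.1) Å —
  the exact "near the origin" coordinate is unspecified upstream, so a
  small non-zero constant avoids exact-coincidence degeneracies), `heuristic`
  (rebuilt from the backbone), or `template` (kept). In `origin`/`heuristic`
  modes glycine also receives a C&beta; by default, consistent with
  glycine-extension semantics.
* `heuristic_cbeta(n, ca, c)` is the fixed linear combination
  `CB = CA + w_a (b x c) + w_b b + w_c c` with `b = CA - N`, `c = C - CA`
  and weights (-0.58273431, 0.56802827, -0.54067466); it reproduces an
  ideal tetrahedral C&beta; to well under 0.01 Å and is exactly rigid-motion
  equivariant.
* `glycine_cb_template(s)` renames every residue to glycine and reduces it
  to backbone + C&beta;, erasing amino-acid identity while keeping geometry.
* `filter_template_hits()` keeps homology hits with identity inside
  [30, 70]% and query coverage `(qend - qstart + 1)/qlen >= 0.8`, then one
  best-e-value hit per query (ties: higher identity, then target id).
  Query coverage is used because a template must cover the modeling target;
  the thresholds are arguments, not constants.

Diffusion-based partial denoising is an external GPU tool; only the
predictor adapter contract acknowledges it.

## Sequence alignment

When reference and model sequences differ, residues are paired by global
Needleman–Wunsch alignment under BLOSUM62 with affine gaps (open 10,
extend 0.5 — "default" parameters differ between tools, so these widely
used values are exposed as arguments). `'X'` scores 0 against everything.
The implementation delegates to `Biostrings::pairwiseAlignment()`; the test
suite checks the score against an independent full-matrix Gotoh dynamic
program with identical parameters.

## The synthetic generator

`make_backbone()` extends an N-CA-C-O chain by internal coordinates with
ideal bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 Å) and
angles; presets fix the torsions (helix: &phi; = -57, &psi; = -47; strand:
&phi; = -120, &psi; = +120; omega = 180 throughout) or sample them from
allowed basins (`coil`, `mixed`). The default sequence cycles through all
20 amino acids so every residue type's &chi; conventions are exercised.

`attach_sidechains()` builds full heavy-atom side chains from an ideal
internal-coordinate table (documented constants in the source) at the
&chi; angles dictated by the rotamer mode. `ideal_single` uses one fixed
&chi; set per residue type — the values were calibrated once so that the
helix and strand fixtures are free of severe overlaps, and are constants
thereafter. Proline gets a tighter N-CA-C&beta; angle (101 degrees) and
ring-closing &chi; values (36, -2); its ring closes exactly only near
helix-like &phi;, which is where real proline lives anyway.

`make_globule()` grows a self-avoiding backbone in torsion space inside a
soft harmonic confinement sphere. Because the next C&alpha; depends only on
&psi; while &phi; bends the chain one residue later, the confinement energy
looks two steps ahead. Per-candidate clearance floors are 3.55 Å for
C&alpha;–C&alpha; (non-adjacent), 2.2 Å for backbone N/CA/C, and 1.7 Å for
O and C&beta; (which only need severe-overlap clearance). After growth,
ideal side chains are attached and residual overlaps are resolved by
greedily re-picking &chi; angles (truncation to C&beta; is the last
resort). An internal gate regrows with an adjusted confinement radius if
the realized C&alpha; radius of gyration leaves the
$2.2\,L^{1/3}$ Å &plusmn; 25% band, so the generator meets its stated
compactness contract deterministically in `(length, seed)`.

**What the generator does and does not emulate.** The fixtures have exact
ideal covalent geometry, protein-like compactness and density, and full
side chains — enough for superposition metrics, lDDT, &chi; statistics and
burial stratification to behave as on real folds. They do **not** have
native-like packing energetics, hydrogen bonding, Ramachandran statistics
beyond the sampled basins, or real secondary-structure topology. Passing
tests therefore demonstrate the correctness and calibration of the
*metrics and perturbations*, not biological realism of the chains. The
free-torsion `coil`/`mixed` presets are torsion chains, not self-avoiding
walks; only `make_globule()` and the regular presets guarantee a clean
stereochemistry report.

## Numerical choices

* Torsions follow the IUPAC sign convention; dihedrals of collinear
  quadruples are undefined and truncate &chi; lists.
* PCA eigenvector signs: largest-magnitude component positive; eigenvalue
  ties broken by original axis order.
* The TM search cutoff is $\max(d_0, 2)$ Å with +0.5 Å relaxation whenever
  fewer than 3 pairs qualify; 20 refinement iterations; Nelder–Mead polish
  with relative tolerance 1e-10.
* Altloc ties resolve to the lexicographically first identifier; occupancy
  wins first.
* Random draws always flow through a single seeded generator; pipeline runs
  derive every seed from the config seed and the target/perturbation
  indices, so reports are bitwise repeatable.

## Problem sizes in the shipped checks

The packaged checks run the Gaussian-noise lDDT signature on twenty
150–300-residue all-atom chains and the TM signature on eight to twenty
globules of 100–400 residues; these sizes were chosen as the smallest at
which the mean estimates stabilize well inside the tolerance bands (the
lDDT estimator's spread across structures is below 0.01 at these sizes).

## Known limitations

* Single-conformer, heavy-atom-only model; no hydrogens, no ligands or
  nucleic acids, first model only from multi-model files.
* Multi-chain structures are evaluated over concatenated chain order; the
  mapping machinery does not align chains independently.
* The burial proxy is a neighbor count, not SASA.
* The rectification rule inside the C&alpha;-RMSD (cap location and value)
  is a package convention exposed as a flag; published implementations
  differ in this detail.
* mmCIF output writes a single canonical `atom_site` loop; exotic dialect
  features (multiple data blocks, anisotropic records) are not produced.
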