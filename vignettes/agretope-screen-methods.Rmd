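---
title: "Methods: empirical scoring and two-stage agretope screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical scoring and two-stage agretope screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model, the numerical choices, and the limits of
what a green test establishes. It states no empirical result that the test
suite does not itself compute.

## The problem and the model

A peptide bound in an MHC class II groove can often be replaced by a
higher-affinity analogue without changing the positions that face the T-cell
receptor. Given the bound complex, the package screens substitutions on a
rigid scaffold: the template's side chains are removed (poly-Gly scaffold,
main chain preserved bit-exactly), candidate side chains are rebuilt on the
fixed backbone, and each candidate complex is scored with a five-term
empirical binding free energy

$$\Delta G_{bind} = \Delta G_0 + \Delta G_{polar} + \Delta G_{apolar} +
\Delta G_{solv} + \Delta G_{flexi}.$$

All energies are kcal/mol. The affinity score is
$-100\,\Delta G/(\ln 10 \cdot R T) = -100\log_{10} K_i$ with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; at 298 K the
coefficient is 73.337. The conventional printed value 73.33 arises from
the textbook truncation $\ln 10 \approx 2.303$; we keep exact constants and
treat the printed value as correct to its two printed decimals. The two
historical conversion formulas (score $\propto -\Delta G$ and
score $= 100\log K_i$) are mutually sign-inconsistent for sub-molar $K_i$;
the package uses the self-consistent convention score $= -100\log_{10}K_i$
(higher score = tighter binding) and documents, rather than resolves, the
discrepancy.

## Terms, parameters, defaults

The term weights are LUDI-style literature values; the source screen named
the five terms but printed no weights, so every number below is
configuration (`score_model()`), not a constant.

| parameter | default | units | role |
|---|---|---|---|
| `dG0` | +1.29 | kcal/mol | constant offset |
| `w_hbond` | −1.12 | kcal/mol per ideal H-bond | polar |
| `w_ionic` | −1.98 | kcal/mol per ideal ionic pair | polar |
| `w_lipo` | −0.0406 | kcal/mol per Å² | lipophilic contact area |
| `w_aromatic` | −0.17 | kcal/mol per ring pair | stacked rings < 5 Å |
| `w_solv` | +0.01 | kcal/mol per Å² | buried uncompensated polar area |
| `w_rot` | +0.335 | kcal/mol per rotatable bond | side-chain entropy |
| `R_ideal` | 2.9 | Å | ideal donor–acceptor distance |
| `dR_tol`, `dR_max` | 0.2, 0.6 | Å | distance penalty knots |
| `dA_tol`, `dA_max` | 30, 80 | deg | donor-angle penalty knots |
| `probe` | 1.4 | Å | rolling-probe radius |
| `temperature` | 298 | K | conversion |

Geometry factors are piecewise linear: full weight within the tolerance
knot, falling linearly to zero at the outer knot. Ionic pairs are scored on
distance only. Hydrogen positions are never stored; the donor angle is
measured at the idealized polar-hydrogen position, i.e. as the deviation of
the antecedent–donor–acceptor angle from the donor's ideal value (109.5°
sp³, 120–126° sp²). Probe pseudo-atoms without an antecedent are treated as
orientationally ideal.

Surface areas use the Shrake–Rupley rolling-probe method on a deterministic
golden-spiral point set (240 points/atom). Because the point set is fixed
in space, areas are evaluated in a canonical body frame anchored on the
first peptide residue's backbone; this makes every term rigid-body
invariant to better than $10^{-6}$ kcal/mol, which the suite asserts. The
desolvation term charges only peptide polar atoms that are buried *and*
uncompensated: any atom participating in a polar contact with $f > 0$ is
exempt, a declared stand-in for the unpublished desolvation functional of
the historical scorer.

## Side-chain building and clash rules

Side chains are rebuilt by NeRF forward kinematics from a fixed
ideal-geometry table (Engh–Huber-like bond lengths and angles), with the
L-configuration improper dihedral C–N–CA–CB = −122.6° (IUPAC sign, the
convention verified against deposited structures). Rotamers come from a
backbone-independent grid χ ∈ {−60°, +60°, 180°} per dihedral (so a 4-χ
residue has 81 rotamers). There is no continuous optimization and no
backbone relaxation; determinism is a design goal, and placement is
bit-reproducible.

A placement is rejected when a side-chain atom comes closer than (vdW sum −
0.4 Å) to any receptor atom or other-residue peptide atom. Two refinements:
the CB's covalently constrained 1–4 partners (previous C, next N) are
exempt, and pairs capable of hydrogen bonding (donor/acceptor, or opposite
formal charges) use a fixed contact sum of 2.5 Å instead of the vdW sum —
H-bonded heavy atoms legitimately sit at 2.6–3.0 Å, inside vdW contact, and
without this exemption an ideal hydrogen bond would be only 0.23 Å away
from being scored as a clash. Proline is excluded from the substitution
alphabet (backbone incompatibility on a fixed scaffold) and cysteine by
default (disulfide ambiguity); both can be re-added.

## The two-stage screen

Stage 1 scores each alphabet residue at each unfrozen position, one at a
time, in the all-Gly context (inter-substitution coupling therefore only
enters in stage 2, which matches the published description of the original
screen). Residues strictly above the Gly baseline form the candidate
lists. Positions with no pocket site within 8 Å of their backbone are
frozen by default — 8 Å rather than the 4.5 Å pocket cutoff because the
peptide enters the scan as bare backbone and its side chains reach several
Å further.

The "manual selection" of the original workflow is replaced by a
declarative rule: per-position top-k above the *original* residue, plus the
original itself, plus forced extras (e.g. Gly at positions whose candidate
list is empty). The packaged fixture reproduces the published starred
selection exactly (set sizes 1,1,1,4,3,3,2,3,2,2,2,2,1,1; product 3456).

Stage 2 enumerates the full cross product. Rotamers are placed greedily per
position in left-to-right order: the best-scoring receptor-feasible rotamer
(cached from single-substitution scoring) that does not clash with earlier
placements. A full combinatorial rotamer search would be exponential and
the published method does not specify one; the independent brute-force
oracle in the test suite implements the same declared rule through a
different code path, so the equality test checks the bookkeeping, not the
rule choice. Two documented edge rules keep enumeration total: a residue
with no receptor-feasible rotamer keeps its identity (and rotatable-bond
penalty) on a bare backbone, and if every rotamer clashes with earlier
placements the best receptor-feasible one is used regardless. Ties in the
ranking break lexicographically on the one-letter sequence, making the
output invariant to candidate-set insertion order.

An exact shortcut makes large scans affordable: a side chain more than 8 Å
from every receptor atom cannot change any interaction term (no polar pair
within reach, no shared occlusion of surface points), so its score is the
scaffold's plus its rotatable-bond penalty. The shortcut is
bit-identical to the full computation — the oracle-equality suite would
fail otherwise — and prunes most rotamers at weakly coupled positions.

## The synthetic generator: what it emulates and what it does not

`make_toy_complex()` builds an ideal extended backbone (φ = −139°,
ψ = +135°) and a receptor made of disconnected single-site pseudo-residues:
donor (DNR), acceptor (ACC), charged (CAT/ANI), lipophilic (LIP), aromatic
ring (ARO) probes and inert blockers (BLK). For each planted position it

1. picks a clash-free anchor rotamer of the intended residue (seeded),
2. plants up to three complementary probes at exactly ideal geometry
   (distance `R_ideal`, ideal donor angle) for the anchor's key atom, or a
   van-der-Waals-contact lipophilic cage around its terminal atoms, and
3. runs an adversary sweep: every other alphabet residue's grid rotamers
   are scored against the planted probes — optimistically (distances padded
   by 0.6 Å, angles ideal, lipophilic contact credited generously) — and
   compared with a pessimistic estimate of the intended residue's benefit
   (interaction part discounted to 65%); any competitor within the margin
   is sterically excluded by an inert blocker placed ≥ 4.2 Å from every
   protected atom (backbone, anchors).

Gaussian jitter (σ per spec) is applied to the pocket atoms last, so the
same seed yields the same anchors and probes at every noise level. The
asymmetric optimistic/pessimistic sweep and the blocker standoff are sized
against that jitter: probes must survive a 0.3 Å perturbation without either
losing the planted interaction or drifting into clash range of the anchor.

Limits, stated plainly: the generator does **not** mimic real MHC-II groove
geometry, solvent, or a folded receptor, and uniqueness of the planted
optimum is only guaranteed for intended residues without a *chemical
near-twin*. Twins (Ser/Thr, Val/Ile, His against Trp's ring nitrogen,
Arg against Lys) reach the planted site through atoms that coincide with
the protected anchor footprint, where no blocker can be placed; which twin
wins under jitter is then decided by sub-0.1 kcal/mol surface-area
minutiae. The recovery suites therefore plant winners from the twin-free
pool {Asp, Asn, Tyr, Lys, Leu, Phe}. A green recovery test establishes
that the pipeline finds a planted, steric-and-chemistry-unique optimum —
not that the score function would rank real MHC binders correctly.

## Numerical and degenerate-input choices

* Scores are compared exactly; ranking ties break lexicographically, and
  rotamer-score ties break on the lower rotamer index (stable).
* Coordinates round-trip through PDB at 3 decimals; chemistry flags are
  re-derived from residue codes on read, so round-trips are lossless for
  everything the model consumes.
* Empty pockets warn and return empty results rather than erroring;
  `peptide_position_contacts()` with cutoff 0 returns an empty set.
* Altloc conformers collapse to the highest-occupancy copy; waters,
  heteroatoms and hydrogens are dropped on read.
* The enumeration cap (default $10^6$) fails loudly with advice to tighten
  the candidate sets; the published 73,728,000-member first-screen library
  is deliberately far above it.

## Known limitations

* Absolute scores are not comparable to the historical proprietary scorer;
  only combinatorics, conversions and qualitative behaviour are.
* Stage-1 scoring in the all-Gly context ignores substitution coupling by
  construction (as the original screen did).
* The greedy per-position rotamer rule can miss jointly feasible rotamer
  combinations that a cross-positional search would find.
* The desolvation proxy (buried uncompensated polar area) is a declared
  stand-in; no electrostatics beyond the ionic pair term, no entropy beyond
  the rotatable-bond count.
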