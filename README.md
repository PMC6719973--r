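# agrescreen

In-silico positional-scanning design of MHC class II binding peptides
(agretopes) on a rigid peptide–receptor complex, with an empirical
LUDI-style binding free-energy score and exhaustive combinatorial ranking.

## Who this is for

Immunologists and structural bioinformaticians who want to redesign a
receptor-bound template peptide — e.g. a 14-mer antigen fragment sitting in
an MHC class II groove — so that it binds the groove more tightly, using
nothing but the complex structure and a desk-scale amount of compute. The
package reimplements the classic two-stage screen as tested, scriptable
code: no proprietary modelling suite required.

## The method

Starting from a peptide–receptor complex (PDB), the bound peptide is
reduced to a poly-glycine scaffold: every side chain is removed while the
main-chain 3D structure is preserved exactly. Candidate side chains are
then rebuilt on the fixed backbone from ideal internal geometry over a
discrete rotamer grid (χ ∈ {−60°, +60°, 180°} per dihedral) and scored
against the receptor with a five-term empirical binding free energy

```
ΔG_bind = ΔG_0 + ΔG_polar + ΔG_apolar + ΔG_solv + ΔG_flexi   [kcal/mol]
```

where ΔG_polar rewards hydrogen bonds and ionic pairs with a
piecewise-linear distance/angle penalty, ΔG_apolar rewards lipophilic
contact area and stacked aromatic rings, ΔG_solv penalises buried polar
surface without a compensating hydrogen-bond partner, and ΔG_flexi
penalises side-chain rotatable bonds. The free energy converts to a
dimensionless affinity score

```
score = −100 ΔG / (ln 10 · R T) = −100 log10(Ki)
```

(≈ −73.33·ΔG at 298 K), so higher scores mean tighter predicted binding.

The screen then runs in two stages:

1. **Positional scan** — each position of the scaffold is substituted, one
   at a time, by every residue of an 18-letter alphabet (no Pro/Cys); the
   best feasible rotamer is kept and residues scoring strictly above the
   Gly baseline form per-position candidate lists. Positions not in
   contact with the receptor stay frozen at the original residue.
2. **Exhaustive enumeration** — a declarative selection rule (top-k above
   the original residue, forced inclusions, frozen ends) defines
   per-position candidate sets whose cross product is enumerated in full,
   scored and ranked.

A seeded synthetic-complex generator plants interaction sites at
analytically ideal geometry for a chosen optimal sequence (and sterically
excludes competitors), so the whole pipeline is testable against known
ground truth with no downloads.

## Worked example

The packaged fixture is a synthetic receptor pocket built around the
classic 14-mer ovalbumin template RGISQAVHAAHAEI, engineered so that the
published top design RGIFFYVFAAYKEI is the true optimum. The packaged
candidate sets reproduce the published first-screen selection (library
size 1·1·1·4·3·3·2·3·2·2·2·2·1·1 = 3456):

```r
library(agrescreen)
cplx <- read_pdb(system.file("extdata", "synthetic_ova_iad_complex.pdb",
                             package = "agrescreen"), peptide_chain = "P")
sets <- fixture_candidate_sets()
library_size(sets)
#> [1] 3456
res <- stage2_enumerate(cplx, sets)
top_peptides(res, 5)
#>   rank       sequence    score hamming
#> 1    1 RGIFFYVFAAYKEI 806.5739       6
#> 2    2 RGIFFYVFAGYKEI 732.0429       7
#> 3    3 RGIFFYVFGAYKEI 723.5560       7
#> 4    4 RGIIFYVFAAYKEI 713.5459       6
#> 5    5 RGIFFYTFAAYKEI 707.2962       7
res$original_rank
#> [1] 3030
```

Rank 1 recovers the planted optimum, six mutations away from the template
(`hamming = 6`), and the original sequence ranks deep in the 3456-member
library — the qualitative signature of the original screen, in which the
template ranked 3362nd of 3456. (Absolute scores are this package's own
five-term model; the historical screen used a proprietary scorer whose
values are not reproducible.)

The same pipeline is scriptable from the shell:

```sh
inst/scripts/screen size --counts 5,6,8,5,4,4,3,8,1,1,8,2,5,2   # 73728000
inst/scripts/screen run --pdb complex.pdb --peptide-chain P --out results/
inst/scripts/screen synth --spec spec.json --seed 7 --out toy.pdb
```

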