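# nanopep

Design and dosimetry toolkit for peptide–gold-nanoparticle (p-AuNP)
nanovaccine candidates.

Epitope-based vaccines deliver short T-cell epitopes on a nanocarrier to
overcome the poor immunogenicity of free synthetic peptides. A common design
conjugates modular peptides to spherical gold nanoparticles (AuNPs): a CALNN
pentapeptide anchors the construct to the gold surface through its cysteine
thiol, a spacer (the dibasic cathepsin-B target KK, or the flexible GPGPG
linker) separates the anchor from a CD4+ T-cell epitope, and an optional
arginine-rich TAT-derived cell-penetrating peptide caps the C-terminus.
`nanopep` implements the computational side of designing and analysing such
conjugates, for vaccinologists and nanomaterials researchers:

- **Construct modelling** — parse one-letter sequences into annotated
  anchor/spacer/epitope/CPP regions (greedy, priority-ordered motif
  matching) and count their charges under an explicit convention
  (K + R side chains + one N-terminal amine; amidated C-terminus by
  default).
- **Cleavage-site prediction** — score every scissile bond with an
  eight-subsite (P4…P4′) protease specificity matrix via a sliding window:
  the score of the bond between residues *p* and *p*+1 is
  Σⱼ M[subsiteⱼ, residue at p−4+j], ranked descending with position
  tie-breaks. Top-*k* cuts (default *k* = 3) are applied one at a time to
  the intact parent (single-cut model), yielding a fragment set and an
  epitope-release flag. A synthetic cathepsin-B-like matrix is bundled.
- **Nanoparticle dosimetry** — sphere geometry (V = πd³/6, A = πd²), gold
  atoms per particle from bulk density, the size-dependent extinction
  coefficient ln ε = a + k ln d (Liu et al. 2007 calibration),
  Beer–Lambert concentrations, and conjugation recipes that hold the
  peptide surface density constant across particle sizes.
- **Population coverage** — diploid Hardy–Weinberg phenotypic coverage
  1 − Π(1 − p_locus)² from MHC allele-frequency tables and a set of
  predicted binding alleles.
- **Assay statistics** — percent-of-control normalization, four-parameter
  logistic dose–response fits r(d) = lower + (upper − lower)/(1 + (d/IC₅₀)^h)
  with curvature standard errors, survival-normalized enzymatic activity
  (raw / survival fraction), and zeta-potential-binned activity summaries
  with OLS.
- **Synthetic data** — seeded generators for every input above (constructs
  with planted region truth, specificity matrices with a planted dibasic
  preference, 4PL plates, Dirichlet allele tables), so the whole pipeline
  runs and tests offline.

## Worked example

```r
library(nanopep)

p2 <- parse_construct("p2", "CALNNKKPKYVKQNTLKLATRKKRQRRR")
p2$regions
#> # A tibble: 4 × 4
#>   kind    start   end motif
#> 1 anchor      1     5 CALNN
#> 2 spacer      6     7 KK
#> 3 epitope     8    20 PKYVKQNTLKLAT
#> 4 cpp        21    28 RKKRQRRR

charge_summary(p2)[, c("n_lys", "n_arg", "n_positive")]
#> # A tibble: 1 × 3
#>   n_lys n_arg n_positive
#> 1     7     5         13
```

Seven lysines and five arginines plus the free N-terminal amine give p2 its
13 positive charges — the composition behind the strongly positive zeta
potential of p2-coated particles.

```r
predict_cleavage(p2, cathepsin_b_matrix(), k = 3, core = "YVKQNTLKL")
#> <cleavage_report> p2 (28 aa), 3 selected site(s)
#> epitope core YVKQNTLKL released: TRUE
#> # A tibble: 6 × 5
#>   fragment            start   end  bond side
#> 1 CALNNKKPK               1     9     9 N
#> 2 YVKQNTLKLATRKKRQRRR    10    28     9 C
#> 3 CALNNKKPKYVKQNT         1    15    15 N
#> 4 LKLATRKKRQRRR          16    28    15 C
#> 5 CALNNKKPKYVKQNTLK       1    17    17 N
#> 6 LATRKKRQRRR            18    28    17 C
```

The top-ranked cut (bond 9) separates the anchor-spacer module from the
epitope; at least one fragment carries the nonameric binding core, so
endosomal processing is predicted to release the epitope for MHC class II
loading.

```r
au <- sphere_quantities(c(23, 68))
au[, c("label", "volume_nm3", "surface_area_nm2", "atoms_per_particle")]
#> # A tibble: 2 × 4
#>   label volume_nm3 surface_area_nm2 atoms_per_particle
#> 1 Au23       6371.            1662.            375916.
#> 2 Au68     164636.           14527.           9714792.

conjugation_recipe(0.054, 2, 0.75, au[2, ], reference_np = au[1, ],
                   peptide_stock_mM = 30)
#> # A tibble: 1 × 12
#>   label coverage area_scale molar_ratio surface_density_printed peptide_volume_uL
#> 1 Au68      0.75       8.74     655577. 0.22                                 2.36
```

A 68-nm particle has ~26× the volume and gold content and ~8.7× the surface
area of a 23-nm particle, so holding the peptide *surface density* equal
(coverage 0.75 ≙ 0.22 nmol-peptide/nm²) requires scaling the per-particle
molar ratio by the area ratio: 2.36 µL of 30 mM peptide stock for 2 mL of
0.054 nM particles.

## Notes

- The bundled specificity matrix is a synthetic cathepsin-B-like table (see
  its provenance string), not a database export; cleavage predictions with
  it are illustrative of the method, and any eight-subsite matrix can be
  supplied via `read_specificity_matrix()`.
- A thin command-line wrapper over the same functions is installed at
  `inst/scripts/nanopep-cli.R` (subcommands `annotate`, `cleave`,
  `conjugate`, `coverage`, `synth`).
- The methods vignette (`vignettes/nanopep-methods.Rmd`) documents the
  models, conventions, numerical choices and limitations.
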