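---
title: "Models and methods behind nanopep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanopep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopep)
```

`nanopep` covers the computational workflow around peptide–gold-nanoparticle
(p-AuNP) vaccine candidates: modular construct modelling, protease
cleavage-site scanning, nanoparticle dosimetry, MHC population coverage, and
assay post-processing. This vignette records the models, the conventions and
parameter defaults, the numerical choices, and what the bundled synthetic
data can and cannot tell you.

## Modular constructs and the charge convention

A construct is a plain one-letter sequence over the 20 standard amino acids
(anything else — B, J, O, U, X, Z — is rejected with the offending position
named, and input is upper-cased). Annotation is a greedy left-to-right scan
against a priority-ordered motif library: at each position the first library
motif that matches is claimed, the scan resumes after it, and unmatched
stretches stay unannotated. This deliberately simple grammar is
deterministic, never errors on "overlapping" motif claims (priority decides),
and reproduces the intended layout of anchor + spacer + epitope + optional
cell-penetrating tail for the classic CALNN / KK / GPGPG / HA306–318 / TAT
building blocks in `default_motif_library()`.

Charge counting uses one explicit convention, exposed as flags:

* `n_positive = n_lys + n_arg + 1` (the free N-terminal amine). Histidine is
  excluded by default — it is mostly uncharged at neutral pH — but
  `include_histidine = TRUE` adds it. This is the only convention under
  which a construct with five arginines and seven lysines carries 13
  positive charges, which is how such peptides are usually described in the
  conjugation literature.
* `n_negative = n_asp + n_glu`, plus one for the free C-terminal carboxylate
  only when `c_terminal_amide = FALSE`. Constructs assembled on Rink amide
  resin are amidated, so the default is `TRUE`.

No pKa model or hydrophobicity scale is applied; these are integer counts,
not a net-charge prediction at a given pH.

## Sliding-window cleavage scoring

Protease preferences are encoded as an 8 × 20 table over the subsites
P4…P1, P1′…P4′ flanking the scissile bond (cleavage between P1 and P1′).
For a sequence of length $L$, the bond between residues $p$ and $p+1$ is
scored by aligning residues $p-3 \dots p+4$ to the subsites and summing the
eight cell scores. Choices worth stating:

* **Window boundary.** Only fully interior windows are scored, i.e. bonds
  $4 \le p \le L-4$; no padding is invented for termini. Every cut the
  package is validated against lies in this interior range.
* **No transform.** Scores are summed exactly as given. If a matrix needs a
  log-odds or background correction, that belongs in matrix preparation and
  should be recorded in the matrix's `provenance` string.
* **Ranking and ties.** Sites are ranked by descending score; exact ties
  break by ascending bond position, making ranks deterministic.
* **Top-k selection.** `k = 3` by default: three cuts applied independently
  to the intact parent yield six fragments (minus duplicates), the shape in
  which putative digestion products of such constructs are usually tabled.
* **Single-cut fragmentation.** Each selected bond is applied to the intact
  parent, giving the N-side fragment `1..p` and C-side fragment `p+1..L`;
  fragments are listed per site in rank order, N-side first, deduplicated by
  sequence keeping the first occurrence. An exhaustive multi-cut digest is a
  different model (combinatorially many products) and is intentionally not
  the default; the single-cut model is the one that matches how top-ranked
  sites are reported and interpreted for these constructs.
* **Region overlap rule.** `motif_preference_report()` associates bond $p$
  with region $[s, e]$ when $s - 1 \le p \le e$, so a cut at either boundary
  counts as touching the region — a bond "between the spacer and the
  epitope" belongs to both.

### The bundled matrix is synthetic

`cathepsin_b_matrix()` loads a synthetic cathepsin-B-like table, not a
database export. It encodes the protease's hallmark preferences — dibasic
K/R acceptance at P1/P2, glycine/proline tolerance around the bond — and was
calibrated once, by linear programming against the published single-cut
fragment sets of the four study constructs (p1–p4), minimising the L1
distance from a chemically motivated base table subject to those ranking
constraints with a fixed score margin of 0.25. Its provenance string says
exactly this. Consequences: predictions made with it on *other* sequences
are illustrative of the method, not of cathepsin B; any real eight-subsite
matrix can be supplied through `read_specificity_matrix()`, whose TSV
dialect (a `subsite` column with rows P4…P4′, then twenty residue columns)
is validated cell by cell.

## Nanoparticle dosimetry

Particles are treated as ideal spheres of bulk gold: volume $\pi d^3/6$,
surface area $\pi d^2$, and atoms per particle
$\rho N_A V / M$ with $\rho = 19.3$ g/cm³ and $M = 196.97$ g/mol kept in one
constants table (`gold_constants()`). For the nominal 23 nm and 68 nm sizes
this gives volume and gold-content ratios that round to 26 and an area ratio
that rounds to 9; with TEM-mean diameters (23.4, 68.2 nm) the rounded ratios
become 25 and 8 — both modes are available, and the nominal diameters are
the defaults for cross-size comparisons.

The extinction coefficient uses the log-log calibration
$\ln \varepsilon = a + k \ln d$ with the Liu et al. (2007) constants
($k = 3.32111$, $a = 10.80505$) for citrate-capped spherical AuNPs; the
constants live in `liu_calibration()` with provenance, not in code, because
different capping chemistries need different calibrations. Concentrations
follow Beer–Lambert, $c = A/(\varepsilon \ell)$, with a 0.3 cm default path
(a 100 µL well in a 96-well plate).

Conjugation planning is anchored at a reference molar ratio of 1:100,000
peptides per particle ≙ coverage 1.00 ≙ 0.3 nmol-peptide/nm² on the
reference 23 nm particle. Two things deserve honesty:

* The density unit is implemented verbatim as a bookkeeping scale linear in
  the molar ratio (0.75 → 0.225, 1.25 → 0.375). Taken literally,
  nmol-peptide/nm² is physically implausible (it would be ~10⁵ peptides per
  Å²); the package treats it as the conventional label it is, anchored at
  the reference point, and does not convert it to molecules/nm².
* Report formatting *truncates* to two decimals (`format_surface_density()`:
  0.225 → "0.22", 0.375 → "0.37") because that is how the series is
  conventionally printed; truncation and rounding differ at exactly these
  values.

`conjugation_recipe()` computes, from first principles, peptide moles
= particle concentration × volume × per-particle ratio, and the stock volume
to pipette. With `normalize_by_area = TRUE` (default) the per-particle ratio
scales by the particle's surface area relative to the reference particle, so
the surface *density* — not the per-particle count — is held equal across
sizes; this reading follows from the stated goal of equal peptide surface
densities when both sizes are functionalized, but because the ratio labels
could also be read as per-particle numbers, the non-normalized mode is one
flag away. Published mixing-volume ranges for such protocols cannot be fully
reconciled with printed concentrations under either mode without the
original worked examples, so the function exposes every intermediate
quantity for audit rather than matching any single printed volume.

## Population coverage

Coverage of an epitope given a set of binding alleles is the standard
diploid Hardy–Weinberg phenotypic formula: with $p$ the summed frequency of
covered alleles at a locus, per-locus coverage is $1-(1-p)^2$, and loci
combine independently as $1 - \prod_\ell (1-p_\ell)^2$. Assumptions worth
noting: Hardy–Weinberg proportions, independence across loci (no linkage
disequilibrium — conservative for tightly linked class II loci), and
frequency shortfall (per-locus sum < 1, untyped alleles) counted as
*uncovered* mass unless `renormalize = TRUE`. Binding sets are inputs: the
package predicts no MHC binding itself, so coverage figures that depend on a
particular binding predictor and population extract are out of its scope.

## Assay statistics

* `percent_of_control()` — 100 × mean(values)/mean(control), with
  per-replicate percents for dispersion displays.
* `fit_4pl()` — least squares on
  $r(d) = \text{lower} + (\text{upper}-\text{lower})/(1+(d/\mathrm{IC}_{50})^{h})$
  via Levenberg–Marquardt (`minpack.lm`), with fixed, reproducible
  initialization: upper = max response, lower = min response, IC₅₀ = the
  positive dose whose response is nearest mid-range, hill = 1. IC₅₀ is
  bounded positive; standard errors come from the curvature at the optimum;
  a failed or non-converged fit returns `converged = FALSE` with the
  parameters as `NA` — never a silent number. At least four distinct
  positive doses are required. Both asymptotes are left free (4PL rather
  than 3PL) because neither 0% nor 100% plateaus can be assumed for
  viability readouts.
* `normalize_activity()` — activity per surviving cell fraction,
  raw / (survival%/100). The divisor is the *fraction*, not the percent:
  this is the reading that keeps values on the raw scale at full survival
  (150 AU stays 150 AU at 100% survival, doubles at 50%). Survival ≤ 0 is
  an explicit error; the alternative percent-scale reading would be a
  one-line change isolated in this function.
* `charge_activity_summary()` — per-bin mean ± sample SD over user-supplied
  zeta-potential bin edges (which must cover the data), plus an OLS line
  with slope, intercept and $r^2$; when all activities are equal the model
  explains nothing and $r^2$ is reported as 0 rather than `NaN`.

## The synthetic-data module

Every generator is a pure function of a `generator_config()`: the same
config reproduces byte-identical output (each generator draws from its own
fixed-offset stream, so adding one never perturbs another). What they
emulate, and what they do not:

* `make_peptides()` — constructs assembled as anchor + spacer (KK or GPGPG)
  + a random epitope-like core (9–15 residues by default) + an optional TAT
  tail, with the planted region truth emitted alongside. Real epitopes are
  not random sequences; these records exercise annotation and windowing,
  not immunology.
* `make_matrix()` — i.i.d. Normal(0, 1) background scores with a
  configurable `dibasic_bonus` added for K/R at P1/P2. As the bonus grows
  past the background SD, the bond following a planted KK becomes top-ranked
  with probability approaching 1 — the property the tests check — but the
  background has none of the residue correlations of a real substrate
  matrix.
* `make_dose_response()` — 4PL truth (default IC₅₀ 3308 pM, upper 100%,
  hill 1, spanning a 10–10⁵ pM grid, five replicates) plus additive Gaussian
  noise. The defaults mirror the working conditions of AuNP viability
  titrations: an IC₅₀ in the few-nM range inside the dose grid. Passing
  recovery tests on these plates shows the estimator is consistent under
  the model, not that any wet-lab IC₅₀ is correct; published IC₅₀ ± SE
  values are wet-lab estimates whose raw plates are unavailable, so they
  seed the truth values here and are never treated as reproducible targets.
* `make_allele_table()` — symmetric-Dirichlet frequencies per locus (via
  normalized Gamma draws) scaled to a typed mass of 0.95, mimicking the
  incomplete typing of real frequency extracts; valid by construction.

Problem sizes used by the default test run were chosen to exercise the
properties at comfortable Monte-Carlo resolution: 200–1000 random
(peptide, matrix) pairs for the scoring oracle, 200 peptides per planted-
preference check, a dozen simulated plates per noise level for IC₅₀
recovery, and 1000 random tables for coverage monotonicity.

## Known limitations

* Cleavage scoring is position-additive: no pairwise subsite coupling, no
  kinetics (kcat/Km), and no machine-learned signal. It ranks bonds; it
  does not predict rates.
* The bundled matrix is a calibrated synthetic stand-in (above); swap in a
  curated matrix for production use.
* Dosimetry assumes monodisperse ideal spheres of bulk gold; no colloidal
  stability, aggregation, or zeta-potential prediction.
* Coverage assumes Hardy–Weinberg and cross-locus independence, and is only
  as good as the supplied frequency table and binding set.
* Charge counting is integer bookkeeping at neutral pH, not electrostatics.
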