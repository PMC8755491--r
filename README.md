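# domainer

Topology-partitioned dN/dS estimation and expression–rate correlation
analysis for transmembrane proteins.

## The problem

Highly expressed genes tend to encode slowly evolving proteins — the
expression level–evolutionary rate (E–R) anticorrelation. The leading
explanations (translational robustness, misfolding avoidance, misinteraction
avoidance) all predict that the anticorrelation should be weaker for protein
regions that fold in the endoplasmic reticulum and act outside the cell.
Transmembrane proteins offer a within-protein test: their intracellular
loops fold and act in the cytosol, while their extracellular domains fold in
the ER lumen and act outside. `domainer` implements the full analysis needed
to run that test on a pair of genomes:

1. **Ortholog pairing** by reciprocal best hit over exhaustive affine-gap
   global protein alignments (BLOSUM62, gap open 11, extend 1).
2. **Codon alignment** by back-translating the protein alignment onto the
   CDS pair (residue gap ↔ codon gap `---`).
3. **Topology partitioning**: per-residue inside/TMhelix/outside labels
   (TMHMM-style segment files) are projected onto alignment columns; a
   column is assigned to a domain class only when both species agree, and a
   gene is retained only when both species have both an intracellular and an
   extracellular segment.
4. **Per-domain divergence**: dN, dS and ω = dN/dS estimated separately for
   the intracellular (ω_i), transmembrane (ω_t) and extracellular (ω_e)
   subalignments, by either Nei–Gojobori (1986) counting with Jukes–Cantor
   correction or maximum likelihood under the Goldman–Yang one-ratio (M0)
   codon model with F3x4 frequencies. Estimates with dS = 0 (infinite ω) are
   removed.
5. **Statistics**: Spearman correlations of each ω with protein or mRNA
   abundance; Fisher r-to-z comparison of two correlation coefficients,
   `Z = (atanh(ρ₁) − atanh(ρ₂)) / sqrt(1/(n₁−3) + 1/(n₂−3))`;
   exact binomial ordering tests (ω_e > ω_i against 1/2; ω_t below both
   against 1/3); abundance terciles; per-tissue sweeps with intermediacy
   counts.
6. **A ground-truth simulator**: ortholog codon pairs evolved under the same
   M0 model with domain-specific ω, plus gene abundances tied to each
   domain's ω through a Gaussian copula at a configurable Spearman
   correlation — so every stage can be validated against known truth.

Everything is tibble-in/tibble-out and pipes cleanly; `tidy()`/`glance()`
methods cover the M0 fit object, and `plot_domain_correlations()` /
`plot_tissue_sweep()` draw the standard figures.

## Worked example

A synthetic cohort of 500 single-pass transmembrane proteins (80 residues
inside, 21 in the membrane, 80 outside), human–mouse-like divergence
(t = 0.6 substitutions/codon), with the abundance–ω_i rank correlation set
to −0.3 and the abundance–ω_e correlation set to 0:

```r
library(domainer)

run_pipeline(list(
  mode     = "simulate",
  simulate = list(n_genes = 500, target_rho_i = -0.3, target_rho_e = 0,
                  n_tissues = 5),
  engine   = "ng86",
  outdir   = "demo_run",
  seed     = 1
))
```

`demo_run/summary.tsv` from this exact call:

```
type         label                  rho        n    p
correlation  omega_i vs abundance   -0.260548  500  3.34091e-9
correlation  omega_t vs abundance   -0.122872  488  0.00657443
correlation  omega_e vs abundance   0.018929   500  0.672849
comparison   omega_i vs omega_e     -4.502603  500  3.35631e-6
comparison   omega_i vs omega_t     -2.24357   500  0.01243
comparison   omega_t vs omega_e     -2.231437  488  0.0128261
```

Reading it: the intracellular domains show a clear E–R anticorrelation
(ρ = −0.26), the extracellular domains none (ρ = 0.02), and the
transmembrane domains sit in between (ρ = −0.12) — the `comparison` rows are
Fisher r-to-z tests of each pair of coefficients (for comparisons, the `rho`
column holds Z and `p` the one-tailed probability). The estimated
correlations are attenuated relative to the simulated −0.3 because ω is
estimated from ~80-codon subalignments. `orderings.tsv` shows ω_t was the
smallest of the three ω's in 304/488 genes (binomial P ≈ 5e-39 against 1/3),
and all five simulated tissues place ρ_t strictly between ρ_i and ρ_e
(`sweep.tsv`).

A shell front end wraps the same functions:

```sh
Rscript exec/domainer run --config config.yaml --outdir demo_run --seed 1
```

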