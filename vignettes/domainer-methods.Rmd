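---
title: "Models and methods behind domainer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind domainer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`domainer` asks whether the expression level–evolutionary rate (E–R)
anticorrelation differs between the intracellular, transmembrane and
extracellular portions of transmembrane proteins. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic-data validation does and does not establish.

## The divergence model

Both the simulator and the likelihood engine use the Goldman–Yang one-ratio
(M0) codon model on the 61 sense codons of the standard genetic code. The
instantaneous rate from codon $x$ to codon $y$ is zero if they differ at
more than one position and otherwise proportional to $\pi_y$, multiplied by
$\kappa$ for transitions and by $\omega$ for nonsynonymous changes. The
generator is scaled so one time unit equals one expected substitution per
codon, so the divergence $t$ is in substitutions per codon. An ortholog pair
is modelled as two lineages of length $t/2$ from a common ancestor; a
pairwise analysis can only estimate the total $t$, so the symmetric split is
a convention, not an assumption.

dN and dS are derived from a fitted (or simulating) generator in the PAML
convention: the expected substitution flux is split into synonymous and
nonsynonymous parts, and each is divided by the corresponding site
proportion computed from the same mutational process with $\omega = 1$.
Under this convention $dN/dS$ equals the model's $\omega$ identically, which
makes estimator-recovery tests sharp.

### The M0 fit

`m0_fit()` maximises $\sum_{\text{sites}} \log(\pi_x P_{xy}(t))$ over
$(t, \kappa, \omega)$ with L-BFGS-B on log-parameters, box constraints
$t \in [10^{-6}, 50]$, $\kappa \in [0.01, 99]$, $\omega \in [10^{-4}, 99]$
(PAML-like bounds that keep the optimiser away from boundary pathologies),
and a three-point multistart $\omega_0 \in \{0.1, 0.5, 2\}$ because
low-divergence pairwise likelihoods are occasionally multimodal; ties in
log-likelihood resolve to the smallest $\omega$. Codon frequencies default
to F3x4 estimated jointly from both sequences; a uniform option exists for
closed-form checks. F3x4 frequencies are floored at $10^{-6}$ (then
renormalised) so the chain stays irreducible when a nucleotide is unobserved
at a codon position — relevant for short subalignments. Transition matrices
are computed by symmetrising the reversible generator with
$D^{1/2} Q D^{-1/2}$ and taking a symmetric eigendecomposition. Alignments
with no variable sites return $t$ at its lower bound with the estimate
flagged invalid rather than an arbitrary $\omega$.

### The NG86 engine

The counting engine follows Nei–Gojobori (1986): each of a codon's nine
single-nucleotide neighbours contributes one third of a site to the
synonymous or nonsynonymous class, with stop-codon neighbours excluded
entirely; observed differences at codons differing in 2–3 positions are
averaged with equal weight over the minimal substitution paths that avoid
stop codons (over all paths in the rare case every ordering passes through a
stop); proportions are corrected with the Jukes–Cantor transform
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$. Codon columns containing a gap,
an ambiguity character or a stop are skipped pairwise rather than imputed.
NG86 is the default pipeline engine: at cohort scale it is orders of
magnitude faster than M0 and its $\omega$ ranks agree with M0's (Spearman
$> 0.9$ in the engine-consistency test), which is what rank-based E–R
statistics need.

### dS = 0 filtering

Genes with $d_S = 0$ have an undefined or infinite $\omega$ and are
removed. Whether the removal is per subalignment or per gene is genuinely
ambiguous in this analysis tradition, so both scopes are implemented:
`"per-domain"` (default) drops only the affected domain's estimate,
`"whole-gene"` drops the gene everywhere once any domain that has codons
fails. Domains with zero codon columns are treated as unused and do not
penalise the gene under either scope.

## Alignment and partitioning

Ortholog identification uses reciprocal best hits over exhaustive
Needleman–Wunsch affine-gap alignments (BLOSUM62, gap open 11, extend 1; a
gap of length $L$ costs $11 + L$). A deterministic aligner replaces
probabilistic consistency aligners deliberately: at desk scale exhaustive
scoring is feasible, E-values are database-size-dependent and hence
irreproducible, and closely related orthologs are insensitive to the
aligner. A minimum-score floor (default 50) stands in for the E-value
screen. Score ties exclude the pair, which also resolves recent duplicates
conservatively. CDS with internal stop codons indicate annotation errors
and are dropped with a warning.

Topology comes in as TMHMM-style segment files (1-based inclusive
coordinates at the boundary; all internal column indices are 0-based
half-open) or as per-residue `i`/`M`/`o` strings. The per-residue labels of
each species are projected onto its gapped alignment row; a codon column
joins the intracellular/transmembrane/extracellular sets only when both
species carry the same label there (`"concordant"` policy). How to treat
columns whose species labels disagree is not specified in this analysis
tradition; dropping them is conservative and species-symmetric, and a
`"reference"` policy (use species A's label) is provided for sensitivity
analysis. The retention rule — both domain kinds present in both species —
is applied before any estimation.

## The synthetic-data generator

The simulator is the package's ground truth and its defaults are the
validation conditions:

| parameter | default | meaning |
|---|---|---|
| `domain_architecture` | inside 80 aa, TMhelix 21 aa, outside 80 aa | a typical single-pass receptor-like topology; 21 residues is the canonical TM helix length |
| `t` | 0.6 subs/codon | human–mouse-like synonymous-site divergence |
| `kappa` | 2 | a typical mammalian transition/transversion rate ratio |
| `omega_i`, `omega_t`, `omega_e` | 0.15, 0.10, 0.25 | median purifying-selection strengths; membrane helices most constrained, extracellular loops least |
| `sigma_log_omega` | 0.6 | gene-level spread of log ω, matching the right-skewed ω distributions of real cohorts |
| `target_rho_i`, `target_rho_e` | −0.3, 0 | the E–R contrast under test |
| `target_rho_t` | midpoint of the two | emulates the observed intermediacy of transmembrane domains |
| `rho_omega` | 0.45 | rank correlation among a gene's domain ω's (observed 0.41–0.50) |
| `abundance_meanlog`, `abundance_sdlog` | 3, 2 | log-normal ppm-like abundances spanning ~4 orders of magnitude |

Gene-level ω's and log-abundance are drawn from a Gaussian copula; the
Pearson parameter for a requested Spearman correlation $\rho_S$ is
$r = 2\sin(\pi\rho_S/6)$, exact for the Gaussian copula and unchanged by
the monotone log-normal transforms applied afterwards. Requesting jointly
unattainable rank correlations fails the positive-definiteness check with a
hard error, as does $|\rho| = 1$ with nondegenerate ω noise. Ancestral
codons are i.i.d. uniform over the 61 sense codons, which keeps closed-form
expectations (for example the expected fraction of differing codon sites,
$1 - \sum_x \pi_x [e^{Qt}]_{xx}$) exactly checkable. Both species share one
topology; an explicit `n_missing_domain` toggle appends genes whose
species-B topology lacks extracellular segments, to exercise the retention
filter's failure path. Reproducibility uses one root seed with per-gene
substreams derived by integer hashing of (seed, gene index), so results do
not depend on iteration order.

What the simulator deliberately omits: indels (so real-alignment error is
not modelled), among-site rate variation beyond the three-domain partition,
codon-usage bias beyond the frequency vector, topology divergence between
species beyond the toggle, and abundance measurement error. Passing the
synthetic suites therefore demonstrates that the estimation and statistics
recover a known signal under the model's own assumptions — not that
TMHMM-style annotations or real alignments are error-free.

## The statistical layer

Spearman correlations use average ranks for ties and the t-approximation
with $n - 2$ degrees of freedom for two-tailed p-values (adequate at the
sample sizes involved). A gene enters a correlation only if that domain's
ω is valid and the abundance is present and positive; zero abundance is
treated as below detection rather than as a measurement. Two correlations
are compared with the independent-samples Fisher r-to-z statistic. Back-
calculation from published analyses of this design shows the one-tailed
probability $\Phi(Z)$ is the conventionally reported value, so both tails
are emitted with the one-tailed value flagged. The two coefficients in the
comparison share the abundance variable and are computed on overlapping
gene sets, which the independent-samples form ignores; a Steiger-type
overlapping-correlations variant is available (`overlap_r12`) but is not
the default, because the independent form is what this analysis tradition
reports. The practical consequence, visible in the null-calibration test,
is mild conservatism: with both rank-correlation targets at zero the
one-tailed test rejects at slightly under the nominal 5%.

Ordering statistics count strict inequalities (ties are failures):
ω_e > ω_i against a null of 1/2 (two-sided, minimum-likelihood convention)
and ω_t below both against 1/3 (upper tail), both with exact binomial
tails. Abundance terciles cut at ranks with a stable order for ties; when
$n$ is not divisible by 3 the extra genes go to the lowest bins first
(n = 10 gives 4/3/3). Multi-tissue abundances are averaged over the tissues
in which a gene is measured — missing tissues are dropped, not zero-filled —
and the per-tissue sweep records, for each tissue, the three correlations
and whether ρ_t lies strictly between ρ_i and ρ_e, with the intermediacy
count tested against 1/3. No multiple-testing correction is applied across
tissues, matching the presentation conventions of this analysis type.

## Pipeline mechanics

`run_pipeline()` executes simulate (or ingest) → align → partition → dnds →
correlate under one output directory. Each stage records a hash of its
parameters and upstream state in `manifest.tsv` plus an execution counter;
a stage re-runs only when its hash changes or an output is missing, and a
re-executed stage cascades downstream through the counter. Identical
configuration and seed give byte-identical TSV outputs. Per-stage gene
counts are logged (retention-filter drops, dS = 0 losses, abundance joins)
so the attrition from predicted proteins to correlated genes is auditable.

## Problem sizes used in validation

The validation suites run at sizes chosen to bound Monte-Carlo error while
staying desk-scale: copula calibration at 2,000 genes (Spearman sampling
error ≈ 0.022, tolerance ±0.05); M0 recovery with 50 replicates of
2,000-codon pairs at $(\omega, \kappa, t) = (0.2, 2, 0.4)$, median
$\hat\omega$ required in [0.16, 0.24]; power at 100 cohorts of 500 genes
with targets (−0.3, 0), requiring one-tailed rejection in ≥ 80% (observed
essentially always, since the expected Z is near −4); size at 200 null
cohorts, requiring the rejection rate within three binomial standard errors
of 5%; NG86 equivalence against an exhaustive path-enumeration oracle on 50
random 30-codon alignments.

## Known limitations

Pairwise (two-taxon) estimation only; no site-model heterogeneity (M1a/M2a
and relatives are out of scope); no codon-usage-corrected dS variants (LWL,
YN00); no phylogenetically independent contrasts or partial correlations
controlling for covariates; topology labels are taken at face value, with
no modelling of signal peptides or re-entrant loops. The NG86 engine's
Jukes–Cantor correction becomes undefined when an observed proportion
reaches 3/4 — such estimates are flagged invalid rather than clamped.
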