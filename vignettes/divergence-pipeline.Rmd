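---
title: "Quantifying phenotypic divergence and gene flow along sulfide gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phenotypic divergence and gene flow along sulfide gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfidiv)
```

## The scientific problem

Hydrogen-sulfide-rich springs are acutely toxic to most fishes: H2S blocks
oxidative phosphorylation, and only locally adapted populations of
livebearing fishes (poeciliids, chiefly *Gambusia* and *Poecilia* species)
persist in them. Replicated pairs of sulfidic and adjacent non-sulfidic
populations form a natural experiment in ecological speciation: divergent
selection should (i) push life histories toward larger but fewer offspring,
(ii) enlarge heads (more gill surface for aquatic surface respiration), and
(iii) — if local adaptation reduces migrant fitness — curtail gene flow,
visible as elevated neutral genetic differentiation.

`sulfidiv` implements the full analysis chain used to test these
predictions across many population pairs:

1. **Geometric morphometrics** — generalized Procrustes analysis (GPA) of
   13 lateral landmarks and relative warps (shape principal components) as
   shape variables.
2. **Nested MANCOVAs** — mixed-design multivariate analyses of covariance
   with Type-III sums of squares and Wilks' lambda, a nested random site
   term, and stepwise pruning of non-significant interactions.
3. **Canonical divergence vectors** — the axis in trait space that best
   separates habitat types for the habitat (H2S) model term, scored per
   individual.
4. **Population genetics** — Weir–Cockerham pairwise F_ST from
   microsatellites and (partial) Mantel permutation tests.
5. **Integration** — per-system divergence scores, a two-measure PCA giving
   one phenotypic-divergence axis, and one-tailed Spearman correlations of
   divergence with F_ST and with H2S concentration.

Because specimen-level field data of this kind are rarely deposited, the
package ships a first-class synthetic-data generator that emulates the
study design, so every stage — and the pipeline end to end — is testable.

## The statistical models

### Shape variables

Each specimen is a 13 x 2 landmark configuration. GPA centres every
configuration, scales it to unit centroid size, and rotates it onto a
running consensus until the consensus stabilizes (full Procrustes
superimposition; reflections disallowed because all fish are photographed
in the same lateral orientation). Aligned shapes are projected orthogonally
into the tangent space at the consensus; relative warps are their principal
components with equal landmark weighting (bending-energy exponent 0, the
default of the common tps software family). Seven axes are retained by
default as the downstream shape variables. The consensus is rotated to its
principal axes (proper rotations only), which makes the whole alignment
invariant to a common rigid motion of the raw data.

### Nested MANCOVA and Wilks statistics

For responses $Y$ (traits or relative warps) the design crosses clade, sex,
and habitat (H2S present/absent) with covariates (standard length or
centroid size, embryonic stage of development) and a random site term
nested in clade x habitat. All factors are coded sum-to-zero; each term's
hypothesis SSCP $H$ is the Type-III difference between the residual SSCP of
the model without that term and the full-model residual SSCP $E$.
Significance uses Wilks' $\Lambda = \det E / \det(H + E)$ with Rao's F
approximation (exact for $\min(p, q) \le 2$), effect size is partial
$\eta^2 = 1 - \Lambda^{1/s}$, $s = \min(p, \mathrm{df}_h)$, and the
relative variance is each term's partial $\eta^2$ divided by the model's
largest.

Interactions are pruned stepwise: the highest-order interaction with the
largest $p > 0.1$ is dropped and the model refit, except that a term is
retained while a significant higher-order interaction contains it. Main
effects, covariates, and the site term are never dropped.

The random site term is handled with a *site-means* approximation: the
between-site fixed effects (clade, habitat, clade x habitat) are re-tested
by aggregating covariate-adjusted responses to site mean vectors and
running the clade x habitat MANOVA on those, so that site-to-site variation
within cells is the error stratum — site is the unit of replication. In a
balanced univariate design this is exactly the classical nested-ANOVA ratio
$MS_\mathrm{term} / MS_\mathrm{site(nested)}$ with denominator df
`n_sites - n_cells`. A full multivariate REML fit with Kenward–Roger df was
considered and rejected: the site-means test has a closed form the test
suite can verify independently, and its logic is identical. Output rows
carry `approx = "site-means"` so the approximation is visible.

### Divergence vectors and scores

The canonical axis of the habitat term is the first eigenvector of
$E^{-1} H_\mathrm{H2S}$, normalized to unit length and oriented so sulfidic
individuals have the larger pooled mean score. Individual scores project
the responses onto this axis after adjusting for covariates and the
non-focal *main* effects (allometry, stage, clade, sex).

This adjustment set was a genuinely open design choice. Residualizing on
*all* non-focal terms — including the clade x habitat interaction and the
nested site block — looks natural but is degenerate for the downstream
stage: those terms absorb every between-system difference in divergence
magnitude, so all systems within a clade would receive numerically
identical per-system divergence, and the divergence-versus-H2S gradient
could never be detected. Adjusting only for covariates and non-focal main
effects removes allometric, sex, and clade-level contamination while
leaving habitat-linked between-site variation in the scores, which is what
per-system divergence must measure.

Individuals of a second genus, whose clades and sites the training model
never saw, are projected with the stored eigenvector coefficients after
centering at the training grand mean (`adjust = "center"`), using the
training sample's transformation constants.

### Per-system divergence and integration

For every sulfide system, per-site mean scores are computed first;
the system's divergence is mean(non-sulfidic site means) minus the sulfidic
site mean. With sulfidic-positive vectors this signed value is
systematically negative, so the summary reports the signed value *and* its
magnitude and uses magnitudes for the combined axis — this keeps the sign
of the divergence–H2S correlation unambiguous. Life-history and
morphological divergence magnitudes are standardized and combined by PCA on
their 2 x 2 correlation matrix; the leading eigenvalue is $1 + |r|$ and its
variance fraction $(1 + |r|)/2$ (an eigenvalue of 1.88 is 94.0 % of the
total variance). Correlations of divergence with F_ST (to the
geographically closest non-sulfidic site, great-circle distance) and with
H2S use one-tailed Spearman tests; the default p-value is the
t-approximation $t = r\sqrt{(n-2)/(1-r^2)}$, which reproduces the reported
p-values at n = 9 and n = 44, with exact permutation enumeration available
for n <= 10.

### Population genetics

Pairwise F_ST is the Weir–Cockerham (1984) estimator: per-allele,
per-locus variance components a, b, c combined as a ratio of sums
$\theta = \sum a / \sum(a+b+c)$, negative per-locus components retained.
The partial Mantel test regresses the upper triangles of the F_ST and
habitat-difference matrices on the clade-difference matrix, rebuilds
residual matrices, and permutes rows and columns of the residualized
dependent matrix (the Smouse–Long–Sokal scheme); the observed statistic
equals the closed-form partial correlation. Permutation p-values use the
add-one convention, so p is never 0.

## The synthetic generator: what it emulates

The generator's defaults encode the study conditions:

* **Design** — ten sulfide systems across six clades in two genera (one
  *affinis*-type, three *holbrooki*-type, one *eurystoma*-type, one
  *hubbsi*-type mosquitofish system, plus four molly systems), each pairing
  one sulfidic spring (H2S drawn from 20–200 uM) with a nearby non-sulfidic
  reference site.
* **Life histories** — standard length by sex (females ~27.5 mm, males
  ~20.9 mm geometric means) with mild clade offsets; lean weight allometric
  with SL (log-log slope 3); fat, GSI/reproductive-allocation on the
  arcsine-sqrt scale. At the reference concentration (midpoint of the
  sulfidic range) sulfidic females produce embryos 1.52 mg heavier
  (3.04 vs 1.52 mg) and broods 5.89 offspring smaller (9.09 vs 14.98) —
  the reported habitat contrasts; effects scale linearly with a site's H2S
  (a saturating option exists but is off by default, mirroring the
  possibility of an asymptotic dose–response).
* **Trade-off and allometry** — a latent allocation variable couples
  embryo mass (positively) and fecundity (negatively); an SL coupling on
  the sqrt-fecundity scale is calibrated so the fecundity–length
  correlation is 0.67 by default.
* **Noise model** — Gaussian on the transformed scales (log10 / sqrt /
  arcsine-sqrt) with lognormal mean-bias correction, so back-transformed
  traits are positive and right-skewed; fecundity is rounded to a count.
* **Shape** — each specimen is the mean configuration plus a head
  enlargement (snout, crown, jaw, eye, pectoral girdle displaced;
  magnitude 0.03 Procrustes units at the reference H2S), plus individual
  variation on a few smooth deformation modes with decreasing scale and a
  small isotropic digitizing residual, then random scaling, rotation, and
  translation for GPA to remove. The structured modes make the leading
  relative warps carry most shape variance, as real landmark data do
  (around 90–95 % in seven axes); purely isotropic noise would spread
  variance evenly over all 22 shape dimensions, which no real dataset
  shows. The bundled 13-landmark mean configuration is an idealized
  poeciliid outline constructed for simulation (labelled synthetic), not a
  digitized consensus.
* **Genetics** — per-locus ancestral allele frequencies from a flat
  Dirichlet; site allele frequencies from the multiallelic Balding–Nichols
  model, whose differentiation parameter F is the direct estimand of the
  Weir–Cockerham estimator — that choice makes parameter recovery a clean
  closed-loop test. By default a sulfidic site's F scales with its H2S
  concentration (background 0.15 F elsewhere), so neutral differentiation
  grows with divergence strength; a flag switches to uniform F for
  estimator calibration. The generator parameterizes differentiation
  directly rather than demographically, because no migration rates or
  census sizes are reported for these systems.

What the generator does **not** emulate: sequence data or phylogenies,
temporal environmental variation, measurement error correlated across
traits, unbalanced sampling, missing genotypes, or colonization history.
Passing tests therefore certify the statistical machinery and its
calibration under the stated model — not robustness to every property of
field data.

One structural caveat surfaced by the generator: under Balding–Nichols
drift, two sulfidic springs are as differentiated from each other as from
their references, so same-habitat pairs can carry high F_ST and the
habitat-difference partial Mantel signal is weaker than the per-system
F_ST–divergence correlation. The pipeline reports both.

## Numerical choices and degenerate inputs

* GPA converges on the consensus Frobenius change (`tol = 1e-10`, cap 200
  iterations); coincident-landmark configurations are rejected.
* Relative-warp axes are sign-fixed so each axis's largest-magnitude
  loading is positive; requesting more axes than the effective rank
  (eigenvalues above 1e-12 of the largest) errors.
* `wilks_stats` rejects singular error SSCPs with advice to reduce the
  response set; lambda is clamped to (0, 1] against floating-point
  spillover.
* Rank-deficient designs error naming the aliased terms rather than
  silently dropping columns.
* F_ST is `NA` with a warning when no locus varies in either site; missing
  genotypes are handled per-locus complete-case within each pair.
* Mantel tests reject constant matrices; a constant covariate matrix
  demotes the partial test to the simple test with a warning.
* Permutation and simulation seeds all derive from one master seed
  (`child_seed`), kept below 2^31; identical configurations produce
  byte-identical reports.

## Problem sizes used in the tests

The test suite exercises the pipeline at deliberately compact sizes chosen
to keep a full run in a few minutes while leaving every estimator in its
operating range: 4–10 systems, 10–30 individuals per site, 6–11 loci,
permutation counts of 99–999, 20–200 replicate seeds for the power,
calibration, and uniformity checks. These sizes are the package's own
test-design choice; the defaults of `run_config()` (10 systems, 30
individuals per site, 11 loci) are the emulated study conditions.

## Known limitations

* The site-means test is an approximation to a full multivariate mixed
  model; with very unequal site sample sizes it weights sites equally.
* Divergence-vector scores depend on the adjustment convention discussed
  above; both the choice and its rationale are documented here because the
  original derivation details are not public.
* The partial Mantel habitat signal under the default genetic model is
  structurally weak (see above); interpret `mantel_fst_habitat_*` output
  accordingly.
* Exact permutation p-values enumerate n! permutations and are practical
  only to n = 10 (and slow there); the t-approximation is the default.
* TPS and GenePop support covers the common dialects (LM=/ID=/SCALE=;
  2- and 3-digit codings) rather than every historical variant.

## A minimal run

```{r example, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
report$correlations
tidy(report)          # the three headline correlations
autoplot(report$summary)
```
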