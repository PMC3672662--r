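---
title: "Methods: models, estimators and design choices in paritykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in paritykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paritykit)
```

paritykit quantifies how an early full-term pregnancy (parity) changes the
mammary basal stem/progenitor cell compartment, along five axes: in-vivo
repopulating frequency, differential gene expression, transcription-factor
motif activity, pathway-level enrichment, and stained-area fractions in
tissue sections. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where several defensible
constructions exist.

## Limiting-dilution analysis: the single-hit Poisson model

In a limiting-dilution transplantation assay, FACS-sorted cells are injected
into cleared (de-epithelialized) mammary fat pads at a series of doses
$d_i$, and each graft is scored positive when an epithelial outgrowth forms.
Under the single-hit model, the number of repopulating cells received by a
graft is Poisson with mean $f d_i$, where $f$ is the frequency of mammary
repopulating units (MRU) per injected cell, and a graft is negative iff it
receives zero such cells:

$$P(\text{negative} \mid d_i) = e^{-f d_i}.$$

The positives $r_i$ among $n_i$ injections are then binomial with success
probability $1 - e^{-f d_i}$, giving the log-likelihood

$$\ell(f) = \sum_i \left[ r_i \log\!\left(1 - e^{-f d_i}\right) -
  (n_i - r_i)\, f d_i \right].$$

`fit_single_hit()` maximizes $\ell$ over $\phi = \log f$ (golden-section
bracketing plus Newton polishing of the score to machine precision; the
likelihood is unimodal in $\phi$). This is exactly the model behind a
binomial GLM with complementary log-log link and offset $\log d$ — the
formulation used by standard limiting-dilution software — and the test
suite confirms agreement with `glm()` on every packaged table.

**Confidence intervals.** The default 95% interval is Wald on the natural
log of $f$: $\exp(\hat\phi \pm 1.96\,\mathrm{SE}(\hat\phi))$, with the
standard error from the observed information (numeric curvature of $\ell$
at the maximum). This is the construction used in the classical
limiting-dilution literature and reproduces published interval bounds for
the packaged tables to within about 2%. Note that the observed and the
expected (IRLS) information differ by a few percent at these small group
sizes, which is the residual discrepancy one sees against `glm()`'s
standard errors. A profile-likelihood interval (`ci = "profile"`) is
offered for small or unbalanced tables where the Wald interval is least
trustworthy.

**Group comparison.** `compare_frequencies()` uses the likelihood-ratio
test: $\chi^2 = 2(\ell_a + \ell_b - \ell_{\text{pooled}})$ with one degree
of freedom, where the pooled fit constrains both groups to a common $f$.
The likelihood-ratio form was preferred over a Wald test because it is
symmetric in the two groups and better behaved at small positive counts;
on the packaged tables it reproduces the published p-values (two highly
significant comparisons near $4 \times 10^{-4}$ at the stringent outgrowth
scorings, one non-significant near 0.08 at the rudimentary scoring).

**Boundaries.** Tables with zero positives everywhere (MLE $f = 0$) or all
positives (MLE $f = \infty$) are flagged, not fitted; rows with $r_i = 0$
inside an otherwise informative table are ordinary data and contribute
$-(n_i) f d_i$ to the likelihood. Frequencies display as
$1/\mathrm{round}(1/\hat f)$, the "1 repopulating unit per N cells"
convention of transplantation tables.

**Outgrowth scoring.** `classify_outgrowths()` implements the threshold
rule that defines the scoring variants: a transplant is positive when the
outgrowth fills at least 3% (rudimentary), 10%, or 25% (large) of the fat
pad.

## Moderated differential expression

`moderated_t()` implements the empirical-Bayes moderated t for a two-group
(virgin vs parous) comparison of log2 expression. Gene-wise pooled
variances $s_g^2$ (residual df $d_g = n_a + n_b - 2$) are assumed to follow
a scaled-F sampling model around a prior $(d_0, s_0^2)$, estimated by
method of moments on $\log s_g^2$: writing
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior df solves
$\mathrm{var}(e) - \psi'(d_g/2) = \psi'(d_0/2)$ (via a Newton inversion of
the trigamma function) and $s_0^2$ follows from the mean of $e$. Posterior
variances are the usual shrinkage blend

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and $t_g = \widehat{\Delta}_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ is
referred to a t distribution with $d_0 + d_g$ df. When the moment equation
has no positive solution the variances are fully pooled ($d_0 = \infty$)
and the result flagged. `prior_df = 0` recovers the ordinary pooled t
exactly — a useful analytic limit that the tests exercise — and the
estimates agree with limma's independent implementation to 6 decimals on
simulated data.

**Filters.** The retention rules are linear fold change
$2^{|\log_2 \text{FC}|}$ above 1.5, Benjamini-Hochberg adjusted p below
0.05, and average linear expression above 4 — with a stricter shortlist
variant (fold change 2.0, adjusted p 0.001) used for top-gene tables.
Because expression values arrive on the log2 scale, "average linear
expression" is computed as the mean of $2^{x}$ across all samples of both
conditions; the thresholds are plain arguments, so an analyst who prefers
the log-scale reading can pass `min_ave_linear_expr = 2` instead.
Benjamini-Hochberg was chosen for the adjustment because it is the default
of the linear-modeling ecosystem this stage mirrors. `zscore_rows()`
provides the $Z = (x - \mu)/\mathrm{sd}$ row standardization used for
heatmap display, mapping constant rows to zero with a warning rather than
NaN.

## Motif activity response analysis

Motif activity analysis explains centered log-expression as a linear
combination of transcription-factor motif activities, with coefficients
fixed by promoter binding-site counts: for sample $s$,

$$E_{gs} \approx \sum_m N_{gm} A_{ms},$$

where $N$ is the genes-by-motifs site-count matrix. The expression matrix
is centered per gene and per sample and the site-count columns are
centered, so fitted activities are invariant to adding constants to any
gene row or sample column (a property the tests check). Because motif
site-count columns are sparse and correlated, $N^\top N$ is
ill-conditioned, and the system is solved by ridge-regularized least
squares in closed form:

$$\hat A_{\cdot s} = (N^\top N + \lambda I)^{-1} N^\top E_{\cdot s},$$

with standard errors from the per-sample residual variance times the
diagonal of $(N^\top N + \lambda I)^{-1}$. By default $\lambda$ is chosen
by 5-fold gene-wise cross-validation over a logarithmic grid scaled by the
mean diagonal of $N^\top N$ (so the grid is invariant to gene count and
site density); a fixed $\lambda$ can be supplied for deterministic runs.
$\lambda = 0$ is allowed only for well-conditioned designs and errors
otherwise with an instruction to regularize.

**Condition changes.** `motif_change_z()` scores each motif by
$\Delta_m = \bar A_m^{\text{parous}} - \bar A_m^{\text{virgin}}$, divided
by a standard error to give $z$ (two-sided normal p, motifs ranked by
$|z|$). A design subtlety: the within-condition spread of the *recovered*
per-sample activities already contains the activity-fitting error, so
adding the ridge standard errors on top would double-count uncertainty
and make $z$ conservative, while using each motif's raw 4-df spread alone
would make $|z| > 1.96$ fire at roughly twice the nominal rate. The SE
therefore uses the per-motif within-condition pooled variances moderated
by the same empirical-Bayes squeeze as the expression stage, which borrows
strength across motifs and keeps the null rate of $|z| > 1.96$ at 5%
(verified by simulation in the tests). The fitted per-sample standard
errors remain available in the `motif_activity_result` for diagnostics.

In the planted-truth acceptance run, one motif carries a $-4$
activity-unit parity response against a per-sample activity SD of 1. The
shift is four sigma by design: with three arrays per condition the
expected $z$ is about $-4.9$, so requiring the planted motif to rank first
with $z < -3$ is a high-power check rather than a coin flip; a one-sigma
shift, by contrast, is genuinely undetectable at this design size.

## Gene-set enrichment with a gene-set permutation null

`rank_by_difference()` scores each gene by its parous-minus-virgin mean
expression difference and sorts descending (ties broken lexicographically
for determinism). `enrichment_score()` computes the classic weighted
Kolmogorov-Smirnov running sum: walking down the ranked list of $N$ genes,
an in-set gene ("hit") increments the sum by $|x|^p$ normalized over the
in-set total and a miss decrements by $1/(N-k)$; the enrichment score (ES)
is the signed maximum deviation. The weight exponent defaults to $p = 1$;
$p = 0$ gives the unweighted form used for the analytic test cases (a
contiguous top-$k$ set reaches ES $= 1$ exactly).

`permute_and_score()` builds the null from **gene-set permutation** —
random same-size gene sets — rather than phenotype permutation, which is
the only valid option at three arrays per condition. Per set: the nominal
p is the fraction of same-sign null ES at least as extreme; NES divides ES
by the mean magnitude of same-sign null ES; the FDR q-value uses the
tail-ratio construction on the pooled normalized null (fraction of pooled
null NES as extreme over fraction of observed NES as extreme, capped at
1); and FWER is the fraction of permutations whose most extreme same-sign
null NES beats the observed one. Sets outside the 5-500 size bounds are
flagged, never silently dropped. Everything is seeded; identical inputs
and seed give byte-identical results, and the ES and NES agree with an
independent implementation (fgsea's random-gene-set method) in the test
suite.

## IHC color segmentation by Mahalanobis distance

Stained-area quantification (e.g. versican deposition in mammary gland
sections) uses a reference color model: `fit_color_reference()` takes at
least 10 training pixels of the stain and records their RGB mean $\mu$ and
covariance $\Sigma$ (diagonal-inflated and flagged if near-singular).
`segment_by_mahalanobis()` calls a pixel positive when its squared
Mahalanobis distance $d^2 = (x-\mu)^\top \Sigma^{-1} (x-\mu)$ is at most
$\chi^2_3(q)$. Expressing the cutoff as a chi-square(3) quantile (default
$q = 0.99$) makes it probabilistically interpretable — on pixels drawn
from the reference distribution itself the positive rate equals $q$ — and
calibration-testable. An optional luminance-based tissue mask excludes
near-white background from the denominator. Images are 8-bit RGB promoted
to doubles; segmentation is affine-invariant under a common linear color
transform of image and training pixels.

## The synthetic-data generators

Each stage is paired with a generator producing data under exactly the
model the stage assumes, plus a truth record sufficient to score recovery:

* `simulate_dilution_assay()` draws binomial outcomes under the single-hit
  model at user-specified doses and group sizes.
* `simulate_expression_dataset()` draws gene baselines from N(7, 2) log2
  units, gene-wise variances from a scaled inverse-chi-square with
  (`variance_prior_df` = 4, `variance_prior_scale` = 0.05) — the exact
  generative family of the moderated-t prior, which makes shrinkage
  recovery a sharp test — and plants a ±`de_log2_effect` shift on a
  `de_fraction` subset in the parous condition.
* `simulate_motif_dataset()` draws sparse Poisson site counts
  (`motif_site_rate` = 0.5 sites/promoter, so most entries are 0, matching
  the conditioning of real promoter-site matrices), per-sample activities
  around condition means separated by the planted shifts, and expression
  `N %*% A` plus baseline plus N(0, `expression_noise_sd`²) noise.
* `simulate_ihc_image()` places exactly `floor(positive_fraction * H * W)`
  stained pixels at random positions, colors drawn from two multivariate
  normal populations, and returns the ground-truth mask.

Defaults mirror a small two-condition microarray study: 5000 genes, three
arrays per condition, 50 motifs. The defaults are the package's own
choices of a realistic regime — the noise magnitude of any particular
deposited array series is not claimed. One global seed is expanded into
per-generator substreams (hashed from the generator name), so adding a
generator to a pipeline never perturbs the draws of the others; every
generator is byte-reproducible under a fixed seed.

What the generators deliberately do **not** emulate: probe-level array
artifacts, normalization residuals, correlated gene-gene noise, batch
structure, FACS contamination between subpopulations, or tissue texture in
images. Passing recovery tests on this synthetic data therefore
demonstrates correctness of the estimators under their assumed models, not
robustness to the full messiness of deposited microarray or histology
data.

## Numerical choices and problem sizes

Tolerances: the single-hit MLE is polished to $|\Delta \log f| <
10^{-13}$ and checked against an independent grid-search oracle at
$10^{-6}$; ridge solutions use Cholesky factorization; the trigamma
inversion iterates Newton steps to relative $10^{-10}$; running-sum
profiles return to zero within $10^{-12}$ by construction. Degenerate
inputs (constant expression rows, all-zero site columns, color-plane
training pixels, boundary transplant tables) are flagged or errored
explicitly rather than propagating NaN.

The simulation-backed checks use 1000 replicate assays for interval
coverage, 10⁴-gene matrices for error-rate calibration, a 5000-gene /
50-motif instance for activity recovery, and 150 random sets × 200
permutations for enrichment-null calibration — sizes at which Monte-Carlo
error is comfortably inside each test's acceptance band while the whole
suite stays fast enough to run routinely.

## Known limitations

* The Wald interval can undercover for tables dominated by boundary rows;
  the profile option mitigates but the package makes no small-sample
  exactness claim.
* Motif activities are identified only up to the centering conventions;
  absolute activity levels are not interpretable, only contrasts.
* The FDR q construction pools normalized null distributions across sets
  of different sizes; with very heterogeneous collections the pooled tail
  is an approximation.
* Mahalanobis segmentation assumes a single Gaussian stain color; mixed
  stains would need per-stain references or deconvolution, which is out of
  scope.
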