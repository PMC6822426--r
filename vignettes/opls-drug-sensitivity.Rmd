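---
title: "Predicting targeted-therapy sensitivity from proteomic profiles with O-PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting targeted-therapy sensitivity from proteomic profiles with O-PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsense)
```

## The problem

Mutation status alone is a weak predictor of response to targeted cancer
therapeutics: among BRAF-V600E cell lines, many non-melanoma (and some
melanoma) lines are intrinsically resistant to BRAF inhibition.  `oplsense`
implements a pharmacoproteomic modelling workflow for this setting: a
reverse-phase protein array (RPPA) style matrix of total- and
phospho-protein levels across cell lines is regressed against a continuous
drug-sensitivity readout — the normalized area under the dose-response
inhibition curve (IC50 AUC, bounded in [0, 1], higher = more sensitive,
with AUC < 0.2 conventionally labelling resistant lines).

The statistical challenge is the usual one for such panels: far more
features than samples (hundreds of antibodies, a few dozen lines), plus a
strong nuisance factor — tumor type drives large, coordinated protein
expression differences that have nothing to do with drug response.

## The model

### O-PLS regression

Orthogonal projections to latent structures (O-PLS) fits, for a scalar
response, **one predictive latent component** plus zero or more
**response-orthogonal components**.  On an autoscaled matrix $X$
(n samples x p features, each feature mean 0, variance 1) and a centered
(optionally unit-variance) response $y$, the NIPALS-style extraction used
here is:

1. predictive weights $w = X^\top y / \lVert X^\top y \rVert$ (unit norm);
2. for each orthogonal component: scores $t = Xw$, loadings
   $p = X^\top t / t^\top t$, orthogonal weights
   $w_o \propto p - (w^\top p)\,w$ (normalized), scores $t_o = X w_o$,
   loadings $p_o = X^\top t_o / t_o^\top t_o$, then deflation
   $X \leftarrow X - t_o p_o^\top$;
3. finally $t = Xw$ on the deflated matrix and the inner regression
   $\hat y = b\,t$ with $b = t^\top y / t^\top t$.

Because $X^\top y$ is invariant under the deflation, every orthogonal
score satisfies $t_o^\top y = 0$ exactly: the orthogonal components
absorb systematic feature variation (tumor type, in the motivating
setting) while provably carrying no response information.  Prediction for
a new sample applies the stored scaling, removes each orthogonal
component ($x \leftarrow x - (x^\top w_o)\,p_o^\top$), and projects onto
$w$.

Two numerical choices matter and are recorded in the model object:

- **Per-training-set centering.** Every fit (including every
  cross-validation refit) re-centers the feature columns on its own
  training rows.  Autoscaling the full matrix once and subsetting leaks
  fold means into held-out predictions; with per-fold re-centering an
  exactly latent-linear response reaches Q2Y ~ 1, as it should.
- **Response scaling.** The response is centered and, by default, scaled
  to unit variance inside the fit (`scale_y = TRUE`); predictions are
  always returned on the original scale, and the convention is stored in
  the serialized model so either choice is reproducible.

### Model statistics and component selection

R2Y is the in-sample fraction of response variance explained; Q2Y is its
7-fold cross-validated analogue, `1 - PRESS/TSS`, computed over a seeded
random fold partition with the full component structure refitted in each
fold.  Q2Y may be negative and is never floored.  Orthogonal components
are added sequentially and one is retained only if it raises Q2Y by more
than `delta_q2 = 0.05` (an absolute increase); selection stops at the
first failure.  The single predictive component is always kept — with a
scalar response there is nothing to select on that axis.

### VIP scores and signatures

The variable importance in projection for feature $j$ sums over the
predictive and retained orthogonal components $m = 1 \dots M$:

$$VIP_j = \sqrt{\frac{p \sum_m w_{mj}^2\, SS(b_m t_m)}{\sum_m SS(b_m t_m)}}$$

where $SS(b_m t_m)$ is the fraction of response variance explained by
component $m$.  Orthogonal components contribute essentially nothing
(their scores are uncorrelated with $y$, so $SS \approx 0$), and with
unit-norm weights the identity $\operatorname{mean}(VIP^2) = 1$ holds to
machine precision — both facts are asserted in the test suite.  Features
with VIP > 1 form the signature; the sign of the predictive weight
assigns each to the resistance-associated (negative) or
sensitivity-associated (positive) side.  Weights and predictive loadings
are proportional for this component, so either orders the signature
identically.

## Curation defaults

| parameter | default | meaning |
|---|---|---|
| detection threshold | 0.25 | a feature must be observed in at least 25% of samples (inclusive) |
| imputation | feature mean | equivalently 0 after autoscaling; neutral under mean-centering |
| variance | sample (n-1) | recorded in `scaling_params` for bit-reproducibility |
| resistance cutoff | AUC < 0.2 | strict inequality |
| CV folds | 7 | Q2Y estimation |
| `delta_q2` | 0.05 | orthogonal-component retention |
| test set | 6 samples | stratified by tumor-type x resistance |

The train/test split is random but constrained so that each of the four
melanoma/non-melanoma x sensitive/resistant strata appears at least once
in both sets; a stratum with fewer than two members is an error rather
than a silent violation.

## In-silico receptor inhibition

The receptor-only model restricts the matrix to receptor-flagged features
(total and phospho forms) and trains on **all** samples.  Inhibition of a
receptor set is simulated by clamping the targeted features to their
per-feature minima over the model's training matrix — on the raw
measurement scale, so "minimum" is interpretable in assay units — and
re-applying the model.  Only the requested features are perturbed;
whether correlated features should co-vary is deliberately out of scope.
Since the model is linear in the scaled features, the prediction change
equals the inner product of the scaled displacement with the model's net
coefficient vector (`opls_coefficients()`), which the tests verify to
1e-8.  Predictions are deliberately not clipped to [0, 1]: a clamp that
large signals extrapolation beyond the training envelope and should be
visible, not hidden.

## Dose-response and Loewe synergy

Viability plates are converted to percent inhibition by blank-correcting
all signals, taking the blank-corrected vehicle mean as $A_{min}$, and
computing $y = (A_{min} - x)/A_{min} \times 100$ (duplicates averaged per
dose; growth stimulation appears as negative inhibition).  Curves are
fitted with the fixed-asymptote Hill model
$y = 100 / (1 + (IC_{50}/x)^{Hill})$ by bounded least squares
(`minpack.lm`), initialized at the dose nearest 50% inhibition with
Hill = 1 and bounded by $IC_{50} \in$ [min dose/100, 100 max dose],
$Hill \in$ [0.1, 10].  A fit whose IC50 sits at a bound — the typical
signature of an IC50 beyond the tested range — is flagged unreliable and
refuses to enter a synergy index.

The sensitivity AUC for synthetic curves is defined here as the
trapezoidal integral of fractional inhibition (clipped to [0, 1]) over
log10 dose, normalized by the log10 dose range.  Published AUC values
from pharmacogenomic portals use their own normalizations and are always
consumed as supplied numbers, never recomputed.

Fixed-ratio combinations (1:2 means drug 2 at twice drug 1's
concentration in every well) are fitted on drug 1's concentration axis;
the combination IC50 is split by the ratio into per-drug concentrations
$x^1, x^2$, and the Loewe index is
$x^1/X^1_{LOEWE} + x^2/X^2_{LOEWE}$ with monotherapy IC50s in the
denominators.  Values below 1 flag synergy.  How per-drug concentrations
are extracted from a dual-therapy curve is not uniquely defined; the
ratio-split convention is the package's documented choice and is what the
combination generator inverts, so round trips are exact in expectation.

## The synthetic study generator

`generate_rppa_like()` emulates the structure the analysis assumes, with
full ground truth:

- response `y ~ Uniform(0, 1)` across samples (mirroring the wide
  observed AUC span), conditioned on at least 4 resistant and 4 sensitive
  samples so that every stratification stratum can be populated — a
  degenerate draw would make the study design itself infeasible;
- a predictive latent score `t = y - mean(y)` loading with chosen signs
  (+1 sensitivity, -1 resistance) onto a planted feature set;
- an orthogonal latent score driven by a binary tumor-type label that is
  assigned by a fair coin within each resistance class — marginally
  independent of the response, which the tests verify empirically
  (median |corr| < 0.15 over seeds);
- i.i.d. Gaussian feature noise, and feature-biased missingness (a few
  percent of background missingness plus a set of mostly-missing
  features) so the detection filter has real work to do.

Defaults are n = 30 samples, p = 200 features, 10 planted features with
unit loadings and noise SD 0.45, which places the recoverable signal near
R-squared 0.8; the confounded preset raises the orthogonal factor to 3x
the predictive signal.  These dimensions echo the 26 x 232 scale of the
motivating RPPA panel while leaving headroom for the split constraints.
All randomness flows from the single spec seed through a fixed, documented
draw order, so outputs are bit-reproducible.

What the generator does **not** emulate: real RPPA antibody noise models
(heteroscedastic, antibody-specific), correlated pathway blocks beyond
the two planted factors, batch structure, or transcript/protein
discordance.  A passing recovery test therefore demonstrates that the
machinery identifies the structure it is built for at realistic
dimensions — not that any particular real panel satisfies that structure.

Dose-response plates are generated by inverting the percent-inhibition
formula around a nominal vehicle level (blank and vehicle wells exact,
treated wells noisy, floored at the blank level so inhibition saturates
at 100%), and the combination generator places the true combination IC50
so the underlying Loewe index equals the requested interaction.

## Problem sizes used in the tests

The recovery and retention properties are asserted at the generator's
native regime (30 x 200) over 10–20 seeds; leave-one-out comparisons use
24–30 samples with 60–80 features; Hill-recovery statistics use 50
replicate plates.  The full suite and the acceptance script each complete
in well under a minute on a single CPU.

## Known limitations

- Single scalar response only; no O2-PLS or kernel variants.
- Baseline hyperparameters are fixed, documented values (lasso penalty by
  internal 5-fold CV with an extended path, random forest 100 trees
  averaged over 5 seeds, SVR C = 1, epsilon = 0.1), not tuned per
  dataset; the SVR epsilon-tube in particular bounds its achievable
  error at ~epsilon even on noiseless data.
- The Q2Y fold partition is seeded-random; a different seed gives a
  (slightly) different Q2Y, which is why the seed is stored in the model.
- No plate-effect or edge-effect correction, and no Bliss/ZIP-style
  synergy models.
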