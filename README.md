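# tentemix

Dose–response modelling of radiation-induced tumour counts with **targeted
plus non-targeted effects** (TE+NTE), a **weighted negative binomial** (WNB)
error distribution, and **mixture predictions** for multi-ion exposures such
as the galactic-cosmic-ray environment of a Mars mission.

The package is aimed at radiation biologists and biostatisticians who need
to quantify dose–response shapes, radiation-quality metrics (RBE, RER), and
mixture risks from per-animal tumour-count data — the setting of the
APC^(1638N/+) mouse intestinal tumorigenesis experiments with γ rays and H,
He, C, O, Si, and Fe ions.

## The model

The latent mean tumour intensity per animal at dose *D* (Gy) is

```
M(D) = B + N (1 − e^(−sD)) + T·D
```

with `B` the background yield, `T` the linear TE slope (Gy⁻¹), `N` the NTE
saturation plateau, and `s` the NTE saturation rate (Gy⁻¹). Counts per
animal follow a weighted negative binomial — a negative binomial with mean
`M` and dispersion `r`, reweighted by `(M + kq)/(M(1+q))` — which is
underdispersed (V/µ = 1/(1+q)) at small `M` and overdispersed at large `M`,
as the mouse data are. `B` and `q` are eliminated as free parameters by
constraining them to the observed control-arm mean (3.279) and variance
(2.625). Model fitting is joint constrained maximum likelihood across all
radiation types with configurable parameter sharing, multi-start
optimization, and AICc comparison; uncertainty comes from Monte Carlo
parameter clouds inside the 95% likelihood region; mixtures are predicted by
incremental effect additivity (IEA), solving
`dE/dD = Σ f_j µ′_j(F⁻¹_j(E))`, against the naive simple effect additivity
(SEA) sum. See the methods vignette (`vignettes/tentemix-methods.Rmd`) for
the full account.

## Worked example

```r
library(tentemix)

# packaged best-fit parameters and the Mars-mission ion mixture
mix <- mars_mixture()
iea_predict(mix)            # 4.735075
sea_predict(mix)            # 12.32171
sea_predict(mix) / iea_predict(mix)   # 2.602221
```

The IEA prediction — about 4.7 radiation-induced tumours per mouse for the
0.519 Gy mission dose — falls within the range of the individual ion
responses, while the naive SEA sum (12.3) overshoots even the most
effective single ion by adding six saturating NTE plateaus; the ratio is
about 2.6.

```r
# RBE of Fe ions relative to gamma rays at 0.1 Gy
p <- apc_study_params()
rbe(p$Fe, p$gamma, 0.1)     # 12.0881
rer(p$Fe, p$gamma, 0.1)     # 4.489063
```

At this space-relevant dose the iso-effect dose ratio (RBE) exceeds the
same-dose effect ratio (RER), as expected when NTE saturation makes the ion
response concave.

A full synthetic-study round trip:

```r
dat <- simulate_study(seed = 1)                      # 679 mice, 8 arms
fit <- fit_wnb_model(dat, default_scheme(),
                     n_starts = 25, seed = 2)        # joint constrained ML
cloud <- sample_cloud(dat, default_scheme(), fit,
                      n_min = 600, seed = 3)         # 95% likelihood region
fit_report(fit, cloud)                               # parameter table + CIs
```

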