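# isgrelease

Mechanistic drug-release analysis for **in situ forming gel (ISG) depots**,
built around the cup-method dissolution assay used for periodontal
formulations such as levofloxacin HCl in zein. The package is for
pharmaceutical scientists who need to (i) estimate release parameters from
cumulative-release time series, (ii) predict how formulation changes shift
the release profile, and (iii) simulate the underlying radial diffusion in a
three-phase spherical depot.

## The model

The exterior bath concentration `C3(t)` (% of dose) follows the first-order
exterior-transfer law

    dC3/dt + a C3 = a C2(r2),   a = K32 / V3
    C3(t) = C2(r2) [1 − exp(−a (t − t0))]

where `C2(r2)` is the drug concentration at the outer edge of the polymer
matrix (the release plateau, %), `K32` the matrix-to-bath transfer
coefficient (`K32 = a · V3`, `V3` in mL) and `V3` the bath volume. The
estimator discretizes `y' + a y = b` with a finite-difference stencil —
2-point forward `O(h)` or 5-point central `O(h⁴)` — and recovers `(a, b)` by
ordinary least squares, then identifies `K32 = a·V3` and `C2(r2) = b/a`.
A forward finite-volume simulator of the full three-phase picture
(liquid core / porous matrix shell / well-mixed bath) is included and
validated against the classical series solution for diffusion in a sphere.

## Worked example

Generate a synthetic cup-method dataset from a known model, then re-estimate
the parameters:

```r
library(isgrelease)

m <- first_order_model(C2_edge = 103.5, rate_a = 0.7081)
m
#> First-order exterior-transfer release model
#>   C2_edge : 103.5 % of dose (plateau)
#>   rate a  : 0.7081 / day  (K32 = 56.65, V3 = 80 mL)
#>   t0      : 0 day

# cup assay: 80 mL medium, 5 mL aliquots replaced with fresh buffer,
# 4 mg dose, sampled 0.5–7 days
d <- make_dataset(m, cup_protocol())
round(d$observed$release_pct, 2)
#> [1]  30.86  52.52  78.39  91.13  97.41 100.50 102.02 102.77

# re-fit from a dense noise-free curve with the forward-difference estimator
s <- evaluate_release_curve(m, seq(0, 7, by = 0.001))
fit_release(s, method = "O(h)")
#> First-order release fit [O(h), n = 7000, h = 0.001 d]
#>   K32     = 56.6279   C2_edge = 103.5000 %
#>   rate a  = 0.707849 /day
#>   rel_err = 9.488e-05   r^2 = 1.000000
```

The release climbs from 31% at 12 h towards its 103.5% plateau (plateaus
slightly above 100% are a feature of the fitted parameterisation, not a mass
balance). The re-fitted rate shows the forward stencil's textbook `O(h)`
bias — `â = (1 − e^{−ah})/h`, here 0.04% low — while the plateau `b/a` is
recovered exactly because the bias cancels in the ratio.

A thin command-line interface wraps the same functions
(`inst/exec/isgrelease <generate|fit|sweep|simulate-sphere> --config run.yaml`).

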