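# tcatrace

Quantifying how much of the acetyl-CoA feeding the Krebs (TCA) cycle comes
from a given fuel is a central question in cardiac and tissue metabolism.
When a uniformly ¹³C-labelled substrate (glucose, even-chain fatty acids) is
supplied, its carbon enters the cycle as [1,2-¹³C₂]acetyl-CoA, and the
steady-state mass-isotopologue distributions of the cycle intermediates
measured by LC–MS encode the fraction **α** of acetyl-CoA that was labelled.
Reading α off those distributions is not trivial: CO₂ release is positional,
citrate is handled stereospecifically by aconitase (the Ogston effect), and
the symmetric intermediates succinate/fumarate scramble label 50:50 — so a
single labelled entry spreads into the full range of isotopologues over
successive turns.

`tcatrace` implements a positional-isotopomer network model of one cycle
turn for metabolomics researchers analysing steady-state ¹³C tracing data:

* **State space** — from a data-driven atom-transition table it enumerates
  every reachable positional isotopomer of citrate (6C),
  α-ketoglutarate (5C), succinate (4C) and malate (4C).
* **Transition model** — a pair of row-stochastic matrices (unlabelled /
  [1,2-¹³C₂] acetyl input) over that state space; the model at labelled
  fraction α is `(1 − α)·M_unlabelled + α·M_labelled`, and a pool row-vector
  `x(T) = x(T−1) · M(α)` is iterated to the isotopic steady state.
* **Isotopologue collapse** — positional isotopomers are summed by label
  count into the M+0…M+n proportions that LC–MS measures, including
  bifurcation scans of every isotopologue across α ∈ [0, 1].
* **Fitting** — α is estimated from raw peak-area tables (no
  natural-abundance correction) by minimising a discrepancy score
  `D(α) = mean over metabolites of ½·Σ_k |p_k(α) − q_k|` (total-variation
  distance; 0 = perfect fit, 1 = worst possible), via a grid search with
  golden-section refinement, per replicate, summarised as mean ± SEM. The
  percent contribution of a substrate whose labelled fraction is *f* is
  `100·α̂/f`.
* **Validation tools** — an independent molecule-level Monte-Carlo
  simulator and a synthetic peak-area generator for recovery experiments.

## Worked example

```r
library(tcatrace)

table <- default_transition_table()
space <- enumerate_states(table)
space
#> <tca_states> 60 isotopomers (citrate: 24, alpha_ketoglutarate: 16, succinate: 8, malate: 12)

model <- build_transition_model(table, space)

# steady-state isotopologue distributions at a given labelled fraction
predict_isotopologues(model, alpha = 0.145)
#> # A tibble: 23 x 3
#>    metabolite mass_shift proportion
#>    <chr>           <int>      <dbl>
#>  1 citrate             0     0.534
#>  2 citrate             1     0.181
#>  3 citrate             2     0.197
#>  4 citrate             3     0.0615
#>  5 citrate             4     0.0206
#>  ...

# synthetic experiment: 3 replicates, 5% multiplicative noise, a quarter of
# the substrate pool labelled
meas <- generate_measurements(model, alpha_true = 0.145, n_replicates = 3,
                              noise_cv = 0.05, seed = 11)
fit <- fit_alpha(meas, model, labelled_fraction = 0.25)
fit
#> <tca_fit> alpha = 0.1450 +/- 0.0026, discrepancy = 0.0142, contribution = 58.0% (n = 3; citrate, alpha_ketoglutarate, succinate, malate)

glance(fit)   # one-row summary (alpha mean/SEM, contribution %, discrepancy)
tidy(fit)     # per-replicate alpha and discrepancy

autoplot(bifurcation_scan(model, grid_step = 0.01))  # isotopologues vs alpha
```

The fitted α of 0.145 with a quarter of the substrate labelled means the
labelled substrate supplied 58.0% of the acetyl-CoA oxidised by the cycle;
the discrepancy of ~0.014 says the predicted and measured distributions
differ by about 1.4% total variation per metabolite on average.

Measured data are read from delimited text with columns
`replicate, metabolite, mass_shift, peak_area` via `read_measurement_csv()`;
glutamate rows stand in for α-ketoglutarate, with which it exchanges
rapidly. A shell interface is included for pipeline use:

```sh
Rscript inst/exec/tcatrace fit --input areas.csv --labelled-fraction 0.25 --out fit.json
```

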