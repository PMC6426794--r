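# sterilopt

Surrogate-assisted optimization of in vitro sterilization protocols for
plant tissue culture.

Starting an aseptic culture means disinfecting the explant hard enough
to kill surface microorganisms but gently enough that the tissue
survives. Screens of sterilants quantify that tension with two
percentages scored after ~3 weeks: **contamination frequency (CF)** and
**explant viability (EV)**. `sterilopt` turns a published factorial
screen of chrysanthemum leaf explants — six sterilants (NaOCl,
Ca(ClO)₂, HgCl₂, H₂O₂, AgNO₃, nano-silver), each at five concentrations
× three immersion times, with treatment means ± SE embedded in the
package — into optimized dose–time protocols:

1. **Dataset reconstruction** — each treatment cell becomes 3
   replicate records drawn from `Normal(mean, SE·√3)` clipped to
   [0, 100]; the 18 identical zero-dose cells pool into one control,
   giving 73 treatments × 3 = 219 records, split 165/54 with a
   test-inside-train range check.
2. **MLP surrogates** — one single-hidden-layer perceptron per
   response, `ŷ = b₀ + Σⱼ wⱼ tanh(Σᵢ Wⱼᵢ xᵢ + bⱼ)` over the seven
   inputs (six doses + immersion time), trained by Levenberg–Marquardt
   (`Δθ = −(JᵀJ + λI)⁻¹ Jᵀr`) with validation early stopping and
   hidden-layer size chosen by internal cross-validation; evaluated by
   R² and RMSE per partition.
3. **NSGA-II** — from-scratch elitist non-dominated sorting genetic
   algorithm (fast sort, crowding distance, binary tournament, SBX +
   polynomial mutation) minimizing `(ĈF, −ÊV)` over each sterilant's
   concentration × time box.
4. **Ideal-point compromise** — the front member minimizing
   `(CF − 0)² + (EV − 100)²`, the observed best of each objective.
5. **Sensitivity** — variable sensitivity errors/ratios: retrain with
   one input removed, `VSR = VSE / baseline RMSE`, rank inputs.

## Worked example

```r
library(sterilopt)

records <- reconstruct_records(seed = 1)      # 219 replicate records
split   <- split_train_test(records, seed = 1) # 165 train / 54 test
fits    <- fit_surrogates(split, pipeline_config(seed = 1,
                                                 candidates = c(3, 7, 14)))
fits$metrics
#>   target phase   n    r2 rmse n_hidden
#> 1     cf train 165 0.961 5.72        7
#> 2     cf  test  54 0.958 5.76        7
#> 3     ev train 165 0.937 7.07        7
#> 4     ev  test  54 0.877 9.30        7

opt <- optimize_experiment(fits$cf, fits$ev, "NaOCl",
                           nsga_config(seed = 1),
                           refs = compute_refs(records))
opt$ideal
#>   experiment concentration time_min cf_pred ev_pred rank crowding
#> 1      NaOCl         1.514       15   2.288   92.77    1    0.135
```

Read: on this seed the surrogates explain ~96 % (CF) and ~88–94 % (EV)
of the response variance, and the compromise protocol for sodium
hypochlorite is ≈1.5 % NaOCl for 15 min, predicted to leave ~2 %
contamination at ~93 % viability. Test RMSEs include the SE-calibrated
noise injected into the held-out labels themselves (≈5–6 points), so
they are not pure model error.

```r
variable_sensitivity(split, "cf", seed = 1)
#> sensitivity_report [CF], baseline RMSE 5.669
#>       input       vse      vsr rank
#>   hgcl2_pct 15.803222 2.787697    1
#>  caclo2_pct 12.885614 2.273029    2
#>   naocl_pct 12.575299 2.218289    3
#>   h2o2_pct  12.072315 2.129563    4
#>      ns_mgL 11.549324 2.037307    5
#>    time_min  9.239229 1.629805    6
#>   agno3_pct  9.068809 1.599743    7
```

A full run (all six sterilants, sensitivity for both responses, CSV/JSON
artifacts) is one call — `run_pipeline(pipeline_config(seed = 1), "out/")`
— or, from a shell, the thin CLI at `inst/scripts/sterilopt`:

```sh
Rscript inst/scripts/sterilopt all --seed 1 --outdir out/
```

The original study's reported fit statistics, optima, sensitivity ranks
and wet-lab validation outcomes ship as comparison fixtures
(`reported_benchmarks()`); they are never used in any computation.

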