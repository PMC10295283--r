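# fnirscast

Reference-free physiological noise filtering for functional near-infrared
spectroscopy (fNIRS) signals, by wavelet decomposition of the resting
state and recurrent forecasting of the noise into the task window.

## The problem

fNIRS measures cortical oxygenated-hemoglobin (HbO) changes.  The
task-evoked hemodynamic response must be separated from physiological
noise: cardiac pulsation (~1 Hz), respiration (~0.25 Hz), Mayer waves
(~0.1 Hz) and a very-low-frequency oscillation (~0.01 Hz).  A standard
20 s-task / 20 s-rest block design responds at 0.025 Hz — inside the
low-frequency noise range — so reference-based methods (GLM with a
modelled response, adaptive filtering) can mistake noise for activation,
and fail entirely when the task timing is unknown.

`fnirscast` implements a reference-free method:

1. **Decompose** the resting-state signal with the maximal overlap
   discrete wavelet transform (MODWT, `sym4` mother wavelet, depth
   `J = 8`), giving details `D_1 … D_8` and approximation `A_8`
   ("wavelets 1–9"):
   `W_{j,t} = Σ_l h̃°_{j,l} X_{t−l mod n}`, `X = Σ_j D_j + A_J`.
2. **Train** one stacked LSTM forecaster (layers `[128, 64, 32]`,
   dropout 0.2, Adam, one-step MSE) per low-frequency wavelet (5–9).
3. **Forecast** each component recursively 244 samples (30 s at
   8.138 Hz) into the task window — preserving the phase of the ongoing
   oscillations across the rest/task boundary.
4. **Subtract** the summed forecasts from the measured task segment; the
   residual is the part resting-state dynamics cannot explain, i.e. the
   putative evoked response.  The forecast error itself separates task
   windows with and without a response (Welch two-sample t-test per
   wavelet).

A labelled synthetic HbO generator (AR(30) baseline + four band-limited
oscillations + optional two-gamma response) and the full validation
protocol (segmentation conditions, windowed error analysis,
leave-one-subject-out evaluation) are included.  See the methods
vignette (`vignettes/physiological-noise-filtering.Rmd`) for the model,
parameter and design details.

## Worked example

Simulate 30 labelled records (half carrying a hemodynamic response),
run the 60-s decomposition / 60-s training condition on wavelet 8 with a
small forecaster, and compare the two groups:

```r
library(fnirscast)

ds  <- fnirs_simulate(n_records = 30, master_seed = 11)
cfg <- forecaster_config(hidden_units = c(32, 16, 8), max_epochs = 10,
                         minibatch = 128, lookback = 32,
                         steps_per_epoch = 30, seed = 3)
ex  <- run_synthetic_experiment(ds, condition = 6, config = cfg,
                                split_seed = 2, levels = 8,
                                n_train = 24, n_test = 6)
tidy(ex)
#> # A tibble: 2 × 12
#>   condition_id wavelet_level group            n mae_mean mae_std rmse_mean
#>          <int>         <int> <chr>        <int>    <dbl>   <dbl>     <dbl>
#> 1            6             8 with_dhrf        3     5.09   1.21       5.96
#> 2            6             8 without_dhrf     3     1.02   0.330      1.09
#>   rmse_std p_value_mae p_value_rmse significance_mae significance_rmse
#>      <dbl>       <dbl>        <dbl> <chr>            <chr>
#> 1    1.49       0.0218       0.0266 *                *
#> 2    0.268      0.0218       0.0266 *                *
```

Errors are in normalized units (z-score of each record's resting
wavelet-8 component).  Test records containing a response are ~5x harder
to forecast in the 0.016–0.032 Hz band than noise-only records — that
gap *is* the detection signal: the forecaster, trained on rest only,
cannot anticipate the task-evoked deviation.  `windowed_metrics(ex)`
shows the gap growing with the scoring window as the slow response
rises; `autoplot(ex)` draws the per-wavelet bar chart;
`denoise_task_segment()` applies the subtraction to a single record.

A command-line interface wrapping the same functions is installed at
`inst/cli/fnirscast` (subcommands `simulate`, `decompose`, `train`,
`predict`, `denoise`, `evaluate`, `experiment`).

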