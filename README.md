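# t2relax

Rician-aware T2 relaxometry: simulation, least-squares and neural-network
fitting, and SNR-resolved error analysis for multi-echo spin-echo (MESE)
T2 mapping.

## The problem

Voxel-wise T2 maps are obtained by fitting the mono-exponential decay

```
|S(TE)| = S0 · exp(−TE / T2)
```

to the magnitudes measured at a series of echo times. Magnitude MR data
carry **Rician** noise: with per-channel Gaussian noise of standard
deviation σ, the measured magnitude never averages below the Rayleigh
floor σ·√(π/2). At low SNR (= S0/σ) this floor biases the naive fit —
T2 is systematically overestimated — which matters in articular cartilage,
where diagnostically relevant T2 differences are a few milliseconds.

`t2relax` implements four per-voxel estimators and everything needed to
characterize them:

| Method | Model | Needs σ? | Low-SNR signature |
|---|---|---|---|
| `fit_lse` | `S0·exp(−TE/T2)` | no | overestimates T2 |
| `fit_olse` | `S0·exp(−TE/T2) + c` | no | overcorrects, underestimates |
| `fit_nclse` | Rician mean of the decay | yes | nearly unbiased |
| `train_t2net` / `predict` | 6-layer, 512-wide MLP trained on synthetic decays | no | nearly unbiased, smallest error |

plus a calibrated synthetic decay generator (shifted log-normal T2 prior
with mode 50 ms and 95% mass below 210 ms; uniform-plus-exponential-tail
S0 prior; random 5–15-echo trains), relative-error metrics (RQE/ARQE),
Mood's median test, an image-domain pipeline with NIfTI I/O, and a
cartilage-like synthetic phantom.

All randomness is seedable; simulations, training, and fits are exactly
reproducible.

## Worked example

Generate 2,000 synthetic decays pinned at SNR 5, fit them with the three
least-squares methods, and summarize the T2 error against the generating
truth:

```r
library(t2relax)

d <- simulate_fixed_snr(2000, snr = 5, seed = 2024)
fits <- dplyr::bind_rows(
  fit_decays(d, "lse"),
  fit_decays(d, "olse"),
  fit_decays(d, "nclse")   # true per-sample sigma supplied automatically
)
error_table(fits)
#> # A tibble: 3 × 8
#>   method   snr     n median_rqe iqr_rqe median_arqe arqe_p2.5 arqe_p97.5
#>   <chr>  <dbl> <int>      <dbl>   <dbl>       <dbl>     <dbl>      <dbl>
#> 1 lse        5  2000      28.3    112.         42.9      1.96       576.
#> 2 nclse      5  2000      -1.31    79.1        35.7      1.70       468.
#> 3 olse       5  2000     -39.9     91.1        61.1      3.16       359.
```

Reading the table: at SNR 5 the traditional fit overestimates T2 by a
median of +28% (signed RQE) and has a median absolute error of 43%; the
offset fit overcorrects (−40%, median ARQE 61%); the noise-corrected fit
is nearly unbiased (−1.3%) and cuts the absolute error to 36%.
`format_error_table(error_table(fits))` renders the conventional
`median [2.5th, 97.5th]` layout, and `autoplot()` draws the error-vs-SNR
figure from a multi-SNR table.

Training the network and fitting an image stack:

```r
net <- train_t2net(simulate_decays(c(train = 2e5), seed = 1),
                   simulate_decays(c(val = 2e4), seed = 2),
                   config = train_config(epochs = 10), seed = 3)

ph  <- make_phantom(shape = c(48, 48), sigma = 100, seed = 4)  # SNR 5
map <- fit_map(ph$noisy, "nn", model = net)
autoplot(map, "t2")
```

A thin command-line wrapper for simulation and image fitting is installed
at `inst/cli/t2map.R` (see its header for usage).

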