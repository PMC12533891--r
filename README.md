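# logmelaci

Eco-acoustic analysis of diel (dawn / noon / night) variation in bird
vocalizations, built around the **Log-Mel Acoustic Complexity Index** — a
variant of the classical ACI computed on a log-compressed 20-band Mel
spectrogram — together with the full processing chain a field recording
needs before any index or classifier can be trusted: spectral-subtraction
denoising, energy/zero-crossing endpoint detection, and pitch-preserving
augmentation. It is aimed at soundscape ecologists and bioacousticians who
want a reproducible, fully tested pipeline from WAV files to diel activity
summaries.

## The indices

The classical Acoustic Complexity Index accumulates, per frequency bin
*b*, the absolute frame-to-frame intensity changes normalized by that
bin's total intensity over a clump of frames:

```
D_b = Σ_t |I_b(t+1) − I_b(t)|          ACI = Σ_b D_b / Σ_t I_b(t)
```

Biotic sound (rapidly modulated chirps) scores high; steady noise scores
low. The ratio makes it invariant to recording gain — and also relatively
insensitive to the subtle rhythm differences a single species shows across
the day.

The Log-Mel variant first maps the magnitude STFT through a 20-filter
triangular Mel bank, compresses with `log(1 + x)`, and then forms the
analogous ratio *per time frame* over Mel bands *k*:

```
d_k(t) = |LogMel(k, t+1) − LogMel(k, t)|
ACI_LogMel(t) = Σ_k d_k(t) / Σ_k LogMel(k, t)
```

The Mel warping concentrates resolution where bird energy lives, and the
log compression amplifies weak syllable onsets relative to loud sustained
energy, so the per-frame series tracks vocal rhythm (syllable rate, call
intervals). A recording-level value is the mean over frames.

## Worked example

```r
library(logmelaci)

# a labeled synthetic diel corpus: 2 species x 3 periods x 5 recordings,
# dawn twice as fast-singing as night, night twice as fast as noon
dd  <- gen_diel_dataset(diel_dataset_spec(n_species = 2, n_per_group = 5, seed = 7))
cmp <- compare_periods(dd$recordings, index_kind = "logmel")
cmp
#> <diel_comparison> logmel ACI over 30 recordings, 2 species
#> # A tibble: 6 × 5
#>   species  period mean_index sd_index     n
#>   <chr>    <chr>       <dbl>    <dbl> <int>
#> 1 species1 dawn        0.150  0.00166     5
#> 2 species1 night       0.135  0.00209     5
#> 3 species1 noon        0.117  0.00160     5
#> 4 species2 dawn        0.145  0.00242     5
#> 5 species2 night       0.131  0.00116     5
#> 6 species2 noon        0.114  0.00160     5
#>   species1: dawn > night > noon
#>   species2: dawn > night > noon
```

The per-group means recover the constructed activity ordering
(dawn > night > noon) for every species. `diel_spread()` turns that into
an effect size — the between-period mean range divided by the pooled
within-period standard deviation:

```r
diel_spread(cmp)
#> # A tibble: 2 × 2
#>   species  spread
#>   <chr>     <dbl>
#> 1 species1   18.9
#> 2 species2   17.3

diel_spread(compare_periods(dd$recordings, index_kind = "traditional"))
#> # A tibble: 2 × 2
#>   species  spread
#>   <chr>     <dbl>
#> 1 species1   3.37
#> 2 species2   1.07
```

The Log-Mel index separates the periods an order of magnitude more
cleanly than the traditional one on the same recordings. `autoplot(cmp)`
draws the grouped bar chart with error bars.

Upstream of the indices, the same package denoises
(`estimate_noise_profile()` + `spectral_subtract()`), segments
(`detect_endpoints()`), augments (`time_stretch()`, `time_shift()`,
`augment_to_minimum()`), extracts second-order MFCC features
(`second_order_mfcc()`, `pool_features()`), and trains the two-layer
species→period classifier (`train_two_layer()`, `evaluate_two_layer()`).

A command-line front end covering the whole chain ships at
`inst/cli/logmelaci` (`logmelaci synth | preprocess | features | aci |
report | classify | augment | convert`).

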