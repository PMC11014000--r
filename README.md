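# mwselect

Choosing a mother wavelet for human activity recognition (HAR) from
body-worn accelerometers.

Wavelet features are widely used to classify activities (sitting,
walking, jogging, stair climbing, …) from tri-axial accelerometer
streams, but the mother wavelet underlying the analysis is usually picked
by habit.  `mwselect` implements a quantitative selection procedure for
researchers and engineers building HAR pipelines: it decomposes fixed
2.5 s signal windows with an n-level wavelet packet transform (WPT),
scores every candidate mother wavelet by the **energy-to-Shannon-entropy
ratio** of its packet coefficients, and verifies the choice downstream
with cross-validated decision-tree and SVM classification of sub-band
features.

## The statistic

For the $m$ pooled terminal-level packet coefficients $C_i$ of one
window,

$$E = \sum_{i=1}^m C_i^2,\qquad
  P_i = C_i^2 / E,\qquad
  S = -\sum_{i=1}^m P_i \log P_i,\qquad
  \xi = E / S,$$

with $0\log 0 := 0$.  A mother wavelet whose shape matches the signal
concentrates the window's energy in few coefficients — high $E$, low
entropy $S$, hence high $\xi$.  Candidates are ranked by the mean $\xi$
over axes and windows, per activity and overall.  Eleven candidates from
six families are registered: haar, db5, db37, sym5, sym18, coif5,
coif14, bior1.3, bior5.5, rbio1.3, rbio5.5.

The transform uses periodized filter-bank cascades on zero-padded dyadic
windows, so Parseval energy conservation and perfect reconstruction hold
to near machine precision for every registered wavelet — these, along
with an independent brute-force reference for the cascade, are enforced
by the test suite.

## Worked example

```r
library(mwselect)

# seeded synthetic benchmark: 6 activities x 120 windows (2.5 s @ 50 Hz),
# 12 simulated subjects per activity
segs <- make_benchmark(seed = 1)

report <- select_mother_wavelet(
  segs, candidates = c("coif14", "db37", "sym18", "db5", "haar", "rbio1.3")
)
print(report)
#> <selection_report> selected mother wavelet: sym18
#>
#>   wavelet activity mean_energy mean_entropy mean_ratio n_segments rank
#> 1   sym18      all    4287.563     3.347309   1471.452        720    1
#> 2  coif14      all    4287.563     3.347774   1469.377        720    2
#> 3    db37      all    4287.563     3.357768   1466.928        720    3
#> 4     db5      all    4287.563     3.356816   1466.441        720    4
#> 5    haar      all    4287.563     3.387923   1457.119        720    5
#> 6 rbio1.3      all    4248.282     3.385460   1444.034        720    6
```

Every orthogonal wavelet captures the same energy (Parseval), so the
ranking is driven by the entropy term: long, smooth, high-vanishing-
moment wavelets (sym18, coif14, db37) represent these oscillatory
signals more sparsely and rank on top, while haar and rbio1.3 rank at
the bottom.  The ratio is in squared signal units (here (m/s²)²) per
nat; ratios from data recorded in g would be ~96× smaller, which is why
the package never converts units silently (`convert_units()`).

Downstream check — does the wavelet choice move classification
performance?

```r
compare_wavelets_classification(segs, c("coif14", "haar"),
                                classifiers = "dt", k = 10, seed = 1)
#>   wavelet classifier balanced_accuracy  macro_f1
#> 1  coif14         dt         0.9361111 0.9361111
#> 2    haar         dt         0.9500000 0.9495109
```

On this synthetic benchmark both wavelets classify well and their gap is
within seed-to-seed noise — per-node sub-band statistics are nearly
sufficient under any orthogonal filter bank for stationary
harmonics-plus-noise signals.  See the methods vignette
(`vignettes/mother-wavelet-selection.Rmd`) for what the generator does
and does not emulate about real recordings.

Real data enter through delimited files:

```r
rec <- read_recording("subject01.csv", recording_schema(sampling_rate = 100))
rec <- resample_recording(rec, 50)
segs <- segment_recording(rec, window_seconds = 2.5)
```

A command-line front end over the same functions ships at
`inst/cli/mwselect.R` with `simulate`, `select` and `evaluate`
subcommands.

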