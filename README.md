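# nichejump

Quantitative analysis of how collective cAMP signalling drives the rapid,
concerted "jump" between cell states in the *Dictyostelium discoideum*
developmental niche — from imaging-derived kymographs and
signalling/transcription coupling statistics to single-cell-transcriptome
jump detection — together with seeded synthetic-data generators that
emulate every input, so the whole pipeline runs and is tested without any
data download.

It is written for researchers quantifying collective signalling and gene
expression dynamics in developing cell populations: image analysts
extracting transcription-spot kymographs and biosensor traces,
and computational biologists classifying genes by their coupling to
oscillatory signals or by their behaviour in signalling mutants.

## The models at the core

**Signalling field.** On the 1-D differentiation axis, wild-type cAMP is a
travelling raised-cosine pulse train right of a moving onset boundary,
`c(x,t) = A·P(φ(t − (x − x_b(t))/v_w) mod 1)`, with the oscillation period
shortening linearly from 8 to 5 min across the movie; an `acaA`-null field
is identically zero; optogenetic (bPAC) stimulation is a spatially uniform
pulse train of chosen interval.

**Gene coupling.** One-step genes (*carA*-like) track the field with a lag:
`r = basal + gain·c(x, t − τ)`, τ = 270 s. Two-step genes (*cafA*-like,
τ = 60 s) are additionally gated by a delayed repressor that integrates
cAMP with a 4-min decay: transcription needs the activator on while the
integrated repressor is below threshold, so 6-min pulse trains silence the
gene and 10-min trains induce it.

**Quantification.** Cross-correlation lags (detrended, z-normalised,
parabolically refined), autocorrelation periods, Theil–Sen inflection
boundaries, induction-onset detection, feeding-front speed and per-section
inter-mound interval box statistics, and a single-cell pipeline —
median-library normalisation, PCA, kernel-density gap ("jump") detection
along PC1, correlation clustering, gene categorisation relative to the jump
boundary (pre-jump / jump / post-jump), and cAMP-dependence classification
against paired `acaA`-null profiles (failed repression / partial induction /
complete loss / retained).

See `vignettes/nichejump-methods.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

Simulate a wild-type niche, couple the *carA* reporter to it, and measure
the signalling→transcription lag:

```r
library(nichejump)

cfg   <- niche_config(duration_min = 180, wave_period_start_min = 6,
                      wave_period_end_min = 6, rng_seed = 1)
truth <- simulate_transcription(simulate_camp_field(cfg), preset_carA())
z     <- zone_mean_traces(truth)
est   <- estimate_lag(z$signal, z$txn)
round(est$lag_s, 1)
#> [1] 269.8
round(est$period_s / 60, 2)
#> [1] 6
```

The lag of ~270 s (4.5 min) is the preset's coupling delay recovered from
the traces, and the period estimate matches the configured 6-min
oscillation. The same generator drives the single-cell analysis:

```r
res <- run_dependence_pipeline(counts_config(rng_seed = 1))
res$n_cells
#> [1] 4743
res$jump_call$jump
#> [1] TRUE
c(res$n_pre_failed, res$n_jump_partial, res$n_post_retained)
#> [1] 46 16  1
```

Of the 54 genes repressed at the jump, 46 (85%) fail to be repressed in
the `acaA`-null condition; 16 of 22 jump genes keep partial induction; and
exactly 1 of 82 post-jump genes retains detectable induction — the
pipeline recovers the fixture's dependence structure blind, from counts
alone.

A command-line wrapper over the same functions is installed at
`inst/cli/nichejump.R` (`simulate`, `quantify`, `couple`, `colony`,
`jump` subcommands).

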