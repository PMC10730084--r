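---
title: "Models and methods behind nichejump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichejump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichejump)
```

# The system

During early *Dictyostelium discoideum* development, cells starving behind
the feeding front switch from single-cell growth behaviour to collective
aggregation. The switch is visible at three scales, and the package models
and quantifies all three:

1. **Transcriptome scale.** A continuous single-cell transcriptomics sample
   across the developmental niche shows two dense cell-state clusters
   separated by a sparsely populated region — a concerted "jump" in global
   gene expression rather than a gradual drift.
2. **Signalling scale.** The jump coincides with the onset of collective
   cAMP oscillations (period shortening from roughly 8 to 5–6 minutes as
   aggregation approaches). Nascent-transcription reporters on jump genes
   oscillate in phase-locked register with the cAMP waves, with
   gene-specific lags.
3. **Colony scale.** The feeding front clears the bacterial lawn at a
   constant speed (about 1.9 µm/min) while mounds form behind it at
   discrete multi-hour intervals, so cells entering the same mound differ
   substantially in starvation age.

Every analysis stage can run on synthetic inputs produced by the package's
own generators, so the full pipeline is testable without any data
download. The generators are first-class, seeded, documented code — not
test fixtures — and their defaults encode the study conditions stated
above.

# The cAMP field model

`simulate_camp_field()` builds the concentration field $c(x, t)$ on a 1-D
differentiation axis (pixel size 0.35 µm, frames every 45 s). In
`wildtype` mode,

$$c(x,t) = A \, P\!\left(\phi(u) \bmod 1\right), \qquad
  u = t - \frac{x - x_b(t)}{v_w},$$

for $x$ right of the onset boundary $x_b(t)$ and zero left of it, where
$P$ is a raised-cosine pulse occupying a `duty_cycle` fraction of the
cycle, $v_w$ the wave speed, and the phase $\phi$ integrates an
instantaneous period that interpolates linearly from
`wave_period_start_min` (8 min) to `wave_period_end_min` (5 min) over the
movie — the oscillations accelerate as aggregation approaches. The
boundary moves toward the undifferentiated side at `onset_advance_um_min`.
The study never states the wave amplitude, duty cycle or boundary speed;
the defaults (amplitude 1, duty 0.5, 0.3 µm/min) are free parameters
chosen once as plausible for an aggregation-stage territory and are not
tuned thereafter. `acaA_null` mode (adenylyl-cyclase-A mutant) is
identically zero; `bpac` mode (optogenetic adenylyl cyclase) is a
spatially uniform raised-cosine pulse train of configurable interval
(6 or 10 min in the experiments) and width. The pulse width default of
3 min reflects the duration of a relayed cAMP transient rather than of
the brief activating light flash; at 45-s sampling it also guarantees
three in-pulse samples, which the induction-onset detector needs.

# Gene coupling models

`simulate_transcription()` adds the transcription-rate layer under a
`gene_preset()`:

* **One-step** (carA-like): $r(x,t) = \text{basal} + \text{gain}\cdot
  c(x, t - \tau)$ with $\tau$ = 270 s. The gene mirrors the cAMP level
  with a lag and is *not* silenced at high pulse frequency.
* **Two-step** (cafA-like): an activator $a(t) = c(x, t-\tau)$ with a
  short lag ($\tau$ = 60 s) is gated by an integrated repressor
  $\rho$ with decay time `repressor_decay_min` (4 min) driven by the cAMP
  input delayed by `repressor_lag_min` (3 min):
  $r = \text{basal} + \text{gain}\cdot a \cdot [\rho < \theta]$.
  Repression acting at a later stage of the oscillation cycle is essential:
  without the delay the repressor loads during the pulse itself and closes
  the gate before the lagged activator opens, and no pulse interval could
  induce the gene. The threshold $\theta$ is calibrated in closed form so
  that, under the reference stimulus (unit-amplitude 3-min pulses at the
  critical interval, default 8 min), the steady-state repressor at the
  centre of the activator window sits exactly at $\theta$. Pulse trains
  with intervals of 6 min or less therefore keep $\rho$ above threshold
  (gene silenced), while 10- and 12-min trains let it decay below
  (gene induced) — the two experimentally printed intervals deterministically
  straddle the gate. The partial penetrance seen experimentally at 10-min
  pulsing (induction in a minority of replicates) is not modelled; the
  default fixture is deterministic so that classification tests are exact.

Sporadic, signalling-independent bursts occur everywhere as a Poisson
process (default 0.5 events/h per position, amplitude 1, two frames),
reproducing the rare transcription events seen in undifferentiated zones
and in the null mutant. In `bpac` mode two niche features are imposed:
cells respond at basal rate during the first `priming_delay_min` (30 min
— priming acts downstream of signal reception, so induction appears at
the end of the delay), and only a `responsive_zone_fraction` of the axis
measured from the differentiated side can respond at all. The study does
not quantify the mechanism of the spatial restriction; the fraction is a
descriptive parameter, not a mechanistic claim.

# Rendering and image quantification

`render_stack()` draws cells as 2-D Gaussian bodies and nascent-
transcription spots as bright puncta whose integrated intensity is
proportional to the local rate; the biosensor channel renders cell pixels
at $F_0(1 - \gamma\, c/c_{max})$ plus Gaussian read noise — the sensor
dims as cAMP rises. Reporter and biosensor cells mix at 1:2.

`detect_spots()` is a difference-of-Gaussians band-pass (σ 1 and 3 px)
with strict local maxima above `median + k·MAD` of the filtered frame and
disc integration (radius 4 px) against an annulus background, plus a
minimum integrated intensity that suppresses residual cell-body
responses. The parameters are matched to the synthetic render, not to any
published detector — the upstream study's exact detector settings are not
public. Detection is 2-D; real z-stacks would be maximum-projected first.

`mask_and_trace()` reproduces the biosensor-trace reduction: reporter
cells (more variable in background) are masked via Otsu thresholding on
the smoothed time-maximum projection of the reporter channel plus 2-px
dilation, cell-containing pixels come from the time-median projection of
the biosensor channel, and the inverted trace `median − trace` rises with
cAMP. Projection-based masks avoid frame-to-frame threshold jitter, which
otherwise adds artifactual variance to the trace. `build_kymograph()`
bins spot intensities into 10-px (3.5 µm) bins by default, with empty
bins at zero.

# Coupling statistics

* **Inflection boundaries** (`find_inflections()`): the position of
  maximum-magnitude spatial derivative of the Gaussian-smoothed profile
  (σ 3 bins), per frame. The study names inflections but never defines
  them; this is the simplest reproducible operationalisation. Frames
  whose strongest derivative falls below 30 % of the best frame emit no
  point — between waves the profile is flat near the boundary and carries
  no positional information. For signalling kymographs the profile is the
  frame-to-frame difference evaluated at wave maxima. Boundary lines are
  Theil–Sen fits (median of pairwise slopes), robust to the sporadic
  transcription outliers; `compare_boundaries()` reports the mean offset
  over the shared time range with a bootstrap CI.
* **Periods** (`estimate_period()`): first autocorrelation peak after lag
  zero with 3-point parabolic refinement, accepted only above a
  $2/\sqrt{n}$ significance floor (the large-sample null level — the
  study reports no null model for oscillation detection, so this floor is
  ours).
* **Lags** (`estimate_lag()`): traces are linearly detrended and
  z-normalised, correlated over all integer frame shifts up to 450 s, and
  the argmax is parabolically refined, ties breaking toward smaller |lag|;
  positive lag means transcription follows signalling. The default window
  is the oscillatory-zone (or responsive-zone) mean trace: whole-field
  means would dilute the oscillatory signal with silent regions. Because
  the wildtype period chirps, the correlation peak at the true lag
  dominates the peaks displaced by one period, which decorrelate.
* **Induction onsets** (`detect_induction()`): a trace is induced when it
  exceeds baseline mean + 3 SD (baseline = first 10 % of frames) for at
  least 3 consecutive frames — one pulse width at 45-s sampling. Shorter
  runs are ignored, which keeps 2-frame sporadic bursts from counting as
  induction.
* **Frequency response** (`classify_frequency_response()`): induced at
  6 and 10 min → one-step; only at 10 min → two-step; neither →
  unresponsive; only at 6 min has no model and is flagged anomalous.

# Colony dynamics

`simulate_colony()` renders a low-magnification lawn (4.2 µm/px — one
150-px section is 0.63 mm) cleared right-to-left at 1.9 µm/min, with
mound events appearing at full brightness and persisting. Per 150-px
section, inter-mound intervals are Gamma (shape 4) truncated at 10 h. The
distribution is parameterised by its **median** (4 h): the printed "once
every 4 h" is the central line of a box plot of pooled intervals, and for
a right-skewed Gamma pinning the mean instead would push the displayed
median toward 3.5 h. Mound centres exclude each other within 12 px, the
spatial footprint of recruitment into an aggregate. The front starts
mid-field, i.e. the right half of the lawn is already cleared when the
movie begins (as in a colony that has been developing before imaging
starts), so sections accrue events over the whole 24-h observation.
Truncation, per-section clearing times and window censoring (an interval
is only observed when both its events fall inside the movie) all pull the
measured pooled median slightly below the distribution's nominal median;
these are properties of the measurement, not of the fit.

`track_front()` finds, per sampled frame (every 5th), the sub-pixel
crossing of the smoothed column-median profile through the midpoint
between lawn and cleared plateau levels, and fits a least-squares line;
the study tracked the front manually, so the automatic rule is ours and
is stated. `detect_mound_events()` thresholds (mounds render brighter
than the lawn), labels connected components and links centroids across
frames; events must persist ≥ 2 frames. `interval_stats()` pools
per-section successive intervals and summarises them with type-7
quartiles and the 1.5×IQR outlier rule. The full field is analysed; the
study restricted one figure to the bottom half of each panel for clarity
only.

# The single-cell fixture and the jump pipeline

`simulate_counts()` draws two replicates (2671 and 2072 cells, 4743 in
total) per condition. Pseudotime $s \in [0,1]$ comes from a four-state
truncated-normal mixture (feeding, starving, aggregating, mound) with an
excluded open interval around the jump position ($s_J = 0.5$,
half-width 0.05) — the gap is the defining feature of the jump. Genes
follow sigmoid programs over $s$: 54 pre-jump genes repressed at the
jump, 22 jump genes induced just before it, 82 post-jump genes induced
after it, plus 78 ribosomal genes repressed at the feeding-to-starving
transition, 100 constant housekeeping genes and a 215-gene
aggregate-upregulated program marking the mound state (the latter two
background sizes follow the marker sets used to annotate the study's
map). Counts are negative binomial (dispersion 0.1) scaled by log-normal
library factors. The `acaA_null` condition rewrites programs per
dependence flag: 46/54 pre-jump genes fail repression (stay high), 16/22
jump genes keep 30 % of their induction amplitude, 6/22 and 81/82 lose
induction completely, one post-jump gene retains its wild-type program,
and the mound program is lost. Those flags *are* the study's printed
class sizes; the pipeline's job is to recover them blind.

What the generator deliberately does not emulate: doublets, ambient RNA,
cell-cycle structure, dropout beyond NB sampling, batch effects beyond a
library-size shift, and any second (fate-separation) transition. Passing
tests therefore demonstrate correctness of the estimators under the
stated generative model, not robustness to every artefact of real
droplet data.

The analysis chain is deliberately plain:

* `normalize_counts()` — per-cell scaling to the median library and
  log1p. Library-size normalisation carries a composition bias (cells
  with a large induced program get larger libraries, deflating their
  normalised values); the categorisation rules below are designed around
  it.
* `embed_cells()` — centred PCA on up to 2000 most-variable genes, 30
  components. PC1 approximates developmental progression; its sign is
  fixed by requiring the ribosomal score to fall along it, exactly as
  stage-marker panels orient the study's maps. A nonlinear embedding adds
  nothing here because the jump is already validated on plain principal
  components; the package therefore implements PCA only.
* `detect_jump()` — kernel density (Silverman bandwidth) along PC1;
  every valley between adjacent modes is scored by prominence (lower
  flanking mode height / valley height) and the most prominent valley is
  the jump if its prominence reaches 2. Modes below 10 % of the density
  maximum are ignored, so a handful of outlier cells cannot fabricate a
  valley. Scoring all valleys rather than only the one between the two
  tallest modes keeps the call correct when a side of the jump itself
  carries sub-structure (two of the four states).
* `correlation_clusters()` — cell–cell Pearson correlation over centred
  genes, average-linkage clustering of `1 − r`, k by maximum mean
  silhouette over 2–8. On the default fixture the silhouette optimum is
  k = 2 and the two clusters are exactly the pre- and post-jump sides:
  the jump is the only true density gap, and a gap dominates any
  silhouette criterion on continuum data. The four developmental states
  are nested inside that split — cutting the same dendrogram at k = 4
  recovers them — which mirrors how the study reports two major
  correlation blocks containing four clusters.
* `categorize_genes()` — three windows along the progression: a spanning
  window (20 % of cells centred on the boundary), the equally wide window
  before it, and everything after it. Repressed genes (post/pre ≤ 0.5)
  are pre-jump. Induced genes (ratio ≥ 2) are split by whether induction
  is already evident immediately before the boundary: the mean over the
  last 3 % of pre-boundary cells must reach 15 % of the gene's profile
  amplitude, measured above the pre-window baseline. The baseline is the
  pre-window mean rather than the profile minimum because of the
  composition bias noted above. Ribosomal genes — repressed long before
  the boundary — fall in neither class and stay unclassified, which is
  the intended behaviour: the pre-jump class is about repression *at* the
  jump.
* `classify_dependence()` — effect-size rules, no hypothesis tests,
  matching how the study reports the classes: pre-jump genes fail
  repression when the knockout late/early ratio stays ≥ 0.5 while the
  wild-type ratio falls ≤ 0.5; induced genes are retained at a knockout
  peak ≥ 50 % of wild type, partial in [10 %, 50 %), lost below 10 %.
  The 50 %/10 % cuts are this package's operationalisation — the study
  reports classes without numeric rules. Knockout profiles are ordered by
  their known collection time (the comparison data are a population time
  course, where time is measured, not inferred).

# Problem sizes and determinism

Every stochastic stage flows from one integer seed per configuration;
identical configurations are bit-identical. The bundled tests and the
acceptance script use the study-scale fixture (4743 cells, ~550 genes)
for the transcriptome results, 3-h traces at 45-s sampling for coupling
statistics (about 240 frames), 24-h colony movies at 5-min frames
(900×60 px), and 20-seed averages for stochastic summaries; smaller
variants of the same configurations are used in unit tests where only
correctness, not calibration, is at stake.

# Known limitations

Space is one-dimensional (the differentiation axis): spiral or target
wave geometry, chemotaxis and aggregation morphodynamics are out of
scope, as are mechanistic ODE models of the cAMP relay, raw-read
simulation, 3-D deconvolution, cell tracking and the post-jump
bottleneck/fate-separation analysis. The two-step gate is the minimal
threshold realisation of activation-plus-delayed-repression, not a fitted
biochemical model. Classification thresholds are fixed effect-size rules;
on real data with unknown class structure they would need sensitivity
analysis rather than the point defaults used here.
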