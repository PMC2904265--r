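# spellerbci

Simulation and offline decoding of ERP-based visual speller
brain–computer interfaces.

## The problem

An oddball visual speller intensifies display elements in rapid succession
(166 ms stimulus onset asynchrony); attending an element enhances the
event-related potentials (P1, N1, P2, N2, P3) evoked by its
intensifications, and a classifier detects these single-trial modulations
to infer the attended symbol. Two design questions drive the analysis this
package implements: does such a speller still work when the user may not
move their eyes (covert attention), and does a layout adapted to
peripheral vision — the two-level Hex-o-Spell, six large discs on a
hexagon with an empty "backdoor" disc — beat the classical row/column
Matrix?

The package is for methods researchers who need a fully verifiable offline
pipeline: every stage runs against a synthetic-EEG generator with known
ground truth, since no public recordings exist for this paradigm.

## What it implements

* **Paradigm** — Matrix (6 rows × 5 columns, 30 symbols, chance 1/30) and
  Hex-o-Spell (6 groups × 6 discs, chance 1/36) layouts; visual-angle
  geometry; constrained pseudo-random intensification schedules (every
  element once per sequence, at least two intervening events before any
  repeat, prequel/sequel padding; 132 events per Matrix trial, 144 per
  Hex-o-Spell trial).
* **Synthetic EEG** — 64-channel recordings as linear superpositions of
  Gaussian component kernels with condition-dependent target gains plus
  1/f colored noise; overt/covert × Matrix/Hex modulation presets.
* **Preprocessing** — anti-aliased downsampling, epoching (−170 to 670 ms,
  170 ms baseline), and the stream-based contamination filters for target
  and nontarget epochs.
* **ERP measurement** — per-condition averages; peak picking with
  mean-amplitude fallback in the standard component windows; posterior /
  midline electrode subsets; target-minus-nontarget difference amplitudes.
* **Classification** — point-biserial temporal-window selection,
  55 × 7 = 385 spatio-temporal features, shrinkage LDA with the analytic
  Ledoit–Wolf intensity, w = Σ(γ)⁻¹(μ₁ − μ₀), Σ(γ) = (1−γ)Σ̂ + γνI;
  two-stage symbol decoding, accuracy-versus-sequences curves, and
  per-electrode / sliding-window discriminability maps.
* **Runner** — `run_experiment()` chains everything per condition with a
  single fanned-out seed; results carry tidy()/glance()/autoplot()
  methods.

## Worked example

A reduced 2 × 2 experiment (3 blocks of two 3-letter words per condition,
recordings simulated at 100 Hz; the study-scale defaults are 3 × 3 words
of 5 letters at 1000 Hz):

```r
library(spellerbci)

cfg <- experiment_config(n_blocks = 3, words_per_block = 2,
                         word_length = 3, fs_sim = 100,
                         do_erp = FALSE, seed = 11)
res <- run_experiment(cfg)
res
#> <experiment_result>
#>   hex / covert: accuracy 66.7% at 10 sequences (12 trials)
#>   hex / overt: accuracy 91.7% at 10 sequences (12 trials)
#>   matrix / covert: accuracy 41.7% at 10 sequences (12 trials)
#>   matrix / overt: accuracy 83.3% at 10 sequences (12 trials)
```

Training always uses block 1, testing blocks 2–3. The numbers are the
fraction of test trials whose symbol is decoded correctly from all 10
sequences: overt attention is near ceiling, covert attention is far lower,
and under covert attention the Hex-o-Spell clearly outperforms the Matrix
— the qualitative pattern the pipeline is built to reproduce (single-seed
numbers at this reduced scale are noisy; the test suite averages 20
seeds). `autoplot(res)` draws the accuracy-versus-sequences curves, and
`chance_level(build_layout("matrix"))` gives the 3.33% / 2.78% floors.

Schedule-level quantities are available without any signal simulation:

```r
sched <- generate_trial_schedule(build_layout("matrix"), "B", seed = 7)
nrow(sched)                                  # 132 intensifications
count_target_intensifications(sched, "core") # 20
```

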