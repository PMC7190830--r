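# wormnav

Quantification of *C. elegans* salt-chemotaxis behavior on linear NaCl
gradients, and of the physiological assays that accompany such studies.

Worms navigate salt gradients with two elementary strategies: a **biased
random walk** (runs last longer when the animal happens to head toward
preferred concentrations) and **klinotaxis** (reorientations preferentially
launch new runs toward preferred concentrations). Aversive conditioning —
pairing salt with food absence — reverses both strategies, turning innate
attraction into learned avoidance. `wormnav` implements the complete
measurement chain for this kind of experiment:

- **Tracking**: dark-worm centroid extraction from bright-field video
  (average background subtraction, Gaussian smoothing, intensity
  thresholding, size-gated blobs, nearest-neighbor linking with
  collision/border termination, 5-min minimum track duration, 1.5 s
  coordinate smoothing, instantaneous speed).
- **Segmentation**: per-sample behavioral states from explicit rules —
  pause (speed < 0.01 mm/s for more than half of a 10 s window), turn
  (vertex angle < 80° between track points 0.3 mm behind/ahead, extended
  over post-turn samples slower than 0.1 mm/s), pirouette (turns separated
  by < 3.8 s), run (everything else, with up/down direction).
- **Indices**, per animal over the first 10 min after release:

  - chemotactic index `⟨v_g⟩ / ⟨s⟩` (mean velocity along the gradient over
    mean crawling speed),
  - biased-random-walk index
    `(⟨len run_up⟩ − ⟨len run_down⟩) / (⟨len run_up⟩ + ⟨len run_down⟩)`,
  - klinotaxis index `(N_up − N_down) / (N_up + N_down)` over qualifying
    (≥ 5 s) post-reorientation runs,
  - quadrant-assay index `(n(A) − n(C)) / (n(A) + n(C))`.

- **Foraging**: roaming/dwelling classification on food (10 s bins in
  speed–angular-speed space, split by the line `Speed = Curvature/450`)
  and off-food local-search state fractions.
- **Physiology**: ΔF/F0 and ratiometric ΔR/R calcium-trace normalization,
  and four-parameter-logistic EC50 fitting of GPCR concentration–response
  series (`y = bottom + (top − bottom)/(1 + 10^((logEC50 − log c)·hill))`).
- **Synthetic data**: a seeded run-and-tumble simulator with independent
  run-length (β) and steering (κ) biases, a video renderer with per-frame
  ground truth, and calcium / dose–response generators — every pipeline
  stage runs without any external data.

## Worked example

Simulate a mock-conditioned-like population (positive biases: salt
attraction) and a conditioned-like population (negative biases: learned
avoidance), then run the analysis exactly as for tracked data:

```r
library(wormnav)
g <- gradient_spec()                 # 0-100 mM over 120 mm, release ~50 mM
w <- analysis_window()               # first 10 min, >= 5 min active

mock <- simulate_population(locomotion_params(brw_bias =  0.4,
                                              klinotaxis_bias =  0.4),
                            g, n_worms = 40, duration_s = 1800, seed = 1)
cond <- simulate_population(locomotion_params(brw_bias = -0.4,
                                              klinotaxis_bias = -0.4),
                            g, n_worms = 40, duration_s = 1800, seed = 2)
colMeans(navigation_indices(mock, g, w)[c("chemotactic", "brw", "klinotaxis")],
         na.rm = TRUE)
colMeans(navigation_indices(cond, g, w)[c("chemotactic", "brw", "klinotaxis")],
         na.rm = TRUE)
```

Output from the bundled drivers (`analysis/01_simulate_populations.R` then
`analysis/03_navigation_indices.R`, which add a weak-reversal "mutant"
condition):

```
mock         n= 40  chemotactic +0.374  brw +0.384  klinotaxis +0.417  mean pos +12.0 mm
conditioned  n= 40  chemotactic -0.370  brw -0.338  klinotaxis -0.427  mean pos -10.8 mm
mutant_cond  n= 40  chemotactic -0.097  brw -0.123  klinotaxis -0.136  mean pos  -3.2 mm
```

All three indices are positive for the attracted population (animals run
longer and steer up-gradient, ending ~12 mm above the release point),
reverse sign after "conditioning", and reverse only weakly for the
attenuated condition — the qualitative signature of learned salt avoidance
and of a learning-defective mutant.

The numbered scripts under `analysis/` form the full workflow — simulate,
render + track video, indices, foraging, physiology — each writing its
tables under `results/`.

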