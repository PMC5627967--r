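# fabsense

Motion artefacts from loosely attached wearable sensors are usually treated
as noise to be eliminated. fabsense is an R package for studying the
opposite idea in a controlled, fully reproducible setting: the motion of the
fabric carrying a sensor acts as a mechanical feature map that can *amplify*
differences between similar motions, making them easier to tell apart.

The package is built for researchers in wearable sensing and activity
recognition who want a desk-scale testbed for that claim. It provides:

* **a physics simulator** of the canonical test rig — a weighted compound
  pendulum (0.57 m) released from the horizontal with an 18 cm fabric strip
  at its tip, modelled as a serial chain of hinged segments, with virtual
  single-axis accelerometers (600 Hz, 10 s, noise + 16-bit quantization) at
  the pendulum tip (R1), fabric middle (F2) and fabric tip (F3), plus a
  rigid-extension control (R2/R3). The two motion classes are swinging with
  and without a tip load (0–3 N);
* **similarity analysis**: cluster matrices `Ψ ∈ R^(6000×10)` of repeated
  trials, mean prototypes `ψ`, Euclidean similarity scores `s = d(ψ, φ′)`,
  min–max normalization over a comparison, and one-way ANOVA group tests;
* **online windowed classification**: half-overlapping windows of `n`
  samples (stride `n/2`), per-window SVM train/predict over leave-one-out
  repeats, 5-fold cross-validated hyperparameters, and window-size sweeps;
* **experiment scenarios**: configuration-driven end-to-end runs
  (rigid vs fabric, 0.5–3 N weight sweep, material comparison, window
  sweep, fixed 250 ms online prediction) writing tidy CSV/JSON artifacts.

## Worked example

Simulate the reference experiment — ten 3 N and ten unloaded trials on
jersey — then ask whether the classes are distinguishable at each sensor:

```r
library(fabsense)

cfg <- apparatus_config(pendulum_spec(), fabric_spec("jersey"))
ds  <- generate_dataset(cfg, trials_per_condition = 10,
                        conditions = c(0, 3), master_seed = 101)
rep <- class_separation_report(ds, c("R1", "F2", "F3"))
rep$summary
#>   sensor condition_a condition_b separation      F df_between df_within       p
#> 1     R1       load0       load3     0.0133 0.0919          1        18 0.76524
#> 2     F2       load0       load3     0.2448 5.9815          1        18 0.02496
#> 3     F3       load0       load3     0.7925 8.6396          1        18 0.00877
```

`separation` places each sensor's between-class similarity scores on a
normalized axis shared by the whole comparison. The rigidly mounted sensor
R1 barely tells the two motions apart (separation 0.013, ANOVA p = 0.77:
the 3 N load leaves its signal at the noise floor), while the fabric-tip
sensor F3 shows a large, significant contrast (separation 0.79, p < 0.01) —
the fabric's secondary swinging amplifies the load's small change in
pendulum period and decay into qualitatively different signals.

Classify online with 250 ms windows:

```r
run <- online_run(ds, "F2", window_spec(150, sample_rate = 600),
                  classifier_spec("gaussian"), seed = 202)
run
#> <online_run> F2 | n = 150 (250 ms) | accuracy 97.9% +/- 2.8% over 20 repeats x 79 windows
```

Each window index trains a fresh SVM on the 19 training trials' windows and
predicts the held-out trial's window, so this is the accuracy of a live
stream classifier that re-decides every 125 ms. At small windows the fabric
sensors' advantage over R1 grows — see `window_sweep()`.

Full scenarios, with all artifacts written to disk:

```r
report <- run_experiment(experiment_config("material_sweep", master_seed = 7,
                                           out_dir = "out/materials"))
```

A thin command-line front end over the same functions lives at
`inst/cli/fabsense.R`:

```sh
Rscript inst/cli/fabsense.R simulate --material jersey --tip-load 3 \
    --trials 10 --seed 42 --out dataset/
Rscript inst/cli/fabsense.R analyze --dataset dataset/ --sensors R1,F2,F3
```

## The science in brief

An accelerometer on a rigid pendulum at radius `d` reads
`(d·θ̈ + g·sinθ)/g = (1 − d/L_eq)·sinθ` — for a bob-dominated pendulum the
tip sensor sits near the centre of percussion and its reading is small and
nearly load-invariant, while the tip *motion in space* that drives the
fabric stays large and carries the load's signature in period, amplitude
and decay envelope. The fabric chain, a driven nonlinear oscillator,
converts that small signature into diverging trajectories; the similarity
and classification analyses quantify how much easier the diverged signals
are to tell apart. The methods vignette
(`vignettes/fabsense-methods.Rmd`) derives the model, documents every
default and its rationale, and states what the simulator does not emulate.
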