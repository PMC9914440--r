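# sptnano

Quantification of membrane-transporter lateral diffusion and nanoscale
clustering from single-molecule imaging, for neurobiology labs studying how
transporters such as the Na–K–2Cl cotransporter NKCC1 move and cluster in
the neuronal plasma membrane. The package covers the full measurement
chain:

* **Quantum-dot single-particle tracking (QD-SPT)** — linking localizations
  into trajectories, removing crossing tracks, and computing
  mean-squared-displacement (MSD) curves, diffusion coefficients, explored
  areas, synaptic dwell times and compartment labels against marker masks;
* **STORM nanocluster analysis** — sliding-window drift correction,
  repeated-detection merging, histogram rendering and density-threshold
  nanocluster segmentation (area, detections, molecular density);
* **Widefield quantification** — background flattening, cluster
  number/area/intensity in a dendritic ROI, surface/total ratio, and
  background-subtracted ratiometric traces;
* **Statistics matched to these data** — log-normalization by the control
  median, Welch-t vs Mann–Whitney selection, and a balanced Monte-Carlo
  Mann–Whitney procedure for observations clustered within neurons and
  cultures;
* **A seeded synthetic-data generator** for all of the above, with ground
  truth, so every estimator is verifiable without raw acquisitions.

## The core quantities

For a trajectory of `N` positions at frame interval `τ`, the time-averaged
MSD at lag `n` is

    MSD(nτ) = 1/(N−n) · Σ_{i=1..N−n} [(x_{i+n}−x_i)² + (y_{i+n}−y_i)²]

The diffusion coefficient is `D = slope/4` of an OLS line through the first
four MSD points (origin excluded), whose intercept estimates `4σ_loc²`
(σ_loc ≈ 25 nm localization accuracy). The explored area `EA` is the MSD at
0.42 s and 0.45 s. Dwell time is total synaptic residence divided by the
number of exits, with sub-five-frame dwells flagged. Trajectories are
synaptic within 760 nm (4 camera pixels at 190 nm) of a marker mask,
extrasynaptic beyond it. STORM nanoclusters are 8-connected components of
the 20 nm-pixel rendered image above 1% of its intensity maximum, kept at
≥ 10 detections and ≥ 0.1 detections/nm², with `density × area =
detections` by construction. See the vignette
(`vignettes/quantifying-transporter-dynamics.Rmd`) for the models, the
design decisions and their limits.

## Worked example

Simulated control vs treated SPT experiment (free diffusion at
0.1 µm²/s vs confined diffusion at 0.03 µm²/s in 0.25 µm domains,
120 QDs each, 1200 frames at 30 ms):

```r
library(sptnano)
sim_group <- function(D, model, r, n, seed0) lapply(seq_len(n), function(k)
  simulate_trajectory(traj_sim_config(
    n_frames = 1200, diffusion_coeff = D, motion_model = model,
    confinement_radius = r, seed = seed0 + k))$trajectory)
ctrl <- sim_group(0.10, "free_brownian", NULL, 120, 0)
trt  <- sim_group(0.03, "confined_ou", 0.25, 120, 500)
pop <- summarize_population(c(ctrl, trt),
  condition = rep(c("control", "treated"), each = 120), max_lag = 16)
pop$summary
#>  condition compartment n_qds n_ea_values   median_D  median_EA n_nonpositive_D
#>    control         all   120         240 0.09905453 0.17193924               0
#>    treated         all   120         240 0.02582807 0.03733658               0
choose_and_test(
  pop$per_trajectory$D[pop$per_trajectory$condition == "control"],
  pop$per_trajectory$D[pop$per_trajectory$condition == "treated"])
#> test: welch_t, statistic = 124.2, p = 2.56e-142
```

The recovered medians sit on the simulated truths (0.1 and ~0.026 µm²/s —
the confined median is slightly below its free-equivalent because the MSD
of confined motion already bends over the first four lags), the explored
area drops with confinement, and the test layer picks Welch's t because
both fitted-D samples pass normality.

A STORM stream (two planted clusters, linear stage drift) through the
post-processing chain:

```r
sim <- simulate_storm(storm_sim_config(
  n_frames = 20000,
  clusters = data.frame(cx = c(0, 1500), cy = c(0, 0),
                        radius = c(300, 200), n_emitters = c(2000, 900)),
  mean_bursts = 2, mean_burst_len = 5, localization_sigma = 5,
  drift_model = "linear", drift_rate = c(0.005, 0.002), seed = 7))
trace     <- estimate_drift(sim$detections)     # 2000-frame sliding windows
corrected <- apply_drift(sim$detections, trace)
mols      <- merge_detections(corrected)        # 2σ / 15 s merging
img       <- render_detections(corrected)       # 20 nm pixels
segment_nanoclusters(img, min_density = 0.01, molecules = mols)
#> 28868 detections -> 1747 molecules
#>  cluster_id n_pixels   area n_detections    density n_molecules
#>           1      876 350400        20491 0.05847888        1184
#>           2      431 172400         8377 0.04859049         561
```

Both planted clusters are recovered with areas close to the planted
π·300² ≈ 283,000 nm² and π·200² ≈ 126,000 nm² (the pixelized outline of a
histogram rendering is slightly generous; see the vignette).

End-to-end runs — simulate → metrics → statistics with a manifest of
parameters, seeds, exclusion counts and output checksums — go through
`run_pipeline()` with a config list or YAML file.

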