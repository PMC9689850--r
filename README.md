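# sodpselect

Epileptic seizure detection from multichannel scalp EEG via the geometry of
the **second-order difference plot (SODP)** and hybrid metaheuristic
**feature selection**.

During a seizure, scalp EEG amplitude rises sharply and spike–wave
complexes appear. The SODP — the scatter of successive first differences
`x(i) = s(i+1) − s(i)` versus `y(i) = s(i+2) − s(i+1)` — makes this visible
geometrically: ictal windows stretch the plot, interictal windows
concentrate it. `sodpselect` is for signal-processing and neuroinformatics
researchers who want a complete, testable implementation of this pipeline:

* **Preprocessing** — a minimal EDF reader/writer, bipolar montage
  selection, sliding 20 s / 15 s-overlap windowing with strict-containment
  seizure labeling, and zero-phase FIR decomposition into the δ (0–4 Hz),
  θ (4–8), α (8–15) and β (15–30 Hz) bands.
* **Ten geometric descriptors** per band-filtered window: the Poincaré
  ellipse axes and area (`STD1`, `STD2`, `STD = π·STD1·STD2`), the sum of
  cosines of inter-vector angles (SAV), radial scattering
  (`SDC = Σ√(x²+y²)`), triangle areas (STA), distance to the identity line
  (`SSHD = Σ|x−y|/√2`), centroid drift (SCC), trajectory length (SSVL) and
  the central tendency measures CTM-0.3/0.4/0.5 (fraction of points within
  ρ× the plot's radial extent).
* **Feature selection** — real-valued particles threshold at 0 into 0/1
  feature masks; a mask's fitness is the stratified 10-fold cross-validated
  accuracy of a Gaussian naive Bayes classifier. Optimizers: GA, PSO,
  AsyLnCPSO (asynchronously scheduled learning factors, c1 2.5→0.5,
  c2 0.5→2.5) and the hybrid **AsyLnCPSO-GA** (swarm update + genetic pass
  per iteration), plus the Rastrigin/Sphere/Rosenbrock/Schwefel benchmark
  functions used to validate them.
* **A synthetic EEG generator** (1/f background with band oscillations,
  spike–wave burst seizures, interictal discharges, correlated channels)
  so every stage is testable without downloading a clinical corpus, and
  reporting helpers (one-way ANOVA, [0,1] normalization, key-feature
  occurrence and band-contribution tables).

## Worked example

Generate a labeled synthetic dataset, extract δ-band SODP features, test a
group difference, and search for the best feature subset:

```r
library(sodpselect)

cfg <- synth_config(n_seizure = 30, n_free = 30)        # 23 ch, 256 Hz, 20 s
ds  <- gen_dataset(cfg, seed = 42)
features <- extract_features(lapply(ds$segments, band_decompose,
                                    band = "delta"))
head(features[, c("segment_id", "label", "STD", "SDC", "CTM03")], 4)
#>   segment_id        label     STD   SDC  CTM03
#> 1    syn0001 seizure_free 0.47265  8394 0.6369
#> 2    syn0002 seizure_free 0.08575  3535 0.6767
#> 3    syn0003      seizure 0.60757  9571 0.5812
#> 4    syn0004      seizure 1.52197 12224 0.7897

anova_oneway(features$SDC[features$label == "seizure"],
             features$SDC[features$label == "seizure_free"])
#> SDC : F = 40.64  p = 3.26e-08
```

Radial scattering is far higher in the seizure group (and the central
tendency measures are lower: CTM-0.5 gives F = 25.6, p = 4.5e-06 — the
ictal plot empties its center relative to its extent). Now the selection:

```r
sc  <- swarm_config(dim = 10, lower = -1, upper = 1, iterations = 100,
                    trials = 10, mode = "AsyLnCPSO-GA", seed = 42)
res <- select_features(features, sc)
res
#> feature selection (AsyLnCPSO-GA, bands delta): accuracy min 0.9000 / mean 0.9150 / max 0.9167
#> best mask: delta.SAV, delta.STA, delta.CTM05

key_feature_frequency(res)$top$delta
#>     band feature fraction
#> 2  delta     SAV      1.0
#> 10 delta   CTM05      1.0
#> 4  delta     STA      0.9
#> 6  delta     SCC      0.1
```

A three-feature combination reaches a mean cross-validated accuracy of
0.915 across 10 trials — above every single-feature accuracy on the same
table — and the occurrence table shows which descriptors the search keeps:
SAV and CTM-0.5 in every trial. Multi-band experiments
(`band_cross_experiment()`) concatenate 10-feature blocks per band
(masks of 20–40 bits) and, on data with informative slow bands, lift the
accuracy of the weaker fast bands.

A command-line front-end with `synth` / `extract` / `benchmark` / `select`
subcommands is installed at `inst/cli/sodpselect.R`.

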