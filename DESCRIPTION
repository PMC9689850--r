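Package: sodpselect
Title: Seizure Detection from EEG via Second-Order Difference Plot
    Geometry and Hybrid PSO-GA Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting epileptic seizures in multichannel scalp
    EEG. Recordings are segmented with a sliding window, decomposed into
    the delta, theta, alpha and beta sub-bands with zero-phase FIR
    filters, and summarized by ten geometric descriptors of the
    second-order difference plot (Poincare-style successive-difference
    scatter): ellipse dispersion, angle sums, distance sums, triangle
    areas and central tendency measures. Feature subsets are selected by
    a hybrid metaheuristic that couples particle swarm optimization with
    asynchronously scheduled learning factors to a genetic algorithm,
    scoring candidate masks with the stratified 10-fold cross-validated
    accuracy of a Gaussian naive Bayes classifier. Includes a minimal
    EDF reader/writer, a synthetic spike-wave EEG generator for
    end-to-end validation, the standard benchmark functions used to
    validate the optimizer, and reporting helpers (one-way ANOVA,
    feature occurrence and band contribution summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
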