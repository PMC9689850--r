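# Feature-subset selection: particles encode 0/1 masks over the per-band
# geometric features; the fitness of a mask is the stratified 10-fold
# cross-validated accuracy of a Gaussian naive Bayes classifier.

#' Canonical band-combination list
#'
#' The 15 combinations of the four sub-bands, in the fixed order used for
#' band-crossing experiments: the four singles, the six pairs, the four
#' triples and the full four-band crossing.
#'
#' @return list of character vectors of band names.
#' @export
band_combos <- function() {
  b <- c("delta", "theta", "alpha", "beta")
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(b, k, simplify = FALSE)), recursive = FALSE)
  # order: singles, pairs, triples, quad (combn already groups by size)
  combos
}

#' Decode a real-valued particle into a feature mask
#'
#' Bit j is set iff the j-th position component is strictly greater than the
#' threshold `tau` (default 0); a component exactly at the threshold decodes
#' to 0. Particle length is 10 x (number of bands), features in the
#' canonical order of [geo_feature_names()] within each band.
#'
#' @param position numeric vector.
#' @param tau decision threshold (default 0).
#' @return integer 0/1 vector of the same length.
#' @export
decode_mask <- function(position, tau = 0) {
  as.integer(position > tau)
}

#' Fit a Gaussian naive Bayes model
#'
#' Class priors plus per-class, per-feature Gaussian conditionals with
#' population variances. All variances are smoothed by
#' `eps = 1e-9 x max feature variance` (computed over the pooled training
#' data) so degenerate features keep finite log-likelihoods.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels (coerced to character), at least two classes with
#'   at least two samples each.
#' @return list of class `nb_model`: `classes` (sorted), `log_prior`,
#'   `mean`, `var` (class x feature matrices), `eps`.
#' @export
nb_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) stop("need at least two samples per class")
  pooled_var <- apply(X, 2, pop_var)
  eps <- 1e-9 * max(pooled_var, .Machine$double.eps)
  mu <- matrix(0, length(classes), ncol(X),
               dimnames = list(classes, colnames(X)))
  va <- mu
  for (ci in seq_along(classes)) {
    Xc <- X[y == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(Xc)
    va[ci, ] <- colMeans(Xc^2) - mu[ci, ]^2
  }
  va <- pmax(va, 0) + eps
  structure(list(classes = classes,
                 log_prior = log(as.numeric(counts) / length(y)),
                 mean = mu, var = va, eps = eps),
            class = "nb_model")
}

#' Predict class labels with a Gaussian naive Bayes model
#'
#' Argmax over classes of `log prior + sum_f log N(x_f; mean, var)`. Ties go
#' to the first class in sorted label order.
#'
#' @param model an [nb_fit()] result.
#' @param X samples x features matrix (same feature order as in fitting).
#' @return character vector of predicted labels.
#' @export
nb_predict <- function(model, X) {
  X <- as.matrix(X)
  k <- length(model$classes)
  ll <- matrix(0, nrow(X), k)
  for (ci in seq_len(k)) {
    v <- model$var[ci, ]
    centered <- sweep(X, 2, model$mean[ci, ])
    ll[, ci] <- model$log_prior[ci] -
      0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(centered^2, 2, v, "/"))
  }
  model$classes[max.col(ll, ties.method = "first")]
}

# restore-on-exit seeded evaluation, leaving the caller's RNG untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Stratified cross-validation fold assignment
#'
#' Samples are canonically ordered by (label, id) before the seeded
#' within-class shuffle, so the assignment is a function of the sample
#' identities and the seed only — permuting table rows does not change which
#' sample lands in which fold.
#'
#' @param labels class labels.
#' @param ids unique sample identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold index (1..k) per sample, aligned with the input.
#' @export
make_folds <- function(labels, ids, k = 10, seed = 1L) {
  labels <- as.character(labels); ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (min(table(labels)) < k)
    stop("fewer samples in a class (", min(table(labels)),
         ") than folds (", k, ")")
  fold <- integer(length(ids))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      ix <- which(labels == cl)
      ix <- ix[order(ids[ix])]           # canonical within-class order
      ix <- ix[sample.int(length(ix))]   # seeded shuffle
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

# core CV accuracy on a prepared matrix; folds precomputed
cv_accuracy <- function(X, y, fold, cols) {
  k <- max(fold)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    m <- nb_fit(X[!te, cols, drop = FALSE], y[!te])
    acc[f] <- mean(nb_predict(m, X[te, cols, drop = FALSE]) == y[te])
  }
  mean(acc)
}

#' Assemble the design matrix for a band combination
#'
#' Joins per-band feature tables on `segment_id` and concatenates their ten
#' feature columns band-major in the canonical band order
#' (delta, theta, alpha, beta). A single table is used as-is.
#'
#' @param tables a single feature table ([extract_features()] output) or a
#'   named list of them, one per band.
#' @param bands bands to use (default: all bands present in `tables`).
#' @return list with `X` (matrix), `y` (labels), `ids`, `bands`,
#'   `feature_names` (band-qualified, length `10 x length(bands)`).
#' @export
feature_matrix <- function(tables, bands = NULL) {
  fn <- geo_feature_names()
  canon <- c("delta", "theta", "alpha", "beta")
  if (is.data.frame(tables)) {
    tb <- unique(tables$band)
    if (length(tb) != 1L) stop("single table must contain a single band")
    tables <- stats::setNames(list(tables), tb)
  }
  if (is.null(bands)) bands <- names(tables)
  bands <- canon[canon %in% bands]
  if (length(bands) == 0) stop("unknown band combination")
  missing_b <- setdiff(bands, names(tables))
  if (length(missing_b) > 0)
    stop("missing band table(s): ", paste(missing_b, collapse = ", "))
  ids <- Reduce(intersect, lapply(tables[bands], function(t) t$segment_id))
  if (length(ids) == 0) stop("no shared segment ids across band tables")
  ids <- sort(ids)
  blocks <- lapply(bands, function(b) {
    t <- tables[[b]]
    t <- t[match(ids, t$segment_id), , drop = FALSE]
    as.matrix(t[, fn, drop = FALSE])
  })
  X <- do.call(cbind, blocks)
  colnames(X) <- unlist(lapply(bands, function(b) paste(b, fn, sep = ".")))
  t1 <- tables[[bands[1]]]
  y <- t1$label[match(ids, t1$segment_id)]
  list(X = X, y = y, ids = ids, bands = bands,
       feature_names = colnames(X))
}

#' Cross-validated naive-Bayes accuracy of one feature mask
#'
#' Stratified k-fold cross-validation (training:test ratio (k-1):1) of the
#' Gaussian naive Bayes classifier restricted to the masked features. Fold
#' assignment depends only on the sample identities and `seed`, so repeated
#' calls with the same table, mask and seed are identical, and all masks
#' evaluated under one seed share the same folds. An empty mask scores 0.
#'
#' @param tables feature table(s), as in [feature_matrix()].
#' @param mask integer 0/1 vector of length `10 x n_bands`.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param bands bands to use (default all in `tables`).
#' @return mean fold accuracy in \[0, 1\].
#' @export
cv_fitness <- function(tables, mask, folds = 10, seed = 1L, bands = NULL) {
  fm <- feature_matrix(tables, bands)
  mask <- as.integer(mask)
  if (length(mask) != ncol(fm$X))
    stop("mask length ", length(mask), " != ", ncol(fm$X), " features")
  if (!any(mask == 1)) return(0)
  fold <- make_folds(fm$y, fm$ids, k = folds, seed = seed)
  cv_accuracy(fm$X, fm$y, fold, which(mask == 1))
}

#' Select a feature subset for one band combination
#'
#' Runs the configured optimizer (maximizing) over real-valued particles of
#' length `10 x n_bands`; positions decode to masks by thresholding at 0 and
#' are scored by [cv_fitness()]. Folds are frozen once per experiment from
#' `config$seed` and shared by all trials, so fitness is a deterministic
#' function of the mask and accuracies are comparable across trials; mask
#' evaluations are cached. With `iterations = 0` the result is the best mask
#' of the random initial population.
#'
#' @param tables feature table(s), as in [feature_matrix()].
#' @param config a [swarm_config]; `dim`, bounds and `direction` are
#'   overridden to fit the problem (positions in \[-1, 1\], maximize).
#' @param bands band combination (default all bands in `tables`).
#' @param folds CV folds (default 10).
#' @return list of class `selection_result`: `best_mask`, `best_features`,
#'   `best_accuracy`, `min`/`max`/`mean` over trial bests, `trial_accuracy`,
#'   `trial_masks`, `mean_trace`, `bands`, `n_masks_evaluated`,
#'   `elapsed_s`.
#' @export
select_features <- function(tables, config, bands = NULL, folds = 10) {
  stopifnot(inherits(config, "swarm_config"))
  t0 <- proc.time()[["elapsed"]]
  fm <- feature_matrix(tables, bands)
  L <- ncol(fm$X)
  cfg <- swarm_config(dim = L, lower = -1, upper = 1,
                      pop_size = config$pop_size,
                      iterations = config$iterations,
                      trials = config$trials,
                      w = config$w, c1 = config$c1, c2 = config$c2,
                      c1_start = config$c1_start, c1_end = config$c1_end,
                      c2_start = config$c2_start, c2_end = config$c2_end,
                      crossover_rate = config$crossover_rate,
                      mutation_rate = config$mutation_rate,
                      mode = config$mode, direction = "maximize",
                      seed = config$seed)
  fold <- make_folds(fm$y, fm$ids, k = folds, seed = config$seed)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fitness <- function(pos) {
    bits <- decode_mask(pos)
    key <- paste(bits, collapse = "")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- if (!any(bits == 1)) 0
           else cv_accuracy(fm$X, fm$y, fold, which(bits == 1))
      cache[[key]] <- v
    }
    v
  }
  summary <- run_trials(fitness, cfg)
  masks <- lapply(summary$trajectories,
                  function(tr) decode_mask(tr$gbest_position))
  best_k <- which.max(summary$best_fitness)
  best_mask <- masks[[best_k]]
  structure(list(best_mask = best_mask,
                 best_features = fm$feature_names[best_mask == 1],
                 best_accuracy = summary$best_fitness[best_k],
                 min = summary$min, max = summary$max, mean = summary$mean,
                 trial_accuracy = summary$best_fitness,
                 trial_masks = masks,
                 mean_trace = summary$mean_trace,
                 bands = fm$bands,
                 feature_names = fm$feature_names,
                 n_masks_evaluated = length(ls(cache)),
                 elapsed_s = proc.time()[["elapsed"]] - t0,
                 mode = cfg$mode),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("feature selection (%s, bands %s): accuracy min %.4f / mean %.4f / max %.4f\n",
              x$mode, paste(x$bands, collapse = "-"), x$min, x$mean, x$max))
  cat("best mask:", paste(x$best_features, collapse = ", "), "\n")
  invisible(x)
}

#' Band-crossing feature-selection experiment
#'
#' Runs [select_features()] for each requested band combination and
#' optimizer mode, and summarizes minimum/maximum/mean accuracy, mean
#' selected feature dimension and mean runtime per cell.
#'
#' @param tables named list of per-band feature tables.
#' @param config a [swarm_config] (its `mode` is overridden per run).
#' @param combos list of band combinations (default: all 15).
#' @param modes optimizer modes to run (default: the mode in `config`).
#' @param folds CV folds (default 10).
#' @return list with `results` (nested `results[[combo]][[mode]]`) and
#'   `summary` (one data.frame row per combo x mode).
#' @export
band_cross_experiment <- function(tables, config, combos = band_combos(),
                                  modes = config$mode, folds = 10) {
  results <- list()
  rows <- list()
  for (combo in combos) {
    cname <- paste(combo, collapse = "-")
    missing_b <- setdiff(combo, names(tables))
    if (length(missing_b) > 0)
      stop("missing band table(s): ", paste(missing_b, collapse = ", "))
    results[[cname]] <- list()
    for (m in modes) {
      cfg <- config; cfg$mode <- m
      res <- select_features(tables, cfg, bands = combo, folds = folds)
      results[[cname]][[m]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        combo = cname, mode = m,
        min = res$min, max = res$max, mean = res$mean,
        mean_dim = mean(vapply(res$trial_masks, sum, numeric(1))),
        mean_time_s = res$elapsed_s / config$trials,
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, summary = do.call(rbind, rows))
}
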