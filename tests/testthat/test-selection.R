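# Mask encoding, Gaussian naive Bayes, CV fitness and feature selection.

test_that("particle positions decode to masks by strict thresholding", {
  pos <- c(-0.2, 0.8, -0.1, -0.9, 0.3, -0.4, -0.5, -0.6, -0.7, 0.9)
  mask <- decode_mask(pos)
  expect_equal(mask, c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(geo_feature_names()[mask == 1], c("SAV", "SSHD", "CTM05"))
  expect_equal(decode_mask(rep(-1, 10)), rep(0L, 10))
  expect_equal(decode_mask(c(0, 0, 1))[1:2], c(0L, 0L))  # 0 is not selected
})

test_that("naive Bayes fitting recovers class moments", {
  set.seed(33)
  n <- 1000
  X <- matrix(c(rnorm(n, -1), rnorm(n, 1)), ncol = 1)
  y <- rep(c("a", "b"), each = n)
  m <- nb_fit(X, y)
  expect_equal(unname(m$mean[, 1]), c(-1, 1), tolerance = 0.1)
  expect_equal(unname(m$var[, 1]), c(1, 1), tolerance = 0.15)
  expect_equal(m$log_prior, c(log(0.5), log(0.5)))

  X2 <- cbind(X, X)
  m2 <- nb_fit(X2, y)
  expect_equal(m2$mean[, 1], m2$mean[, 2])
  expect_equal(m2$var[, 1], m2$var[, 2])

  expect_error(nb_fit(X, rep("a", 2 * n)), "two classes")
  expect_error(nb_fit(X[1:3, , drop = FALSE], c("a", "a", "b")),
               "two samples per class")
})

test_that("naive Bayes predicts by the closed-form boundary and tie rule", {
  m <- list(classes = c("neg", "pos"), log_prior = log(c(0.5, 0.5)),
            mean = matrix(c(-1, 1), 2, 1,
                          dimnames = list(c("neg", "pos"), "f")),
            var = matrix(c(1, 1), 2, 1), eps = 0)
  class(m) <- "nb_model"
  expect_equal(nb_predict(m, matrix(0.9)), "pos")
  expect_equal(nb_predict(m, matrix(-0.2)), "neg")
  expect_equal(nb_predict(m, matrix(0)), "neg")  # tie -> first sorted label
})

test_that("degenerate features keep finite log-likelihoods", {
  set.seed(4)
  X <- cbind(rnorm(40), rep(5, 40))  # one constant column
  y <- rep(c("a", "b"), 20)
  m <- nb_fit(X, y)
  expect_true(all(is.finite(m$var)))
  pred <- nb_predict(m, X)
  expect_true(all(pred %in% c("a", "b")))
})

test_that("our Gaussian NB agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(61)
  n <- 120
  X <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
             matrix(rnorm(n * 3, 1.2), ncol = 3))
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("a", "b"), each = n)
  ours <- nb_predict(nb_fit(X, y), X)
  ref <- e1071::naiveBayes(data.frame(X), y)
  theirs <- as.character(predict(ref, data.frame(X)))
  expect_gt(mean(ours == theirs), 0.995)
})

test_that("fold assignment is stratified and row-order invariant", {
  tab <- make_planted_table(n_per_class = 50)
  fold <- make_folds(tab$label, tab$segment_id, k = 10, seed = 3)
  for (f in 1:10) {
    expect_equal(sum(fold == f & tab$label == "seizure"), 5)
    expect_equal(sum(fold == f & tab$label == "seizure_free"), 5)
  }
  set.seed(1)
  perm <- sample(nrow(tab))
  fold_p <- make_folds(tab$label[perm], tab$segment_id[perm], k = 10, seed = 3)
  expect_equal(fold_p, fold[perm])  # same sample -> same fold
  expect_error(make_folds(rep(c("a", "b"), c(5, 50)), as.character(1:55),
                          k = 10), "fewer samples")
})

test_that("fold assignment leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_folds(rep(c("a", "b"), each = 20), as.character(1:40),
                       k = 5, seed = 7))
  expect_equal(runif(1), before)
})

test_that("CV fitness is 1 for separable classes and ~0.5 under the null", {
  tab <- make_planted_table(n_per_class = 60, planted = 3)
  mask <- integer(10); mask[3] <- 1L
  expect_equal(cv_fitness(tab, mask, seed = 2), 1.0)

  null_tab <- make_noise_table(n_per_class = 200, seed = 13)
  accs <- vapply(1:10, function(s) {
    m <- integer(10); m[s] <- 1L
    cv_fitness(null_tab, m, seed = s)
  }, numeric(1))
  expect_true(all(abs(accs - 0.5) < 0.12))  # individual draws
  expect_lt(abs(mean(accs) - 0.5), 0.04)    # no systematic bias

  expect_equal(cv_fitness(tab, integer(10), seed = 1), 0)  # empty mask
  expect_error(cv_fitness(tab, c(mask, 0L), seed = 1), "mask length")
})

test_that("CV fitness is deterministic and row-permutation invariant", {
  tab <- make_planted_table(n_per_class = 30, planted = 5, seed = 19)
  mask <- decode_mask(rnorm(10))
  if (!any(mask == 1)) mask[1] <- 1L
  a <- cv_fitness(tab, mask, seed = 8)
  b <- cv_fitness(tab, mask, seed = 8)
  expect_identical(a, b)
  set.seed(2)
  tab_p <- tab[sample(nrow(tab)), ]
  expect_equal(cv_fitness(tab_p, mask, seed = 8), a)
})

test_that("selection recovers a planted predictive feature", {
  tab <- make_planted_table(n_per_class = 60, planted = 3, seed = 23)
  cfg <- small_swarm_config(trials = 8, seed = 41)
  res <- select_features(tab, cfg)
  hits <- vapply(res$trial_masks, function(m) m[3] == 1L, logical(1))
  expect_gte(sum(hits), 7)           # nearly every trial keeps the feature
  expect_equal(res$best_mask[3], 1L)
  expect_gte(res$best_accuracy, 0.99)
  expect_true(res$min <= res$mean && res$mean <= res$max)
})

test_that("selection with zero iterations is the best of the initial swarm", {
  tab <- make_planted_table(n_per_class = 30, planted = 2, seed = 29)
  cfg <- small_swarm_config(trials = 1, seed = 17)
  cfg$iterations <- 0
  res <- select_features(tab, cfg)
  # replicate the seeded initial population and score its masks directly
  fm <- feature_matrix(tab)
  icfg <- swarm_config(dim = 10, lower = -1, upper = 1, pop_size = 20,
                       iterations = 0, trials = 1, mode = cfg$mode,
                       direction = "maximize", seed = 17)
  set.seed(17)
  state <- new.env(); state$n_evals <- 0; state$n_nonfinite <- 0
  neg <- function(X) -apply(rbind(X), 1, function(p) {
    bits <- decode_mask(p)
    if (!any(bits == 1)) 0
    else cv_fitness(tab, bits, seed = 17)
  })
  attr(neg, "vectorized") <- TRUE
  sw <- sodpselect:::init_swarm(neg, icfg, state)
  expect_equal(res$best_accuracy, -sw$gbest_fit)
})

test_that("band crossing assembles features band-major and helps accuracy", {
  informative <- make_planted_table(n_per_class = 50, planted = 4,
                                    band = "delta", seed = 31)
  noise <- make_noise_table(n_per_class = 50, band = "alpha", seed = 37)
  noise$segment_id <- informative$segment_id
  noise$label <- informative$label
  tabs <- list(delta = informative, alpha = noise)

  fm <- feature_matrix(tabs, bands = c("delta", "alpha"))
  expect_equal(ncol(fm$X), 20)
  expect_equal(fm$feature_names[1:3], paste0("delta.", geo_feature_names()[1:3]))
  expect_equal(fm$feature_names[11], "alpha.STD")

  cfg <- small_swarm_config(trials = 4, seed = 43)
  both <- band_cross_experiment(tabs, cfg,
                                combos = list("alpha", c("delta", "alpha")))
  expect_equal(nrow(both$summary), 2)
  acc_alpha <- both$summary$mean[both$summary$combo == "alpha"]
  acc_cross <- both$summary$mean[both$summary$combo == "delta-alpha"]
  expect_gt(acc_cross, acc_alpha)  # informative band lifts the noise band

  solo <- select_features(tabs$delta, cfg)
  one <- band_cross_experiment(tabs, cfg, combos = list("delta"))
  expect_equal(one$results$delta[[cfg$mode]]$trial_accuracy,
               solo$trial_accuracy)

  expect_error(band_cross_experiment(tabs["delta"], cfg,
                                     combos = list(c("delta", "theta"))),
               "missing band")
})

test_that("there are exactly 15 canonical band combinations", {
  combos <- band_combos()
  expect_length(combos, 15)
  expect_equal(vapply(combos, length, integer(1)),
               c(rep(1, 4), rep(2, 6), rep(3, 4), 4))
  expect_equal(combos[[15]], c("delta", "theta", "alpha", "beta"))
})
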