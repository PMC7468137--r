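test_that("binarization thresholds strictly and guards against empty masks", {
  expect_equal(binarize_position(c(1, 1, 1)), rep(TRUE, 3))
  expect_equal(binarize_position(c(0.2, 0.7, 0.5)), c(FALSE, TRUE, FALSE))
  z <- binarize_position(c(0.1, 0.4, 0.3))
  expect_equal(z, c(FALSE, TRUE, FALSE)) # argmax guard
  expect_equal(sum(binarize_position(rep(0, 5))), 1)
})

test_that("wrapper fitness matches hand arithmetic and sparsity pressure", {
  expect_equal(fs_fitness(1, 100, 100), 0.99)
  expect_equal(fs_fitness(1, 1, 100), 0.99 + 0.01 * 0.99)
  expect_equal(fs_fitness(0, 100, 100), 0)
  # bounded in [0,1] and strictly decreasing in subset size
  set.seed(1)
  for (i in 1:50) {
    acc <- runif(1)
    f <- vapply(1:5, function(k) fs_fitness(acc, k, 5), numeric(1))
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) < 0))
  }
})

test_that("confusion metrics match hand formulas", {
  m <- confusion_metrics(matrix(c(40, 5, 10, 45), 2, 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 40 / 45)
  expect_equal(m$f_measure, 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
  # perfect diagonal
  p <- confusion_metrics(diag(c(10, 20)))
  expect_true(all(unlist(p) == 1))
  # degenerate all-one-class predictions
  d <- confusion_metrics(matrix(c(50, 50, 0, 0), 2, 2))
  expect_equal(d$specificity, 0)
  expect_equal(d$sensitivity, 1)
})

test_that("metrics agree with brute-force recomputation on random matrices", {
  set.seed(2)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    conf <- matrix(rpois(k * k, 10), k, k)
    m <- confusion_metrics(conf)
    total <- sum(conf)
    expect_equal(m$accuracy, sum(diag(conf)) / total)
    sens <- spec_ <- prec <- fm <- numeric(k)
    for (j in 1:k) {
      tp <- conf[j, j]
      fn <- sum(conf[j, ]) - tp
      fp <- sum(conf[, j]) - tp
      tn <- total - tp - fn - fp
      sens[j] <- if (tp + fn == 0) 0 else tp / (tp + fn)
      spec_[j] <- if (tn + fp == 0) 0 else tn / (tn + fp)
      prec[j] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      fm[j] <- if (prec[j] + sens[j] == 0) 0 else 2 * prec[j] * sens[j] / (prec[j] + sens[j])
    }
    if (k == 2) {
      expect_equal(m$sensitivity, sens[1])
      expect_equal(m$specificity, spec_[1])
      expect_equal(m$precision, prec[1])
      expect_equal(m$f_measure, fm[1])
    } else {
      expect_equal(m$sensitivity, mean(sens))
      expect_equal(m$specificity, mean(spec_))
      expect_equal(m$precision, mean(prec))
      expect_equal(m$f_measure, mean(fm))
    }
    expect_equal(m$recall, m$sensitivity)
  }
})

test_that("subset evaluation separates a separable cloud and is deterministic", {
  d <- synth_descriptors(
    n_samples = 120, n_informative = 1, n_noise = 3,
    effect_size = 10, seed = 1
  )
  rep1 <- evaluate_subset(d, "class", "f01", seed = 1)
  expect_equal(rep1$accuracy, 1)
  rep2 <- evaluate_subset(d, "class", "f01", seed = 1)
  expect_identical(rep1$confusion, rep2$confusion)
  # hold-out protocol also works
  rep3 <- evaluate_subset(d, "class", "f01", folds = 1, seed = 1)
  expect_equal(sum(rep3$confusion), 24)
  # unknown feature names error
  expect_error(evaluate_subset(d, "class", "nope"), "unknown feature")
})

test_that("permuted labels give chance-level accuracy", {
  accs <- vapply(1:10, function(s) {
    d <- synth_descriptors(
      n_samples = 500, n_informative = 2, n_noise = 2,
      effect_size = 2, seed = s
    )
    d$class <- withr::with_seed(1000 + s, sample(d$class))
    evaluate_subset(d, "class", seed = s)$accuracy
  }, numeric(1))
  expect_true(all(accs > 0.4 & accs < 0.6))
})

test_that("the wrapper objective caches masks and punishes failures as worst", {
  d <- synth_descriptors(n_samples = 60, seed = 3)
  ds <- hawkfs:::as_fs_dataset(d, "class")
  obj <- hawkfs:::make_fs_objective(ds$x, ds$y, seed = 3)
  v1 <- obj(rep(1, 20))
  v2 <- obj(rep(0.9, 20))
  expect_identical(v1, v2) # same mask, cached
  expect_lte(v1, 0)
  expect_gte(v1, -1)
})

test_that("select_features finds the separating feature on a tiny task", {
  d <- synth_descriptors(
    n_samples = 100, n_informative = 1, n_noise = 4,
    effect_size = 8, seed = 5
  )
  fit <- select_features(d, "class",
    optimizer = "chho-cs", n_agents = 10,
    n_iter = 15, seed = 5
  )
  expect_true("f01" %in% fit$selected)
  expect_s3_class(fit, "hawk_fs")
  expect_equal(length(fit$mask), 5)
  expect_true(all(diff(fit$trace$objective) <= 0))
  expect_equal(fit$fitness, -min(fit$trace$objective))
  # determinism end-to-end
  fit2 <- select_features(d, "class",
    optimizer = "chho-cs", n_agents = 10,
    n_iter = 15, seed = 5
  )
  expect_identical(fit$selected, fit2$selected)
  expect_identical(fit$trace, fit2$trace)
})

test_that("reserved and unknown optimizer names error clearly", {
  d <- synth_descriptors(n_samples = 40, seed = 1)
  expect_error(
    select_features(d, optimizer = "pso"),
    "pluggable"
  )
  expect_error(
    select_features(d, optimizer = "banana"),
    "valid names"
  )
})
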