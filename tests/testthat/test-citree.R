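scheme4 <- grade_scheme("tree1")

test_that("train_test_split partitions reproducibly at the requested fraction", {
  co <- simulate_cohort(sim_config(n = 10, seed = 2))
  parts <- train_test_split(co, 0.8, seed = 99)
  expect_identical(nrow(parts$train), 8L)
  expect_identical(nrow(parts$test), 2L)
  expect_setequal(c(parts$train$patient_id, parts$test$patient_id),
                  co$patient_id)
  parts2 <- train_test_split(co, 0.8, seed = 99)
  expect_identical(parts, parts2)

  co4 <- simulate_cohort(sim_config(n = 4, seed = 2))
  ph <- train_test_split(co4, 0.5, seed = 1)
  expect_identical(c(nrow(ph$train), nrow(ph$test)), c(2L, 2L))
  expect_error(train_test_split(co4[1, ], 0.5, seed = 1), "at least 2")
  expect_error(train_test_split(co4, 1.2, seed = 1), "fraction")
})

test_that("influence scores are equally spaced band indices", {
  expect_identical(influence_scores(c("0-2", "3", "4", "5"), scheme4), 1:4)
  expect_identical(influence_scores(rep("3", 5), scheme4), rep(2L, 5))
  expect_identical(influence_scores(as.character(0:5), "full"), 1:6)
  expect_error(influence_scores("7", scheme4), "not in scheme")
})

test_that("node_test flags degenerate predictors with the p = 1 sentinel", {
  res <- node_test(rep(1L, 20), rep(c(1, 2), 10), "ordinal")
  expect_identical(res$p.value, 1)
  expect_identical(res$df, 0L)
  res2 <- node_test(rep(c(1L, 2L), 10), rep(2, 20), "nominal")
  expect_identical(res2$p.value, 1)
})

test_that("a perfectly separating predictor is overwhelmingly significant", {
  x <- rep(c(1L, 2L), each = 50)
  y <- rep(c(1, 4), each = 50)
  expect_lt(node_test(x, y, "ordinal")$p.value * 7, 1e-6)
  expect_lt(node_test(x, y, "nominal")$p.value * 7, 1e-6)
})

test_that("analytic permutation moments match Monte-Carlo moments", {
  set.seed(42)
  n <- 30
  B <- 20000
  for (type in c("ordinal", "nominal")) {
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    res <- node_test(x, y, type)
    g <- if (type == "ordinal") matrix(as.numeric(x), ncol = 1) else
      outer(x, sort(unique(x)), `==`) * 1
    idx <- replicate(B, sample.int(n))
    Tmat <- crossprod(g, matrix(as.numeric(y)[idx], n, B))
    mc_mean <- rowMeans(Tmat)
    centered <- Tmat - mc_mean
    mc_cov <- tcrossprod(centered) / (B - 1)
    se_mean <- apply(Tmat, 1, stats::sd) / sqrt(B)
    expect_true(all(abs(mc_mean - res$mu) <= 3 * se_mean + 1e-12))
    # covariance entries within 3 MC standard errors
    p <- nrow(Tmat)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      prods <- centered[i, ] * centered[j, ]
      se_cov <- stats::sd(prods) / sqrt(B)
      expect_lt(abs(mc_cov[i, j] - res$sigma[i, j]), 3 * se_cov + 1e-9)
    }
  }
})

test_that("p-values are invariant to affine score rescaling and nominal relabelling", {
  set.seed(8)
  x <- sample(1:3, 60, replace = TRUE)
  y <- sample(1:4, 60, replace = TRUE) + 0.3 * (x == 2)
  p0 <- node_test(x, y, "ordinal")$p.value
  expect_equal(node_test(x, 10 * y - 3, "ordinal")$p.value, p0,
               tolerance = 1e-9)
  pn <- node_test(x, y, "nominal")$p.value
  relabel <- c(5L, 9L, 2L)[x]   # arbitrary new codes, same partition
  expect_equal(node_test(relabel, y, "nominal")$p.value, pn,
               tolerance = 1e-9)
})

test_that("the chi-square approximation tracks the Monte-Carlo permutation p-value", {
  set.seed(21)
  x <- sample(1:3, 80, replace = TRUE)
  y <- as.numeric(sample(1:4, 80, replace = TRUE)) + (x == 3)
  res <- node_test(x, y, "ordinal", nresample = 5000)
  expect_lt(abs(res$p.value - res$p.mc),
            3 * sqrt(res$p.mc * (1 - res$p.mc) / 5000) + 0.01)
})

test_that("Bonferroni variable selection follows the adjusted p-values", {
  mk <- function(p, df = 1L) structure(list(p.value = p, df = df),
                                       class = "citree_test")
  sel <- select_variable(list(a = mk(0.001), b = mk(0.2)), alpha = 0.05)
  expect_false(sel$stop)
  expect_identical(sel$var, "a")
  expect_equal(sel$p.adjusted, 0.002)

  expect_true(select_variable(list(a = mk(0.04), b = mk(0.04)),
                              alpha = 0.05)$stop)
  sel3 <- select_variable(list(a = mk(0.049)), alpha = 0.05)
  expect_false(sel3$stop)
  # degenerate candidates are not counted in the correction
  sel4 <- select_variable(list(a = mk(0.03), b = mk(1, df = 0L)),
                          alpha = 0.05)
  expect_identical(sel4$var, "a")
  expect_equal(sel4$p.adjusted, 0.03)
  expect_error(select_variable(list()), "no candidate")
})

test_that("select_split maximizes the two-sample statistic under minbucket", {
  # binary predictor: the only admissible split
  x <- rep(c(1L, 2L), each = 10)
  y <- c(rep(1, 10), rep(3, 10))
  sp <- select_split(x, y, "ordinal", minbucket = 3)
  expect_identical(sp$threshold, 1L)

  # target mean jumps between codes 2 and 3: threshold after code 2
  x3 <- rep(c(1L, 2L, 3L), each = 10)
  y3 <- c(rep(1, 20), rep(4, 10))
  expect_identical(select_split(x3, y3, "ordinal", minbucket = 3)$threshold, 2L)

  # all splits violate minbucket -> no split
  expect_null(select_split(rep(c(1L, 2L), c(3, 17)), rnorm(20), "ordinal",
                           minbucket = 5))
  # nominal split returns a code subset
  spn <- select_split(x3, y3, "nominal", minbucket = 3)
  expect_setequal(spn$left_codes, c(1L, 2L))
})

test_that("nodes below minsplit become leaves immediately", {
  co <- simulate_cohort(sim_config(n = 49, seed = 9))
  fit <- grow_tree(co, scheme4, citree_control(minsplit = 50))
  expect_true(fit$node$terminal)
  fit2 <- grow_tree(co, scheme4, citree_control(minsplit = 20))
  expect_false(fit2$node$terminal)
})

test_that("tree growth is deterministic and recovers planted structure", {
  co <- simulate_cohort(sim_config(n = 600, seed = 31))
  f1 <- grow_tree(co, scheme4)
  f2 <- grow_tree(co, scheme4)
  expect_identical(f1, f2)

  parts <- train_test_split(co, 0.8, seed = 17)
  fit <- grow_tree(parts$train, scheme4)
  acc <- mean(predict(fit, parts$test) == band_label(parts$test$mrs, scheme4))
  expect_gte(acc, 0.95)
})

test_that("prediction ties resolve toward the less severe band", {
  # a cohort with equal counts in bands 3 and 4 and no informative
  # predictor grows a single leaf predicting the lower band
  co <- rbind(
    do.call(rbind, replicate(10, {
      p <- canonical_profile_for_grade(3)
      data.frame(patient_id = "x", mrs = 3L, t(p))
    }, simplify = FALSE)),
    do.call(rbind, replicate(10, {
      p <- canonical_profile_for_grade(3)
      data.frame(patient_id = "y", mrs = 4L, t(p))
    }, simplify = FALSE)))
  fit <- grow_tree(co, scheme4, citree_control(minsplit = 10, minbucket = 5))
  expect_true(fit$node$terminal)
  expect_identical(fit$node$prediction, "3")
  expect_identical(unique(predict(fit, co)), "3")
})

test_that("fitted trees survive JSON serialization", {
  co <- simulate_cohort(sim_config(n = 400, seed = 13, noise = 0.05))
  fit <- grow_tree(co, scheme4)
  path <- withr::local_tempfile(fileext = ".json")
  write_citree(fit, path)
  back <- read_citree(path)
  expect_identical(predict(back, co), predict(fit, co))
  expect_identical(back$scheme$name, fit$scheme$name)
})
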