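labs4 <- grade_scheme("tree1")$labels

test_that("confusion_matrix counts pairs and is permutation invariant", {
  cm <- confusion_matrix(c("0-2", "3"), c("0-2", "3"), labs4)
  expect_identical(diag(cm), c(`0-2` = 1L, `3` = 1L, `4` = 0L, `5` = 0L))

  cm2 <- confusion_matrix("3", "0-2", labs4)
  expect_identical(cm2["3", "0-2"], 1L)
  expect_identical(sum(cm2), 1L)

  set.seed(1)
  true <- sample(labs4, 50, replace = TRUE)
  assigned <- sample(labs4, 50, replace = TRUE)
  perm <- sample(50)
  expect_identical(confusion_matrix(true, assigned, labs4),
                   confusion_matrix(true[perm], assigned[perm], labs4))

  expect_error(confusion_matrix(c("3", "4"), "3", labs4), "length")
  expect_error(confusion_matrix("6", "3", labs4), "not among band labels")
})

test_that("accuracy and the no-information rate follow their definitions", {
  d <- matrix(c(5, 0, 0, 7), 2, 2)
  expect_equal(classification_accuracy(d), 1)
  expect_equal(classification_accuracy(matrix(c(0, 3, 2, 0), 2, 2)), 0)
  expect_equal(classification_accuracy(matrix(c(2, 1, 1, 4), 2, 2,
                                              byrow = TRUE)), 0.75)

  # row sums 50, 30, 20 -> NIR 0.5
  cm <- matrix(0, 3, 3); cm[1, ] <- c(40, 5, 5); cm[2, ] <- c(10, 15, 5)
  cm[3, ] <- c(5, 5, 10)
  expect_equal(no_information_rate(cm), 0.5)
  expect_equal(no_information_rate(matrix(1, 4, 4)), 1 / 4)
  one_class <- matrix(0, 3, 3); one_class[2, 2] <- 12
  expect_equal(no_information_rate(one_class), 1)
  expect_error(classification_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("quadratic weights match the Fleiss-Cohen closed form", {
  for (k in 2:6) expect_equal(diag(quadratic_weights(k)), rep(1, k))
  w4 <- quadratic_weights(4)
  expect_equal(w4[1, 4], 0)
  expect_equal(w4[1, 2], 8 / 9)
  expect_true(isSymmetric(w4))
  expect_error(quadratic_weights(1), "at least 2")
})

test_that("weighted kappa hits its closed-form anchors", {
  expect_equal(weighted_kappa(diag(c(5L, 9L, 2L, 7L)))$estimate, 1)

  # independence-structured matrix: p_obs = row x col exactly
  r <- c(0.5, 0.3, 0.2); s <- c(0.2, 0.5, 0.3)
  cm <- outer(r, s) * 1000
  expect_equal(weighted_kappa(cm)$estimate, 0, tolerance = 1e-12)

  fixed <- matrix(c(10, 2, 0, 3, 8, 2, 0, 1, 9), 3, 3, byrow = TRUE)
  expect_equal(weighted_kappa(fixed)$estimate,
               oracle_weighted_kappa(fixed, quadratic_weights(3)),
               tolerance = 1e-12)

  # scale invariance: x10 counts leave Kw unchanged, SE shrinks
  k1 <- weighted_kappa(fixed)
  k10 <- weighted_kappa(fixed * 10)
  expect_equal(k10$estimate, k1$estimate, tolerance = 1e-12)
  expect_lt(k10$se, k1$se)
  expect_true(k1$conf_int[1] <= k1$estimate && k1$estimate <= k1$conf_int[2])

  expect_error(weighted_kappa(matrix(c(10, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("identity weights reproduce unweighted Cohen's kappa", {
  set.seed(7)
  for (rep in 1:20) {
    cm <- random_cm(4)
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    expect_equal(weighted_kappa(cm, weights = diag(4))$estimate,
                 (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("kappa is invariant under simultaneous row/column/weight permutation", {
  set.seed(11)
  w <- quadratic_weights(4)
  for (rep in 1:10) {
    cm <- random_cm(4)
    p <- sample(4)
    expect_equal(weighted_kappa(cm[p, p], weights = w[p, p])$estimate,
                 weighted_kappa(cm, weights = w)$estimate, tolerance = 1e-12)
  }
})

test_that("moving off-diagonal mass onto the diagonal raises Kw with accuracy", {
  cm <- matrix(c(20, 6, 0, 4, 15, 3, 1, 2, 9), 3, 3, byrow = TRUE)
  k0 <- weighted_kappa(cm)$estimate
  cm2 <- cm; cm2[1, 2] <- cm2[1, 2] - 3; cm2[1, 1] <- cm2[1, 1] + 3
  expect_gt(classification_accuracy(cm2), classification_accuracy(cm))
  expect_gt(weighted_kappa(cm2)$estimate, k0)
})

test_that("Landis-Koch interpretation follows the printed cut-offs", {
  expect_identical(interpret_kappa(0.81), "almost perfect")
  expect_identical(interpret_kappa(0.67), "substantial")
  expect_identical(interpret_kappa(0.58), "moderate")
  expect_identical(interpret_kappa(0.20), "slight")
  expect_identical(interpret_kappa(0.21), "fair")
  expect_identical(interpret_kappa(-0.5), "slight")
  # unprinted gap resolves by rounding half-up to two decimals
  expect_identical(interpret_kappa(0.805), "almost perfect")
  expect_identical(interpret_kappa(0.804), "substantial")
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("misclassification profile splits the off-diagonal mass", {
  expect_equal(misclassification_profile(diag(c(3L, 4L, 5L))),
               c(under = 0, over = 0))
  above <- matrix(0, 3, 3); above[1, 3] <- 10
  expect_equal(misclassification_profile(above), c(under = 0, over = 1))
  cm <- matrix(c(2, 1, 1, 4), 2, 2, byrow = TRUE)
  expect_equal(misclassification_profile(cm), c(under = 1 / 8, over = 1 / 8))
})

test_that("agreement reports reconcile their proportions and serialize", {
  set.seed(5)
  cm <- random_cm(4)
  rep <- agreement_report(cm)
  expect_equal(rep$accuracy + rep$under + rep$over, 1, tolerance = 1e-12)
  expect_identical(rep$n, sum(cm))
  js <- jsonlite::fromJSON(report_json(rep))
  expect_equal(js$accuracy, rep$accuracy)
  expect_equal(js$kappa$estimate, rep$kappa$estimate)
})
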