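# Independent oracles kept deliberately separate from the package code
# paths they check.

# Literal clause-by-clause evaluator of the published transformation rules,
# written as plain boolean expressions (no rule engine).
oracle_map <- function(a) {
  q1 <- a[["q1"]]; q2 <- a[["q2"]]; q3 <- a[["q3"]]; q4 <- a[["q4"]]
  q5 <- a[["q5"]]; q6 <- a[["q6"]]; q7 <- a[["q7"]]
  if (q2 == 3 && q3 == 3 && q4 == 2 && q5 == 2) return("5")
  if ((q3 == 3 || q4 == 2 || q5 == 2) && q6 == 2 && q7 == 3) return("4")
  if ((q1 == 2 || q2 == 2 || q3 == 1 || q3 == 2) && q6 == 2) return("3")
  if ((q1 == 3 || q1 == 4 || q6 == 1 || q6 == 2 || q7 == 1 || q7 == 2) &&
      q2 == 1 && q3 == 1 && q4 == 1 && q5 == 1) return("0-2")
  "unclassified"
}

# Full enumeration of the valid (analysis) answer-code space: 648 vectors.
enumerate_answer_space <- function() {
  grid <- expand.grid(q1 = 2:4, q2 = 1:3, q3 = 1:3, q4 = 1:2,
                      q5 = 1:2, q6 = 1:2, q7 = 1:3,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, paste0("q", 1:7)]
}

# Direct-summation weighted kappa: explicit loops over cells, no reuse of
# package internals.
oracle_weighted_kappa <- function(cm, w) {
  n <- sum(cm)
  k <- nrow(cm)
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    po <- po + w[i, j] * cm[i, j] / n
    pe <- pe + w[i, j] * (sum(cm[i, ]) / n) * (sum(cm[, j]) / n)
  }
  (po - pe) / (1 - pe)
}

# Random confusion matrix with strictly positive total count.
random_cm <- function(k, lambda = 8) {
  repeat {
    m <- matrix(stats::rpois(k * k, lambda), k, k)
    if (sum(m) > 0 && !isTRUE(all.equal(
          sum(quadratic_weights(k) * outer(rowSums(m), colSums(m))) / sum(m)^2,
          1)))
      return(m)
  }
}

# A tiny complete cohort built by hand (all records classifiable).
tiny_cohort <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3", "A4"),
    mrs = c(5L, 4L, 3L, 0L),
    q1 = c(2L, 2L, 2L, 4L),
    q2 = c(3L, 2L, 2L, 1L),
    q3 = c(3L, 3L, 2L, 1L),
    q4 = c(2L, 2L, 1L, 1L),
    q5 = c(2L, 2L, 1L, 1L),
    q6 = c(2L, 2L, 2L, 1L),
    q7 = c(3L, 3L, 3L, 1L),
    stringsAsFactors = FALSE)
}
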