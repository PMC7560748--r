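#' Control parameters for conditional inference tree growth
#'
#' @param alpha Significance level for the multiplicity-adjusted variable
#'   selection test; a node becomes a leaf when no candidate predictor is
#'   significant at this level (default 0.05).
#' @param minsplit Minimum node size at which a split is attempted
#'   (default 50, curbing overfitting on registry-sized cohorts).
#' @param minbucket Minimum size of a child node (default 7).
#' @param maxdepth Maximum tree depth; `Inf` (default) for no limit.
#' @param teststat Test-statistic form; only the quadratic form is
#'   implemented.
#' @param nresample Optional number of Monte-Carlo permutations for a
#'   resampling p-value alongside the chi-square approximation (used for
#'   verification; `NULL` disables).
#' @param seed Seed for the Monte-Carlo resampling draw (ignored when
#'   `nresample` is `NULL`).
#' @return A list of class `citree_control`.
#' @export
citree_control <- function(alpha = 0.05, minsplit = 50L, minbucket = 7L,
                           maxdepth = Inf, teststat = "quad",
                           nresample = NULL, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (minsplit < 2L * minbucket)
    stop("minsplit must be at least 2 * minbucket", call. = FALSE)
  teststat <- match.arg(teststat, "quad")
  structure(list(alpha = alpha, minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket), maxdepth = maxdepth,
                 teststat = teststat, nresample = nresample, seed = seed),
            class = "citree_control")
}

#' Split a cohort into training and test sets
#'
#' Random disjoint partition with `round(fraction * n)` training records
#' (clamped so both parts are non-empty), reproducible given the seed.
#'
#' @param cohort A cohort `data.frame`.
#' @param fraction Training fraction in (0, 1); default 0.80.
#' @param seed Integer seed for the partition draw.
#' @return List with components `train` and `test`.
#' @export
train_test_split <- function(cohort, fraction = 0.8, seed) {
  n <- nrow(cohort)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  ntrain <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  idx <- sample.int(n, ntrain)
  train <- cohort[sort(idx), , drop = FALSE]
  test <- cohort[-sort(idx), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Influence scores for an ordinal band target
#'
#' Maps band labels to equally spaced integer scores (1..k in scheme order),
#' the influence function `h(y)` of the linear association statistic.  The
#' resulting p-values are invariant under affine rescaling of the scores.
#'
#' @param bands Character vector of band labels.
#' @param scheme The `mrs_scheme` defining band order.
#' @return Integer score vector.
#' @export
influence_scores <- function(bands, scheme) {
  scheme <- grade_scheme(scheme)
  sc <- match(bands, scheme$labels)
  if (anyNA(sc))
    stop("band label(s) not in scheme: ",
         paste(unique(bands[is.na(sc)]), collapse = ", "), call. = FALSE)
  sc
}

# transformation g(x): ordinal predictors enter by their raw code,
# nominal predictors by indicator columns over observed codes
g_matrix <- function(x, type) {
  if (type == "ordinal") {
    matrix(as.numeric(x), ncol = 1L)
  } else {
    lev <- sort(unique(x))
    m <- matrix(0, length(x), length(lev))
    m[cbind(seq_along(x), match(x, lev))] <- 1
    colnames(m) <- as.character(lev)
    m
  }
}

rank_sym <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(abs(ev), 1e-300))
}

#' Permutation association test between one predictor and the target scores
#'
#' Computes the linear statistic `T = sum_i g(x_i) h(y_i)` with its exact
#' conditional (permutation) mean and covariance, standardizes it to a
#' quadratic form via the Moore-Penrose inverse of the covariance, and
#' approximates the p-value by a chi-square distribution with df = rank of
#' the covariance.  A constant predictor (or constant target) yields the
#' sentinel p-value 1 and is never selected for splitting.
#'
#' @param x Predictor values (integer codes) at the node.
#' @param scores Numeric target scores `h(y)` from [influence_scores()].
#' @param type `"ordinal"` (codes enter as scores) or `"nominal"`
#'   (indicator coding).
#' @param nresample Optional Monte-Carlo permutation count: adds an exact
#'   resampling p-value `p.mc` for verification of the approximation.
#' @return A list of class `citree_test`: `statistic`, `df`, `p.value`,
#'   `linear` (the statistic vector), `mu`, `sigma`, and optionally `p.mc`.
#' @export
node_test <- function(x, scores, type = c("ordinal", "nominal"),
                      nresample = NULL) {
  type <- match.arg(type)
  n <- length(x)
  if (n != length(scores)) stop("length mismatch", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  h <- as.numeric(scores)
  degenerate <- length(unique(x)) < 2L || length(unique(h)) < 2L
  g <- g_matrix(x, type)
  tstat <- as.vector(crossprod(g, h))
  hbar <- mean(h)
  vh <- sum((h - hbar)^2) / n
  gsum <- colSums(g)
  mu <- gsum * hbar
  sigma <- vh * (n / (n - 1) * crossprod(g) - tcrossprod(gsum) / (n - 1))
  if (degenerate) {
    res <- list(statistic = 0, df = 0L, p.value = 1,
                linear = tstat, mu = mu, sigma = sigma, type = type)
    class(res) <- "citree_test"
    return(res)
  }
  d <- tstat - mu
  stat <- drop(t(d) %*% MASS::ginv(sigma) %*% d)
  df <- rank_sym(sigma)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  res <- list(statistic = stat, df = df, p.value = p,
              linear = tstat, mu = mu, sigma = sigma, type = type)
  if (!is.null(nresample)) {
    sp <- MASS::ginv(sigma)
    exceed <- 0L
    for (b in seq_len(nresample)) {
      db <- as.vector(crossprod(g, h[sample.int(n)])) - mu
      if (drop(t(db) %*% sp %*% db) >= stat - 1e-12) exceed <- exceed + 1L
    }
    res$p.mc <- (exceed + 1L) / (nresample + 1L)
  }
  class(res) <- "citree_test"
  res
}

#' Bonferroni variable selection over candidate predictors
#'
#' Adjusts each raw p-value by the number of non-degenerate candidates and
#' selects the predictor with the smallest adjusted p-value if it falls
#' below `alpha`; otherwise signals a stop.  Ties break by predictor order.
#'
#' @param tests Named list of `citree_test` results, one per predictor.
#' @param alpha Significance level.
#' @return List with `stop` (logical), and when not stopping `var` (selected
#'   predictor name), `p.raw` and `p.adjusted`.
#' @export
select_variable <- function(tests, alpha = 0.05) {
  if (!length(tests)) stop("no candidate tests", call. = FALSE)
  praw <- vapply(tests, `[[`, numeric(1), "p.value")
  candidates <- vapply(tests, function(t) t$df > 0L, logical(1))
  m <- sum(candidates)
  if (m == 0L) return(list(stop = TRUE))
  padj <- pmin(1, praw * m)
  padj[!candidates] <- 1
  best <- which.min(padj)
  if (padj[best] < alpha)
    list(stop = FALSE, var = names(tests)[best],
         p.raw = unname(praw[best]), p.adjusted = unname(padj[best]))
  else
    list(stop = TRUE)
}

#' Best binary split of the selected predictor
#'
#' Evaluates every admissible binary partition - order-preserving thresholds
#' for ordinal predictors, proper code subsets for nominal ones - by the
#' absolute standardized two-sample linear statistic of the target scores,
#' subject to both children holding at least `minbucket` records.
#'
#' @param x Predictor values at the node.
#' @param scores Target scores.
#' @param type `"ordinal"` or `"nominal"`.
#' @param minbucket Minimum child size.
#' @return `NULL` when no admissible split exists; otherwise a list with
#'   `type`, and `threshold` (ordinal: left child is `x <= threshold`) or
#'   `left_codes` (nominal: left child is `x %in% left_codes`), plus the
#'   standardized criterion value.
#' @export
select_split <- function(x, scores, type = c("ordinal", "nominal"),
                         minbucket = 7L) {
  type <- match.arg(type)
  n <- length(x)
  h <- as.numeric(scores)
  hbar <- mean(h)
  vh <- sum((h - hbar)^2) / n
  if (vh <= 0) return(NULL)
  lev <- sort(unique(x))
  if (length(lev) < 2L) return(NULL)
  parts <- if (type == "ordinal") {
    lapply(lev[-length(lev)], function(t) list(threshold = t,
                                               left = x <= t))
  } else {
    # proper subsets containing the first level, to enumerate each
    # partition once
    subsets <- list()
    rest <- lev[-1]
    for (k in 0:(length(rest) - 1)) {
      if (k == 0) combos <- list(integer(0))
      else combos <- utils::combn(rest, k, simplify = FALSE)
      for (cc in combos) subsets <- c(subsets, list(c(lev[1], cc)))
    }
    lapply(subsets, function(s) list(left_codes = s, left = x %in% s))
  }
  best <- NULL
  best_crit <- -Inf
  for (p in parts) {
    nl <- sum(p$left)
    if (nl < minbucket || n - nl < minbucket) next
    ta <- sum(h[p$left])
    va <- nl * (n - nl) / (n - 1) * vh
    if (va <= 0) next
    crit <- abs(ta - nl * hbar) / sqrt(va)
    if (crit > best_crit + 1e-12) {
      best_crit <- crit
      best <- p
    }
  }
  if (is.null(best)) return(NULL)
  out <- list(type = type, criterion = best_crit)
  if (type == "ordinal") out$threshold <- best$threshold
  else out$left_codes <- best$left_codes
  out
}

#' Grow a conditional inference tree over the questionnaire answers
#'
#' Recursive partitioning in the permutation-test framework: at each node,
#' every candidate question is tested for association with the band target
#' ([node_test()]), the Bonferroni-adjusted best predictor is selected
#' ([select_variable()]), and the node splits at the partition maximizing
#' the standardized two-sample statistic ([select_split()]).  Growth stops
#' when no test is significant at `control$alpha`, when a node holds fewer
#' than `control$minsplit` records, or when no split respects
#' `control$minbucket`.  Leaves predict their modal band; ties resolve
#' toward the less severe band.
#'
#' @param train Training cohort `data.frame` (post-exclusion) with columns
#'   `mrs` and `q1`..`q7`.
#' @param scheme Grade scheme defining the band target.
#' @param control A [citree_control()] list.
#' @param predictors Character vector of predictor columns (default
#'   `q1`..`q7`).
#' @param codebook Code book supplying each question's `ordinal`/`nominal`
#'   type.
#' @return An object of class `citree`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 400, seed = 7))
#' fit <- grow_tree(cohort, grade_scheme("tree1"))
#' table(predict(fit, cohort), band_label(cohort$mrs, "tree1"))
grow_tree <- function(train, scheme, control = citree_control(),
                      predictors = paste0("q", 1:7),
                      codebook = default_codebook()) {
  scheme <- grade_scheme(scheme)
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  if (anyNA(train[, predictors]))
    stop("training data contain missing answers; apply exclusions first",
         call. = FALSE)
  types <- vapply(predictors, function(q) codebook[[q]]$type, character(1))
  y <- collapse_grade(train$mrs, scheme)          # band index 1..k
  h <- as.numeric(y)                              # equally spaced scores
  k <- length(scheme$labels)
  node_id <- 0L

  build <- function(idx, depth) {
    node_id <<- node_id + 1L
    counts <- tabulate(y[idx], nbins = k)
    names(counts) <- scheme$labels
    node <- list(id = node_id, n = length(idx), counts = counts,
                 prediction = scheme$labels[which.max(counts)],
                 terminal = TRUE)
    if (length(idx) < control$minsplit || depth >= control$maxdepth ||
        length(unique(h[idx])) < 2L)
      return(node)
    tests <- lapply(predictors, function(q)
      node_test(train[[q]][idx], h[idx], type = types[[q]]))
    names(tests) <- predictors
    sel <- select_variable(tests, control$alpha)
    if (sel$stop) return(node)
    xv <- train[[sel$var]][idx]
    sp <- select_split(xv, h[idx], type = types[[sel$var]],
                       minbucket = control$minbucket)
    if (is.null(sp)) return(node)
    if (sp$type == "nominal")
      sp$right_codes <- setdiff(sort(unique(xv)), sp$left_codes)
    left <- if (sp$type == "ordinal") xv <= sp$threshold
            else xv %in% sp$left_codes
    node$terminal <- FALSE
    node$var <- sel$var
    node$split <- sp
    node$test <- list(statistic = tests[[sel$var]]$statistic,
                      df = tests[[sel$var]]$df,
                      p.raw = sel$p.raw, p.adjusted = sel$p.adjusted)
    node$majority <- if (sum(left) >= sum(!left)) "left" else "right"
    node$left <- build(idx[left], depth + 1L)
    node$right <- build(idx[!left], depth + 1L)
    node
  }

  root <- build(seq_len(nrow(train)), 0L)
  structure(list(node = root, scheme = scheme, control = control,
                 predictors = predictors, types = types,
                 n = nrow(train)), class = "citree")
}

route_record <- function(node, answers) {
  while (!node$terminal) {
    v <- answers[[node$var]]
    go_left <- if (is.null(v) || is.na(v)) {
      node$majority == "left"
    } else if (node$split$type == "ordinal") {
      v <= node$split$threshold
    } else if (v %in% node$split$left_codes) {
      TRUE
    } else if (v %in% node$split$right_codes) {
      FALSE
    } else {
      # nominal code not seen at this node during training
      node$majority == "left"
    }
    node <- if (go_left) node$left else node$right
  }
  node$prediction
}

#' Predict grade bands from a fitted tree
#'
#' Routes each record down the splits to a leaf and returns the leaf's modal
#' band.  Records with a missing or unseen code at an internal node follow
#' the majority direction of that node's training records.
#'
#' @param object A `citree` model.
#' @param newdata Cohort `data.frame` with the predictor columns.
#' @param ... Unused.
#' @return Character vector of band labels.
#' @export
predict.citree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    route_record(object$node,
                 as.list(newdata[i, object$predictors, drop = FALSE])),
    character(1))
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.citree <- function(x, ...) {
  cat("Conditional inference tree (", x$n, " training records, scheme '",
      x$scheme$name, "')\n", sep = "")
  rec <- function(node, indent, prefix) {
    pad <- strrep("  ", indent)
    if (node$terminal) {
      cat(sprintf("%s%s[%d] leaf n=%d -> band %s (%s)\n", pad, prefix,
                  node$id, node$n, node$prediction,
                  paste(node$counts, collapse = "/")))
    } else {
      cond <- if (node$split$type == "ordinal")
        sprintf("%s <= %s", node$var, node$split$threshold)
      else
        sprintf("%s in {%s}", node$var,
                paste(node$split$left_codes, collapse = ","))
      cat(sprintf("%s%s[%d] n=%d split %s; p = %.4g %s\n", pad, prefix,
                  node$id, node$n, cond, node$test$p.adjusted,
                  p_stars(node$test$p.adjusted)))
      rec(node$left, indent + 1L, "yes: ")
      rec(node$right, indent + 1L, "no:  ")
    }
  }
  rec(x$node, 0L, "")
  invisible(x)
}

#' Serialize / restore a fitted tree as JSON
#'
#' @param model A `citree` object.
#' @param path File path.
#' @return `write_citree()` returns `path` invisibly; `read_citree()`
#'   returns the restored `citree`.
#' @export
write_citree <- function(model, path) {
  strip <- function(node) {
    out <- node
    out$counts <- as.list(node$counts)
    if (!node$terminal) {
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  obj <- list(scheme = model$scheme$name,
              control = unclass(model$control),
              predictors = model$predictors,
              types = as.list(model$types),
              n = model$n,
              node = strip(model$node))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_citree
#' @export
read_citree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(node) {
    node$counts <- unlist(node$counts)
    node$n <- as.integer(node$n)
    node$terminal <- isTRUE(node$terminal)
    if (!node$terminal) {
      if (!is.null(node$split$left_codes))
        node$split$left_codes <- as.integer(unlist(node$split$left_codes))
      if (!is.null(node$split$right_codes))
        node$split$right_codes <- as.integer(unlist(node$split$right_codes))
      if (!is.null(node$split$threshold))
        node$split$threshold <- as.numeric(node$split$threshold)
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  ctl <- obj$control
  control <- citree_control(alpha = ctl$alpha, minsplit = ctl$minsplit,
                            minbucket = ctl$minbucket,
                            maxdepth = if (is.null(ctl$maxdepth)) Inf else ctl$maxdepth,
                            teststat = ctl$teststat,
                            nresample = ctl$nresample, seed = ctl$seed)
  structure(list(node = fix(obj$node), scheme = grade_scheme(obj$scheme),
                 control = control,
                 predictors = unlist(obj$predictors),
                 types = unlist(obj$types), n = as.integer(obj$n)),
            class = "citree")
}
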