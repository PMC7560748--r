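#' Evaluate the manual transformation algorithm on a cohort
#'
#' Runs the complete manual-mapping evaluation: exclusion of records with
#' missing or "Do not know"-type answers, rule-based band assignment,
#' removal of unclassified records, and a full agreement analysis of the
#' assigned bands against the collapsed true grades.  The analysis
#' denominator (classified records only) is always reported alongside the
#' exclusion and unclassified counts, so every loaded record is attributed
#' to exactly one of excluded / unclassified / analysed.
#'
#' @param cohort A cohort `data.frame`, or a path to a cohort CSV.
#' @param ruleset Transformation rules; default [default_ruleset()].
#' @param codebook Answer code book; default [default_codebook()].
#' @param scheme Grade scheme; must have one band per rule target
#'   (the `"tree1"` grouping 0-2/3/4/5 for the default rules).
#' @return An object of class `manual_run`: list with `n_loaded`,
#'   `n_excluded`, `n_unclassified`, `n_analysed`, `report`
#'   (an [agreement_report()]), `mapped` (per-record assignments),
#'   `dropped` (excluded records with reasons) and `scheme`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 300, seed = 3))
#' run <- run_manual_evaluation(cohort)
#' run$report$accuracy
run_manual_evaluation <- function(cohort, ruleset = default_ruleset(),
                                  codebook = default_codebook(),
                                  scheme = grade_scheme("tree1")) {
  if (is.character(cohort)) cohort <- load_cohort(cohort, codebook)
  scheme <- grade_scheme(scheme)
  validate_ruleset(ruleset, codebook)
  rule_bands <- vapply(ruleset$rules, `[[`, character(1), "band")
  if (!setequal(rule_bands, scheme$labels))
    stop("scheme bands do not match the rule set's target bands; ",
         "the default rules require the 'tree1' scheme", call. = FALSE)
  excl <- apply_exclusions(cohort, codebook)
  mapped <- map_cohort(excl$kept, ruleset)
  classified <- mapped[mapped$band != ruleset$no_match, , drop = FALSE]
  if (!nrow(classified))
    stop("no classifiable records: every kept record is unclassified",
         call. = FALSE)
  cm <- confusion_matrix(band_label(classified$mrs, scheme),
                         classified$band, scheme$labels)
  structure(list(
    n_loaded = nrow(cohort),
    n_excluded = nrow(excl$dropped),
    n_unclassified = nrow(mapped) - nrow(classified),
    n_analysed = nrow(classified),
    report = agreement_report(cm),
    mapped = mapped,
    dropped = excl$dropped,
    scheme = scheme
  ), class = "manual_run")
}

#' Run a decision-tree experiment on a cohort
#'
#' Applies the exclusion criteria, splits the analysable records into
#' training (80 percent by default) and test sets, grows a conditional
#' inference tree on the training set, and reports agreement between
#' predicted and true bands separately for the training and test sets.
#' Unlike the rule-based mapping, the tree classifies every record, so
#' there is no unclassified count; the two procedures therefore use
#' different analysis denominators, which the reports state explicitly.
#'
#' @inheritParams run_manual_evaluation
#' @param scheme Grade scheme used as the tree target (any preset).
#' @param control A [citree_control()] list.
#' @param seed Integer seed for the train/test partition (required).
#' @param fraction Training fraction (default 0.80).
#' @return An object of class `tree_run`: list with the fitted `model`,
#'   `train_report` and `test_report` ([agreement_report()]s), the sizes
#'   `n_loaded`, `n_excluded`, `n_train`, `n_test`, plus `seed` and
#'   `scheme`.
#' @export
run_tree_experiment <- function(cohort, scheme, control = citree_control(),
                                seed, fraction = 0.8,
                                codebook = default_codebook()) {
  if (missing(seed)) stop("a seed is required for the train/test split",
                          call. = FALSE)
  if (is.character(cohort)) cohort <- load_cohort(cohort, codebook)
  scheme <- grade_scheme(scheme)
  excl <- apply_exclusions(cohort, codebook)
  parts <- train_test_split(excl$kept, fraction, seed)
  if (nrow(parts$train) < control$minsplit)
    warning("training set smaller than minsplit; fitting a single-leaf model",
            call. = FALSE)
  model <- grow_tree(parts$train, scheme, control, codebook = codebook)
  rep_for <- function(dat) {
    cm <- confusion_matrix(band_label(dat$mrs, scheme),
                           predict(model, dat), scheme$labels)
    agreement_report(cm)
  }
  structure(list(
    model = model,
    train_report = rep_for(parts$train),
    test_report = rep_for(parts$test),
    n_loaded = nrow(cohort),
    n_excluded = nrow(excl$dropped),
    n_train = nrow(parts$train),
    n_test = nrow(parts$test),
    seed = seed,
    scheme = scheme
  ), class = "tree_run")
}

#' Compare the manual algorithm with a fitted tree
#'
#' Side-by-side accuracy, weighted kappa (with CIs), no-information rate and
#' per-band recall for a manual-mapping run and a tree run on the same grade
#' scheme.  Bands that the tree never predicts on the test set are flagged:
#' a classifier can look accurate overall while being unable to identify an
#' entire disability grade.
#'
#' @param manual A `manual_run` object.
#' @param tree A `tree_run` object on the same scheme.
#' @return An object of class `classifier_comparison`: list with a `summary`
#'   data frame (one row per classifier view), a `recall` matrix (bands x
#'   classifier views) and `zero_prediction_bands` (character vector of
#'   flagged bands on the tree's test set).
#' @export
compare_classifiers <- function(manual, tree) {
  if (!inherits(manual, "manual_run") || !inherits(tree, "tree_run"))
    stop("expected a 'manual_run' and a 'tree_run'", call. = FALSE)
  if (!identical(manual$scheme$labels, tree$scheme$labels))
    stop("the two runs use different grade schemes", call. = FALSE)
  views <- list(manual = manual$report,
                tree_train = tree$train_report,
                tree_test = tree$test_report)
  summary <- do.call(rbind, lapply(names(views), function(nm) {
    r <- views[[nm]]
    data.frame(classifier = nm, n = r$n, accuracy = r$accuracy,
               nir = r$nir, kappa = r$kappa$estimate,
               kappa_lower = r$kappa$conf_int[1],
               kappa_upper = r$kappa$conf_int[2],
               stringsAsFactors = FALSE)
  }))
  recall <- vapply(views, function(r) {
    rs <- rowSums(r$confusion)
    ifelse(rs > 0, diag(r$confusion) / rs, NA_real_)
  }, numeric(nrow(manual$report$confusion)))
  rownames(recall) <- rownames(manual$report$confusion)
  zero <- colnames(tree$test_report$confusion)[
    colSums(tree$test_report$confusion) == 0]
  structure(list(summary = summary, recall = recall,
                 zero_prediction_bands = zero),
            class = "classifier_comparison")
}

#' @export
print.manual_run <- function(x, ...) {
  cat("Manual mRS-RS mapping evaluation\n")
  cat(sprintf("  loaded %d | excluded %d | unclassified %d | analysed %d\n",
              x$n_loaded, x$n_excluded, x$n_unclassified, x$n_analysed))
  print(x$report)
  invisible(x)
}

#' @export
print.tree_run <- function(x, ...) {
  cat("Decision-tree experiment (scheme '", x$scheme$name, "', seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  loaded %d | excluded %d | train %d | test %d\n",
              x$n_loaded, x$n_excluded, x$n_train, x$n_test))
  cat("-- training set --\n")
  print(x$train_report)
  cat("-- test set --\n")
  print(x$test_report)
  invisible(x)
}

#' @export
print.classifier_comparison <- function(x, digits = 3, ...) {
  cat("Classifier comparison\n")
  print(x$summary, digits = digits, row.names = FALSE)
  cat("Per-band recall:\n")
  print(round(x$recall, digits))
  if (length(x$zero_prediction_bands))
    cat("WARNING: band(s) never predicted by the tree on the test set: ",
        paste(x$zero_prediction_bands, collapse = ", "), "\n", sep = "")
  invisible(x)
}
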