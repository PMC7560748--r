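#' The default mRS-RS transformation rule set
#'
#' Encodes the published manual mapping from the seven Riksstroke follow-up
#' questions to mRS grade bands as data.  Each rule carries a target band, a
#' disjunction block (`any`: at least one condition must hold; may be empty)
#' and a conjunction block (`all`: every condition must hold).  A condition
#' is a question id together with its allowed answer codes.
#'
#' Rules are evaluated in severity-descending order (5, 4, 3, 0-2) with
#' first-match-wins: this is the only order under which the band-5 rule is
#' reachable, because every vector satisfying it can also satisfy the band-4
#' rule.  Vectors matching no rule get the `"unclassified"` outcome - the
#' mechanism by which a real cohort shrinks to its analysable subset.
#'
#' The encoded clauses are:
#' \describe{
#'   \item{5}{Q2 = 3 and Q3 = 3 and Q4 = 2 and Q5 = 2 (not in own home;
#'     needs help to move, for toilet visits and for dressing).}
#'   \item{4}{(Q3 = 3 or Q4 = 2 or Q5 = 2) and Q6 = 2 and Q7 = 3.}
#'   \item{3}{(Q1 = 2 or Q2 = 2 or Q3 in 1,2) and Q6 = 2.}
#'   \item{0-2}{(Q1 in 3,4 or Q6 in 1,2 or Q7 in 1,2) and Q2 = 1 and
#'     Q3 = 1 and Q4 = 1 and Q5 = 1.}
#' }
#'
#' @return An object of class `mrs_ruleset`.
#' @export
#' @examples
#' rs <- default_ruleset()
#' map_record(c(q1 = 2, q2 = 3, q3 = 3, q4 = 2, q5 = 2, q6 = 2, q7 = 3), rs)
default_ruleset <- function() {
  rule <- function(id, band, any = list(), all = list())
    list(id = id, band = band, any = any, all = all)
  rs <- structure(list(
    rules = list(
      rule("mrs-5", "5",
           all = list(q2 = 3L, q3 = 3L, q4 = 2L, q5 = 2L)),
      rule("mrs-4", "4",
           any = list(q3 = 3L, q4 = 2L, q5 = 2L),
           all = list(q6 = 2L, q7 = 3L)),
      rule("mrs-3", "3",
           any = list(q1 = 2L, q2 = 2L, q3 = c(1L, 2L)),
           all = list(q6 = 2L)),
      rule("mrs-0-2", "0-2",
           any = list(q1 = c(3L, 4L), q6 = c(1L, 2L), q7 = c(1L, 2L)),
           all = list(q2 = 1L, q3 = 1L, q4 = 1L, q5 = 1L))
    ),
    no_match = "unclassified"
  ), class = "mrs_ruleset")
  rs
}

#' Validate a rule set against a code book
#'
#' Every condition must name a known question, with a non-empty allowed-code
#' set drawn from that question's analysis codes (excluded codes may never
#' appear in rule conditions).
#'
#' @param ruleset An `mrs_ruleset`.
#' @param codebook An `mrs_codebook`.
#' @return The rule set, invisibly, if valid.
#' @export
validate_ruleset <- function(ruleset, codebook = default_codebook()) {
  if (!inherits(ruleset, "mrs_ruleset"))
    stop("not an 'mrs_ruleset' object", call. = FALSE)
  for (r in ruleset$rules) {
    for (block in c("any", "all")) {
      conds <- r[[block]]
      for (q in names(conds)) {
        if (is.null(codebook[[q]]))
          stop("rule ", r$id, ": unknown question ", q, call. = FALSE)
        codes <- as.integer(conds[[q]])
        if (!length(codes))
          stop("rule ", r$id, ": empty code set for ", q, call. = FALSE)
        bad <- setdiff(codes, valid_codes(codebook, q))
        if (length(bad))
          stop("rule ", r$id, ": code ", bad[1], " for question ", q,
               " is not a valid analysis code", call. = FALSE)
      }
    }
  }
  invisible(ruleset)
}

rule_matches <- function(rule, answers) {
  hold <- function(conds) vapply(names(conds), function(q) {
    a <- answers[[q]]
    !is.null(a) && !is.na(a) && a %in% conds[[q]]
  }, logical(1))
  any_ok <- length(rule$any) == 0L || any(hold(rule$any))
  all_ok <- length(rule$all) == 0L || all(hold(rule$all))
  any_ok && all_ok
}

#' Map one answer vector to an mRS grade band
#'
#' Evaluates the rules in precedence order and returns the band of the first
#' rule whose condition holds, or the rule set's no-match label (by default
#' `"unclassified"`) when none does.  The answer vector must be complete:
#' records with missing answers are to be removed first with
#' [apply_exclusions()].
#'
#' @param answers Named integer vector or list with elements `q1`..`q7`.
#' @param ruleset An `mrs_ruleset`; defaults to [default_ruleset()].
#' @return A list with `band` (character label) and `rule_id` (the matching
#'   rule's id, or `NA` when unclassified).
#' @export
map_record <- function(answers, ruleset = default_ruleset()) {
  answers <- as.list(answers)
  qs <- unique(unlist(lapply(ruleset$rules, function(r)
    c(names(r$any), names(r$all)))))
  miss <- qs[vapply(qs, function(q)
    is.null(answers[[q]]) || is.na(answers[[q]]), logical(1))]
  if (length(miss))
    stop("answer vector has missing value(s) for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (r in ruleset$rules) {
    if (rule_matches(r, answers))
      return(list(band = r$band, rule_id = r$id))
  }
  list(band = ruleset$no_match, rule_id = NA_character_)
}

#' Map a whole cohort through the transformation rules
#'
#' @param cohort A cohort `data.frame` (post-exclusion: no missing answers).
#' @param ruleset An `mrs_ruleset`.
#' @return A `data.frame` with columns `patient_id`, `mrs`, `band` and
#'   `rule_id`, one row per input record, order preserved.  The number of
#'   unclassified records is available as `attr(, "n_unclassified")`.
#' @export
map_cohort <- function(cohort, ruleset = default_ruleset()) {
  n <- nrow(cohort)
  band <- character(n)
  rule_id <- character(n)
  for (i in seq_len(n)) {
    a <- as.list(cohort[i, paste0("q", 1:7), drop = FALSE])
    out <- tryCatch(map_record(a, ruleset), error = function(e)
      stop("row ", i, " (", cohort$patient_id[i], "): ", conditionMessage(e),
           call. = FALSE))
    band[i] <- out$band
    rule_id[i] <- out$rule_id
  }
  res <- data.frame(patient_id = cohort$patient_id, mrs = cohort$mrs,
                    band = band, rule_id = rule_id,
                    stringsAsFactors = FALSE)
  attr(res, "n_unclassified") <- sum(band == ruleset$no_match)
  res
}

#' Read / write a rule set as YAML
#'
#' @param path File path.
#' @param codebook Code book used to validate the rules on read.
#' @return `read_ruleset()` returns an `mrs_ruleset`; `write_ruleset()`
#'   returns `path` invisibly.
#' @export
read_ruleset <- function(path, codebook = default_codebook()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$rules)) stop("rule file lacks 'rules'", call. = FALSE)
  rs <- structure(list(
    rules = lapply(raw$rules, function(r) list(
      id = r$id, band = as.character(r$band),
      any = lapply(if (is.null(r$any)) list() else r$any, as.integer),
      all = lapply(if (is.null(r$all)) list() else r$all, as.integer))),
    no_match = if (is.null(raw$no_match)) "unclassified" else raw$no_match
  ), class = "mrs_ruleset")
  validate_ruleset(rs, codebook)
  rs
}

#' @rdname read_ruleset
#' @param ruleset An `mrs_ruleset` to serialize.
#' @export
write_ruleset <- function(ruleset, path) {
  out <- list(
    no_match = ruleset$no_match,
    rules = lapply(ruleset$rules, function(r) list(
      id = r$id, band = r$band,
      any = lapply(r$any, as.integer),
      all = lapply(r$all, as.integer)))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mrs_ruleset <- function(x, ...) {
  cat("mRS-RS transformation rule set (", length(x$rules),
      " rules, first match wins)\n", sep = "")
  fmt <- function(conds, sep)
    paste(vapply(names(conds), function(q)
      paste0(q, " in {", paste(conds[[q]], collapse = ","), "}"),
      character(1)), collapse = sep)
  for (r in x$rules) {
    cat("  band ", r$band, " [", r$id, "]: ", sep = "")
    parts <- character(0)
    if (length(r$any)) parts <- paste0("(", fmt(r$any, " OR "), ")")
    if (length(r$all)) parts <- c(parts, fmt(r$all, " AND "))
    cat(paste(parts, collapse = " AND "), "\n")
  }
  cat("  no match -> ", x$no_match, "\n", sep = "")
  invisible(x)
}
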