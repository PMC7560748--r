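#' Read a cohort file
#'
#' Loads a delimited cohort file with header columns
#' `patient_id, mrs, q1, ..., q7` (one row per patient) and validates every
#' answer code against the code book.  Missing answers are coded as empty
#' fields and come back as `NA`; they are legal at load time and removed by
#' [apply_exclusions()].  Grade 6 (death) is rejected: deceased patients do
#' not reach the three-month questionnaire and are outside the data model.
#'
#' @param path Path to a CSV file.
#' @param codebook An `mrs_codebook`; defaults to [default_codebook()].
#' @return A `data.frame` with columns `patient_id` (character), `mrs`
#'   (integer 0-5) and `q1`..`q7` (integer or `NA`), row order preserved.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 5, seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' write_cohort(cohort, tmp)
#' identical(load_cohort(tmp), cohort)
load_cohort <- function(path, codebook = default_codebook()) {
  validate_codebook(codebook)
  qs <- question_ids(codebook)
  cols <- c("patient_id", "mrs", qs)
  dat <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols))
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- dat[, cols, drop = FALSE]
  to_int <- function(x, col) {
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("malformed value '%s' in row %d, column %s",
                   x[bad[1]], bad[1], col), call. = FALSE)
    out
  }
  dat$mrs <- to_int(dat$mrs, "mrs")
  bad <- which(is.na(dat$mrs) | dat$mrs < 0L | dat$mrs > 5L)
  if (length(bad)) {
    msg <- if (!is.na(dat$mrs[bad[1]]) && dat$mrs[bad[1]] == 6L)
      sprintf("row %d: mRS grade 6 (death) is not admissible; deceased patients are excluded before follow-up", bad[1])
    else
      sprintf("row %d: mRS grade must be an integer in 0..5", bad[1])
    stop(msg, call. = FALSE)
  }
  for (q in qs) {
    dat[[q]] <- to_int(dat[[q]], q)
    defined <- as.integer(names(codebook[[q]]$codes))
    bad <- which(!is.na(dat[[q]]) & !dat[[q]] %in% defined)
    if (length(bad))
      stop(sprintf("row %d: answer code %d is not defined for question %s",
                   bad[1], dat[[q]][bad[1]], q), call. = FALSE)
  }
  rownames(dat) <- NULL
  dat
}

#' Write a cohort file
#'
#' Writes the CSV representation read by [load_cohort()]; missing answers
#' become empty fields.  `write_cohort()` followed by [load_cohort()]
#' round-trips bit-identically on valid cohorts.
#'
#' @param cohort A cohort `data.frame` as returned by [load_cohort()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "mrs", paste0("q", 1:7))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(cohort[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the analysis exclusion criteria
#'
#' Removes records carrying a "Do not know"-type excluded answer code or a
#' missing answer on any of the seven questions, mirroring the complete-case
#' inclusion criterion of the register analysis.  The function partitions its
#' input: every record lands in exactly one of `kept` and `dropped`.
#'
#' @param cohort A validated cohort `data.frame`.
#' @param codebook An `mrs_codebook`.
#' @return A list with components `kept` (cohort rows passing all criteria)
#'   and `dropped` (the removed rows plus a `reason` column of the form
#'   `"missing:<q>"` or `"excluded-code:<q>"`, naming the first offending
#'   question in q1..q7 order).
#' @export
apply_exclusions <- function(cohort, codebook = default_codebook()) {
  validate_codebook(codebook)
  qs <- question_ids(codebook)
  reason <- rep(NA_character_, nrow(cohort))
  for (q in rev(qs)) {        # reverse so the first offending question wins
    v <- cohort[[q]]
    reason[!is.na(v) & v %in% excluded_codes(codebook, q)] <-
      paste0("excluded-code:", q)
    reason[is.na(v)] <- paste0("missing:", q)
  }
  drop <- !is.na(reason)
  dropped <- cohort[drop, , drop = FALSE]
  dropped$reason <- reason[drop]
  kept <- cohort[!drop, , drop = FALSE]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}
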