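#' Canonical answer profile for a raw mRS grade
#'
#' The prototypical answer vector of each grade, constructed so that the
#' default transformation rules recover exactly the band containing the
#' grade (and no more-severe band).  Grades 0, 1 and 2 share the
#' independent-living profile of band 0-2 and differ only in the Q7
#' "return to prior life" shading (fully / partly / cannot); Q6 is
#' "problems completely gone" throughout that band because any band 0-2
#' answer pattern with residual problems and preserved indoor mobility
#' would be captured by the band-3 rule under severity-descending
#' precedence.
#'
#' @param grade Integer mRS grade in 0..5.
#' @return Named integer vector `q1`..`q7`.
#' @export
#' @examples
#' map_record(canonical_profile_for_grade(5))$band   # "5"
canonical_profile_for_grade <- function(grade) {
  grade <- as.integer(grade)
  if (is.na(grade) || grade < 0L || grade > 5L)
    stop("mRS grade must lie in 0..5", call. = FALSE)
  base <- switch(as.character(grade),
    "0" = c(4L, 1L, 1L, 1L, 1L, 1L, 1L),
    "1" = c(4L, 1L, 1L, 1L, 1L, 1L, 2L),
    "2" = c(4L, 1L, 1L, 1L, 1L, 1L, 3L),
    "3" = c(2L, 2L, 2L, 1L, 1L, 2L, 3L),
    "4" = c(2L, 2L, 3L, 2L, 2L, 2L, 3L),
    "5" = c(2L, 3L, 3L, 2L, 2L, 2L, 3L))
  names(base) <- paste0("q", 1:7)
  base
}

#' Configuration for the synthetic registry simulator
#'
#' @param n Cohort size (>= 0).
#' @param marginals Probabilities of raw grades 0..5; the default is the
#'   observed three-month functional-outcome distribution of a Swedish
#'   first-ever-stroke cohort (21/27/23/15/7/5 percent), renormalized to
#'   sum to one.
#' @param noise Per-question probability of replacing the canonical answer
#'   code by a uniformly random other valid code (response noise).
#' @param missing_rate Per-question probability of a missing answer.
#' @param dontknow_rate Per-question probability of a "Do not know"-type
#'   excluded code.
#' @param dispersion Within band 0-2, the probability that the Q7 shading
#'   is redrawn from the distribution shared across grades 0-2 (weighted by
#'   their marginals) instead of keeping the grade's canonical value.  The
#'   default 1 makes grades 0, 1 and 2 carry no recoverable signal beyond
#'   their shared band - the structural property of the real questionnaire
#'   that motivates merging those grades.
#' @param seed Integer seed; the same configuration always reproduces the
#'   same cohort.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n, marginals = c(0.21, 0.27, 0.23, 0.15, 0.07, 0.05),
                       noise = 0, missing_rate = 0, dontknow_rate = 0,
                       dispersion = 1, seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("invalid field 'n': must be a single non-negative count", call. = FALSE)
  if (length(marginals) != 6L || any(marginals < 0) || sum(marginals) <= 0)
    stop("invalid field 'marginals': six non-negative values summing > 0",
         call. = FALSE)
  for (f in c("noise", "missing_rate", "dontknow_rate")) {
    v <- get(f)
    if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      stop("invalid field '", f, "': must lie in [0, 1)", call. = FALSE)
  }
  if (dispersion < 0 || dispersion > 1)
    stop("invalid field 'dispersion': must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), marginals = marginals / sum(marginals),
                 noise = noise, missing_rate = missing_rate,
                 dontknow_rate = dontknow_rate, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic registry cohort
#'
#' Draws each patient's true mRS grade from the configured marginal
#' distribution, starts from the grade's canonical answer profile
#' ([canonical_profile_for_grade()]), applies the within-band Q7 dispersion
#' for grades 0-2, and then contaminates each question independently: with
#' probability `missing_rate` the answer is blanked, with `dontknow_rate` it
#' becomes an excluded "Do not know"-type code, and with `noise` it is
#' replaced by a uniformly random other valid code.  At zero noise and zero
#' contamination, mapping the cohort through the default rules classifies
#' every record into the band containing its true grade.
#'
#' @param config A [sim_config()] object.
#' @param codebook Code book supplying valid and excluded codes.
#' @return A cohort `data.frame` with columns `patient_id`, `mrs`,
#'   `q1`..`q7`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 100, seed = 42))
#' table(map_cohort(cohort)$band)
simulate_cohort <- function(config, codebook = default_codebook()) {
  if (!inherits(config, "sim_config"))
    stop("config must be built with sim_config()", call. = FALSE)
  qs <- question_ids(codebook)
  n <- config$n
  ids <- sprintf("P%05d", seq_len(n))
  if (n == 0L) {
    out <- data.frame(patient_id = character(0), mrs = integer(0))
    for (q in qs) out[[q]] <- integer(0)
    return(out)
  }
  set.seed(config$seed)
  grades <- sample(0:5, n, replace = TRUE, prob = config$marginals)
  prof <- t(vapply(grades, canonical_profile_for_grade, integer(7)))
  colnames(prof) <- qs
  ans <- matrix(NA_integer_, n, length(qs), dimnames = list(NULL, qs))
  ans[] <- prof

  # within-band dispersion of the Q7 shading for grades 0-2
  low <- which(grades <= 2L)
  if (length(low) && config$dispersion > 0) {
    w <- config$marginals[1:3]
    redraw <- low[stats::runif(length(low)) < config$dispersion]
    if (length(redraw))
      ans[redraw, "q7"] <- sample(1:3, length(redraw), replace = TRUE,
                                  prob = w / sum(w))
  }

  # independent per-question contamination and response noise
  for (q in qs) {
    u <- stats::runif(n)
    vc <- valid_codes(codebook, q)
    ec <- excluded_codes(codebook, q)
    m1 <- config$missing_rate
    m2 <- m1 + config$dontknow_rate
    m3 <- m2 + config$noise
    ans[u < m1, q] <- NA_integer_
    dk <- which(u >= m1 & u < m2)
    if (length(dk))
      ans[dk, q] <- ec[sample.int(length(ec), length(dk), replace = TRUE)]
    nz <- which(u >= m2 & u < m3)
    for (i in nz) {
      others <- setdiff(vc, ans[i, q])
      ans[i, q] <- others[sample.int(length(others), 1L)]
    }
  }

  out <- data.frame(patient_id = ids, mrs = as.integer(grades),
                    stringsAsFactors = FALSE)
  for (q in qs) out[[q]] <- ans[, q]
  out
}
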