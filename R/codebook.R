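#' Default answer code book for the seven Riksstroke follow-up questions
#'
#' Returns the code book used by the default mRS-RS transformation rules.
#' Each of the seven self-reported questions of the Riksstroke three-month
#' follow-up carries an integer answer coding; codes flagged as excluded
#' ("Do not know", and for Q1 "Have no relatives/friends or have no contact
#' with relatives/friends") are valid on file but removed from all analyses
#' by [apply_exclusions()].
#'
#' The coding is a reconstruction from the published transformation rules
#' (the authoritative register questionnaire coding is not publicly
#' available); supply your own code book via [read_codebook()] if you hold
#' the register's official dialect.
#'
#' @return An object of class `mrs_codebook`: a list with one element per
#'   question, each a list with elements `id`, `text`, `type` (`"ordinal"`
#'   or `"nominal"`), `codes` (named character vector: code -> label) and
#'   `excluded` (integer codes excluded from analysis).
#' @export
#' @examples
#' cb <- default_codebook()
#' names(cb)
#' valid_codes(cb, "q3")
default_codebook <- function() {
  q <- function(id, text, codes, excluded = integer(), type = "ordinal") {
    list(id = id, text = text, type = type,
         codes = codes, excluded = as.integer(excluded))
  }
  cb <- list(
    q1 = q("q1",
      "Are you today dependent on a family member/next-of-kin for help/support?",
      c("1" = "Have no relatives/friends or have no contact with relatives/friends",
        "2" = "Yes, completely dependent",
        "3" = "Yes, partly dependent",
        "4" = "No, not dependent",
        "9" = "Do not know"),
      excluded = c(1L, 9L)),
    q2 = q("q2",
      "Where are you staying now?",
      c("1" = "In my own home, without community services",
        "2" = "In my own home, with community support",
        "3" = "Not in my own home (community facility or other)",
        "9" = "Do not know"),
      excluded = 9L, type = "nominal"),
    q3 = q("q3",
      "How is your mobility now?",
      c("1" = "Can get around both indoors and outdoors without the help of another person",
        "2" = "Can move around without help at least indoors",
        "3" = "Need another person's help to move",
        "9" = "Do not know"),
      excluded = 9L),
    q4 = q("q4",
      "Do you receive help from anybody to go to the toilet?",
      c("1" = "Can manage to visit the toilet by myself",
        "2" = "Need help to go to the toilet",
        "9" = "Do not know"),
      excluded = 9L),
    q5 = q("q5",
      "Do you need help getting dressed and undressed?",
      c("1" = "Can manage to get dressed and undressed by myself",
        "2" = "Need help to get dressed and undressed",
        "9" = "Do not know"),
      excluded = 9L),
    q6 = q("q6",
      "Are you still having problems after your stroke?",
      c("1" = "All problems have completely gone",
        "2" = "Problems are not completely resolved",
        "9" = "Do not know"),
      excluded = 9L),
    q7 = q("q7",
      "Have you been able to return to the life and activities you had before you had a stroke?",
      c("1" = "Yes, fully",
        "2" = "Yes, partly",
        "3" = "Cannot return to the life and activities I had prior to stroke",
        "9" = "Do not know"),
      excluded = 9L)
  )
  class(cb) <- "mrs_codebook"
  attr(cb, "provenance") <- "reconstructed"
  validate_codebook(cb)
  cb
}

#' Validate an answer code book
#'
#' Checks structural invariants: seven uniquely identified questions, distinct
#' integer codes within each question, and excluded codes that are themselves
#' defined codes.
#'
#' @param codebook An `mrs_codebook` object.
#' @return The code book, invisibly, if valid; otherwise an error is raised.
#' @export
validate_codebook <- function(codebook) {
  if (!inherits(codebook, "mrs_codebook"))
    stop("not an 'mrs_codebook' object", call. = FALSE)
  ids <- vapply(codebook, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate question identifiers in code book", call. = FALSE)
  if (!identical(names(codebook), unname(ids)))
    stop("code book element names must equal question ids", call. = FALSE)
  for (qu in codebook) {
    codes <- as.integer(names(qu$codes))
    if (anyNA(codes))
      stop("non-integer answer code in question ", qu$id, call. = FALSE)
    if (anyDuplicated(codes))
      stop("duplicate answer codes in question ", qu$id, call. = FALSE)
    if (!all(qu$excluded %in% codes))
      stop("excluded code not defined for question ", qu$id, call. = FALSE)
    if (!qu$type %in% c("ordinal", "nominal"))
      stop("question ", qu$id, ": type must be 'ordinal' or 'nominal'",
           call. = FALSE)
  }
  invisible(codebook)
}

#' Codes usable in analysis for one question
#'
#' @param codebook An `mrs_codebook`.
#' @param question Question id, e.g. `"q3"`.
#' @return Integer vector of defined codes with the excluded ones removed.
#' @export
valid_codes <- function(codebook, question) {
  qu <- codebook[[question]]
  if (is.null(qu)) stop("unknown question: ", question, call. = FALSE)
  setdiff(as.integer(names(qu$codes)), qu$excluded)
}

#' Codes excluded from analysis for one question
#'
#' @inheritParams valid_codes
#' @return Integer vector of excluded codes (possibly empty).
#' @export
excluded_codes <- function(codebook, question) {
  qu <- codebook[[question]]
  if (is.null(qu)) stop("unknown question: ", question, call. = FALSE)
  qu$excluded
}

#' Read / write a code book as YAML
#'
#' The on-disk representation mirrors the in-memory structure so that users
#' can supply the register's authoritative coding without touching code.
#'
#' @param path File path.
#' @return `read_codebook()` returns an `mrs_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$questions)) stop("code book file lacks 'questions'", call. = FALSE)
  cb <- lapply(raw$questions, function(qu) {
    codes <- vapply(qu$codes, as.character, character(1))
    list(id = qu$id, text = qu$text,
         type = if (is.null(qu$type)) "ordinal" else qu$type,
         codes = codes,
         excluded = as.integer(unlist(qu$excluded)))
  })
  names(cb) <- vapply(cb, `[[`, character(1), "id")
  class(cb) <- "mrs_codebook"
  attr(cb, "provenance") <- if (is.null(raw$provenance)) "user" else raw$provenance
  validate_codebook(cb)
  cb
}

#' @rdname read_codebook
#' @param codebook An `mrs_codebook` to serialize.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  out <- list(
    provenance = attr(codebook, "provenance"),
    questions = lapply(unclass(codebook), function(qu) {
      list(id = qu$id, text = qu$text, type = qu$type,
           codes = as.list(qu$codes), excluded = qu$excluded)
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mrs_codebook <- function(x, ...) {
  cat("Riksstroke answer code book (", attr(x, "provenance"), ")\n", sep = "")
  for (qu in x) {
    cat(sprintf("  %s [%s]: %s\n", qu$id, qu$type, qu$text))
    for (code in names(qu$codes)) {
      flag <- if (as.integer(code) %in% qu$excluded) " [excluded]" else ""
      cat(sprintf("    %s = %s%s\n", code, qu$codes[[code]], flag))
    }
  }
  invisible(x)
}

question_ids <- function(codebook) names(codebook)
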