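#' Grade schemes: groupings of raw mRS grades into ordered bands
#'
#' A grade scheme partitions the raw modified Rankin Scale grades 0-5
#' (survivors only; grade 6, death, is outside the data model) into ordered
#' bands used as classification targets.  Three presets ship:
#'
#' * `"tree1"` - bands 0-2, 3, 4, 5: the grouping under which the manual
#'   mRS-RS transformation rules operate.
#' * `"full"` - the full scale, one band per grade 0..5.
#' * `"clinical"` - bands 0-1, 2-3, 4-5: no / moderate / severe disability.
#'
#' @param name One of `"tree1"`, `"full"`, `"clinical"`, or an `mrs_scheme`
#'   object (returned unchanged).
#' @return An object of class `mrs_scheme`: list with `name`, `bands`
#'   (list of integer vectors, severity-ascending) and `labels`.
#' @export
#' @examples
#' grade_scheme("clinical")
#' collapse_grade(3, grade_scheme("tree1"))
grade_scheme <- function(name = c("tree1", "full", "clinical")) {
  if (inherits(name, "mrs_scheme")) return(name)
  name <- match.arg(name)
  bands <- switch(name,
    tree1    = list(0:2, 3L, 4L, 5L),
    full     = as.list(0:5),
    clinical = list(0:1, 2:3, 4:5))
  labels <- vapply(bands, function(b)
    if (length(b) == 1L) as.character(b) else paste0(min(b), "-", max(b)),
    character(1))
  structure(list(name = name, bands = bands, labels = labels),
            class = "mrs_scheme")
}

#' Collapse a raw mRS grade into its band index
#'
#' @param grade Integer vector of raw mRS grades in 0..5.
#' @param scheme An `mrs_scheme` (or preset name).
#' @return Integer vector of 1-based band indices; `band_label()` returns the
#'   corresponding display labels.
#' @export
collapse_grade <- function(grade, scheme) {
  scheme <- grade_scheme(scheme)
  grade <- as.integer(grade)
  if (anyNA(grade) || any(grade < 0L | grade > 5L))
    stop("mRS grade must lie in 0..5", call. = FALSE)
  lut <- integer(6)
  for (i in seq_along(scheme$bands)) lut[scheme$bands[[i]] + 1L] <- i
  lut[grade + 1L]
}

#' @rdname collapse_grade
#' @export
band_label <- function(grade, scheme) {
  scheme <- grade_scheme(scheme)
  scheme$labels[collapse_grade(grade, scheme)]
}

#' @export
print.mrs_scheme <- function(x, ...) {
  cat("mRS grade scheme '", x$name, "': ",
      paste(x$labels, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Number of bands in a scheme
#' @param scheme An `mrs_scheme` or preset name.
#' @return Integer band count.
#' @export
n_bands <- function(scheme) length(grade_scheme(scheme)$bands)
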