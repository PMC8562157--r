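#' Origin label encoding
#'
#' Origin labels are plain character strings so that whole origin matrices
#' are ordinary character matrices:
#' \itemize{
#'   \item a parent/ancestor id (e.g. `"F02"`) — a definitive SOURCE call;
#'   \item `"id1|id2"` — AMBIGUOUS between the two parents, ids in sorted order;
#'   \item `"!"` — CONFLICT: the progeny is homozygous for an allele carried
#'     by neither parent (e.g. a genotyping error or pedigree error);
#'   \item `"."` — MISSING: the progeny call is heterozygous or absent.
#' }
#' Line ids must therefore not contain `"|"` and must not equal `"!"` or `"."`.
#'
#' @param label character vector of origin labels.
#' @return `is_source()`: logical vector; `ambiguous_label()`: the canonical
#'   sorted `"id1|id2"` string; `ambiguous_parents()`: a 2-column character
#'   matrix of the two ids (NA rows for non-ambiguous labels).
#' @name origin-labels
NULL

CONFLICT_LABEL <- "!"
MISSING_LABEL <- "."

#' @rdname origin-labels
#' @export
is_source <- function(label) {
  !is.na(label) &
    label != CONFLICT_LABEL &
    label != MISSING_LABEL &
    !grepl("|", label, fixed = TRUE)
}

#' @rdname origin-labels
#' @export
is_ambiguous <- function(label) {
  !is.na(label) & grepl("|", label, fixed = TRUE)
}

#' @param id1,id2 the two candidate parent ids.
#' @rdname origin-labels
#' @export
ambiguous_label <- function(id1, id2) {
  lo <- pmin(id1, id2)
  hi <- pmax(id1, id2)
  paste(lo, hi, sep = "|")
}

#' @rdname origin-labels
#' @export
ambiguous_parents <- function(label) {
  out <- matrix(NA_character_, nrow = length(label), ncol = 2L)
  amb <- is_ambiguous(label)
  if (any(amb)) {
    parts <- strsplit(label[amb], "|", fixed = TRUE)
    out[amb, 1L] <- vapply(parts, `[`, "", 1L)
    out[amb, 2L] <- vapply(parts, `[`, "", 2L)
  }
  out
}

# Reserved characters make label strings unambiguous; enforced on input ids.
check_ids <- function(ids, what = "line") {
  bad <- ids[grepl("|", ids, fixed = TRUE) | ids %in% c(CONFLICT_LABEL, MISSING_LABEL)]
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s id(s) not allowed (reserved characters '|', '!', '.'): %s",
      what, paste(unique(bad), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(ids)
}
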