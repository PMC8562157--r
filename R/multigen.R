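#' Compose origin labels through one pedigree step
#'
#' Each SOURCE(parent) label in the child's row is replaced by that parent's
#' own label at the same marker when a (composed) row for the parent is
#' available.  A parent label that is itself a SOURCE propagates as that
#' deeper ancestor; any non-SOURCE parent label (AMBIGUOUS, CONFLICT,
#' MISSING) propagates as SOURCE(parent_id) — the parent becomes its own
#' ancestral class, because the child genuinely inherited that physical
#' segment from the parent even though the parent's own provenance is
#' unresolved.  Child labels that are not SOURCE are untouched.
#'
#' @param child_row a traced origin row.
#' @param parent_rows named list `parent_id -> origin row` over the same
#'   markers (possibly already composed).
#' @return the composed origin row.
#' @export
compose_origins <- function(child_row, parent_rows) {
  out <- child_row
  for (p in names(parent_rows)) {
    prow <- parent_rows[[p]]
    if (length(prow) != length(child_row)) {
      stop("compose_origins: marker sets differ between child and parent", call. = FALSE)
    }
    idx <- which(child_row == p)
    if (length(idx) == 0L) next
    pl <- prow[idx]
    out[idx] <- ifelse(is_source(pl), pl, p)
  }
  out
}

#' Rewrite a line's unresolved labels as its own ancestral class
#'
#' When a traced line is itself used as a parent, markers whose provenance
#' could not be resolved in that line (AMBIGUOUS) are assigned a new
#' ancestral class named by the line's own id, so its progeny can still be
#' credited with the physical segment.  The original row — used for
#' predicting the line's own performance — is left untouched by callers.
#'
#' @param origin_row the line's traced origin row.
#' @param line_id the line's id.
#' @return origin row with AMBIGUOUS labels replaced by `line_id`.
#' @export
assign_self_classes <- function(origin_row, line_id) {
  origin_row[is_ambiguous(origin_row)] <- line_id
  origin_row
}

#' Trace origins to the most distal traceable ancestors
#'
#' Composes single-generation origin rows through the pedigree in
#' ancestors-first (topological) order, so every SOURCE label is attributed
#' to the most distal ancestor whose own tracing reaches it.  Recursion
#' stops at founders, at ancestors without a traced row (terminal labels),
#' and at non-SOURCE ancestor labels (which become the ancestor's
#' self-class, see [compose_origins()]).
#'
#' @param ped a `pedigree`.
#' @param origins single-generation origin matrix (one row per traced line;
#'   all intermediate lines that should be composed through must be present).
#' @param max_depth generations to compose; `1` returns the input rows
#'   unchanged, `Inf` (default) composes to the most distal ancestors.
#' @param lines rows to return; default all rows of `origins`.
#' @return composed origin matrix over the same markers.
#' @export
trace_to_founders <- function(ped, origins, max_depth = Inf, lines = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(lines)) lines <- rownames(origins)
  stopifnot(all(lines %in% rownames(origins)))
  order_ids <- topo_order(ped)
  traced <- intersect(order_ids, rownames(origins))

  if (is.infinite(max_depth)) {
    composed <- list()
    for (ln in traced) {
      prows <- parent_rows_for(ln, ped, composed)
      composed[[ln]] <- if (length(prows)) compose_origins(origins[ln, ], prows)
                        else origins[ln, ]
    }
  } else {
    stopifnot(max_depth >= 1)
    composed <- lapply(traced, function(ln) origins[ln, ])
    names(composed) <- traced
    d <- 1
    while (d < max_depth) {
      nxt <- list()
      for (ln in traced) {
        prows <- parent_rows_for(ln, ped, composed)
        nxt[[ln]] <- if (length(prows)) compose_origins(origins[ln, ], prows)
                     else origins[ln, ]
      }
      if (identical(nxt, composed)) break # fixed point before depth limit
      composed <- nxt
      d <- d + 1
    }
  }
  out <- do.call(rbind, composed[lines])
  dimnames(out) <- list(lines, colnames(origins))
  out
}

# Composed rows (with self-classes) of a line's traced parents.
parent_rows_for <- function(ln, ped, composed) {
  i <- match(ln, ped$line)
  ps <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
  ps <- ps[ps %in% names(composed)]
  rows <- lapply(ps, function(p) composed[[p]])
  names(rows) <- ps
  rows
}

# Ancestors-first ordering of all pedigree lines (Kahn's algorithm).
topo_order <- function(ped) {
  ids <- ped$line
  parents <- lapply(seq_len(nrow(ped)), function(i) {
    p <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
    intersect(p, ids)
  })
  names(parents) <- ids
  placed <- character(0)
  remaining <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(id) {
      all(parents[[id]] %in% placed)
    }, logical(1L))]
    if (length(ready) == 0L) stop("pedigree: cycle detected", call. = FALSE)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Ancestor set of a line
#'
#' @param ped a `pedigree`.
#' @param line_id line whose ancestors are wanted.
#' @return character vector of all ancestors reachable through the pedigree.
#' @export
ancestors <- function(ped, line_id) {
  seen <- character(0)
  queue <- line_id
  while (length(queue) > 0L) {
    id <- queue[1L]; queue <- queue[-1L]
    i <- match(id, ped$line)
    if (is.na(i)) next
    ps <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
    new <- setdiff(ps, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  seen
}
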