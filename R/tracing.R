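#' Assign anchor markers for one progeny
#'
#' An anchor marker is a SNP at which the two parents carry different
#' homozygous calls, so the progeny's homozygous allele identifies its
#' parental source unambiguously.  Per marker:
#' \itemize{
#'   \item progeny heterozygous or missing: MISSING (`"."`) — an inbred line
#'     should be homozygous, so the call carries no reliable origin signal;
#'   \item parents differ and are both homozygous: SOURCE(the matching parent);
#'   \item parents identical homozygous and progeny matches: AMBIGUOUS;
#'     progeny homozygous for the allele neither parent carries: CONFLICT (`"!"`);
#'   \item either parent heterozygous or missing: AMBIGUOUS.
#' }
#'
#' @param progeny,p1,p2 genotype rows (character vectors in `c("A","B","H",NA)`)
#'   over the same ordered markers.
#' @param p1_id,p2_id parent ids used in the output labels.
#' @return an origin label row (character vector, same length/names).
#' @export
assign_anchor_markers <- function(progeny, p1, p2, p1_id = "p1", p2_id = "p2") {
  if (length(progeny) != length(p1) || length(progeny) != length(p2)) {
    stop("assign_anchor_markers: row length mismatch", call. = FALSE)
  }
  amb <- ambiguous_label(p1_id, p2_id)
  out <- rep(amb, length(progeny))

  prog_missing <- is.na(progeny) | progeny == "H"
  p1_hom <- !is.na(p1) & p1 %in% c("A", "B")
  p2_hom <- !is.na(p2) & p2 %in% c("A", "B")
  informative <- p1_hom & p2_hom & p1 != p2
  identical_hom <- p1_hom & p2_hom & p1 == p2

  i <- !prog_missing & informative & progeny == p1
  out[i] <- p1_id
  i <- !prog_missing & informative & progeny == p2
  out[i] <- p2_id
  # progeny homozygous for an allele carried by neither parent
  i <- !prog_missing & identical_hom & progeny != p1
  out[i] <- CONFLICT_LABEL
  out[prog_missing] <- MISSING_LABEL

  names(out) <- names(progeny)
  out
}

#' Impute ambiguous origins from flanking anchors
#'
#' Each maximal run of non-SOURCE labels whose nearest SOURCE anchors on both
#' sides (within the same chromosome, at any distance) agree is relabeled
#' with that source.  Runs whose flanking anchors disagree are left as they
#' are — such a run is the region within which a recombination occurred but
#' cannot be delimited between two adjacent markers.  Runs at a chromosome
#' end (an anchor on one side only) are also left unchanged, as is a
#' chromosome with no anchors at all.  CONFLICT labels are never used as
#' anchors; they are overwritten only when both flanks agree, otherwise they
#' stay CONFLICT.  Imputation never crosses a chromosome boundary and never
#' changes an existing SOURCE label, so the operation is idempotent.
#'
#' @param origin_row origin label row (named by marker, map order).
#' @param map a `genetic_map` covering the row's markers in the same order.
#' @return the imputed origin row.
#' @export
impute_from_flanks <- function(origin_row, map) {
  stopifnot(inherits(map, "genetic_map"), length(origin_row) == nrow(map))
  out <- origin_row
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    lab <- origin_row[idx]
    src <- is_source(lab)
    if (!any(src)) next
    n <- length(lab)
    # nearest anchor source left/right of each position (last-anchor carry)
    li <- cummax(ifelse(src, seq_len(n), 0L))
    ri_rev <- cummax(ifelse(rev(src), seq_len(n), 0L))
    ri <- rev(ifelse(ri_rev > 0L, n + 1L - ri_rev, 0L))
    left <- ifelse(li > 0L, lab[pmax(li, 1L)], NA_character_)
    right <- ifelse(ri > 0L, lab[pmax(ri, 1L)], NA_character_)
    fill <- !src & !is.na(left) & !is.na(right) & left == right
    out[idx][fill] <- left[fill]
  }
  out
}

#' Trace parental origins for one generation
#'
#' Applies [assign_anchor_markers()] then [impute_from_flanks()] to every
#' requested line.  A line is traceable when both its pedigree parents are
#' known and genotyped; untraceable lines are skipped with a warning.
#'
#' @param genotypes character genotype matrix (lines x markers, map order)
#'   containing progeny and parents.
#' @param ped a `pedigree`.
#' @param map a `genetic_map`.
#' @param lines lines to trace; default: all pedigree lines with two known
#'   parents.
#' @param impute apply flanking-anchor imputation (default `TRUE`).
#' @param smooth_singletons relabel length-1 source islands AMBIGUOUS before
#'   imputation-free reporting (sensitivity analysis aid; default `FALSE`).
#' @return an origin matrix (character, traced lines x markers) with a
#'   per-line summary data.frame in `attr(, "summary")`: counts of
#'   SOURCE/AMBIGUOUS/CONFLICT/MISSING labels and the unassigned fraction.
#' @export
trace_generation <- function(genotypes, ped, map, lines = NULL,
                             impute = TRUE, smooth_singletons = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "genetic_map"))
  if (!identical(colnames(genotypes), map$marker)) {
    stop("trace_generation: genotype columns must match map order", call. = FALSE)
  }
  if (is.null(lines)) {
    lines <- ped$line[!is.na(ped$parent1) & !is.na(ped$parent2)]
  }
  keep <- character(0)
  rows <- list()
  for (ln in lines) {
    i <- match(ln, ped$line)
    p1 <- if (is.na(i)) NA_character_ else ped$parent1[i]
    p2 <- if (is.na(i)) NA_character_ else ped$parent2[i]
    ok <- !is.na(p1) && !is.na(p2) && all(c(ln, p1, p2) %in% rownames(genotypes))
    if (!ok) {
      warning(sprintf("skipping %s: parents unknown or ungenotyped", ln))
      next
    }
    row <- assign_anchor_markers(genotypes[ln, ], genotypes[p1, ], genotypes[p2, ],
                                 p1_id = p1, p2_id = p2)
    if (impute) row <- impute_from_flanks(row, map)
    if (smooth_singletons) row <- smooth_singleton_row(row, map)
    rows[[ln]] <- row
    keep <- c(keep, ln)
  }
  if (length(keep) == 0L) {
    stop("trace_generation: no requested line is traceable", call. = FALSE)
  }
  origins <- do.call(rbind, rows)
  dimnames(origins) <- list(keep, map$marker)
  attr(origins, "summary") <- origin_summary(origins)
  origins
}

# Per-line label counts and unassigned fraction.
origin_summary <- function(origins) {
  m <- ncol(origins)
  n_source <- rowSums(matrix(is_source(origins), nrow = nrow(origins)))
  n_conflict <- rowSums(origins == CONFLICT_LABEL)
  n_missing <- rowSums(origins == MISSING_LABEL)
  n_amb <- m - n_source - n_conflict - n_missing
  data.frame(line = rownames(origins), n_source = n_source,
             n_ambiguous = n_amb, n_conflict = n_conflict,
             n_missing = n_missing,
             frac_unassigned = (m - n_source) / m,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Report singleton source calls
#'
#' A singleton is a SOURCE call whose nearest SOURCE neighbors on both sides
#' of the same chromosome both carry a different source — a length-1 island
#' implying either a double crossover between adjacent markers or a marker
#' order/genotyping problem.  Singletons are reported, never altered.
#'
#' @param origins an origin matrix.
#' @param map the `genetic_map`.
#' @return data.frame with columns `line, chrom, marker, source, left_source,
#'   right_source`.
#' @export
singleton_report <- function(origins, map) {
  stopifnot(inherits(map, "genetic_map"), ncol(origins) == nrow(map))
  res <- list()
  for (ln in rownames(origins)) {
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      lab <- origins[ln, idx]
      si <- which(is_source(lab))
      if (length(si) < 3L) next
      s <- lab[si]
      interior <- seq(2L, length(s) - 1L)
      hit <- interior[s[interior] != s[interior - 1L] & s[interior] != s[interior + 1L]]
      for (h in hit) {
        res[[length(res) + 1L]] <- data.frame(
          line = ln, chrom = ch, marker = map$marker[idx[si[h]]],
          source = s[h], left_source = s[h - 1L], right_source = s[h + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(line = character(0), chrom = character(0),
                      marker = character(0), source = character(0),
                      left_source = character(0), right_source = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Relabel singleton islands AMBIGUOUS(center, left neighbor source).
smooth_singleton_row <- function(origin_row, map) {
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    lab <- origin_row[idx]
    si <- which(is_source(lab))
    if (length(si) < 3L) next
    s <- lab[si]
    for (h in seq(2L, length(s) - 1L)) {
      if (s[h] != s[h - 1L] && s[h] != s[h + 1L]) {
        origin_row[idx[si[h]]] <- ambiguous_label(s[h], s[h - 1L])
      }
    }
  }
  origin_row
}
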