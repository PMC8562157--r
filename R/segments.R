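#' Compile maximal IBD segments for one line
#'
#' Run-length encodes the origin labels per chromosome: each segment is a
#' maximal run of identical labels.  Segments jointly cover every marker of
#' the chromosome and adjacent segments differ in source.
#'
#' @param origin_row traced origin row (named by marker, map order).
#' @param map the `genetic_map`.
#' @param line_id id recorded in the output.
#' @return data.frame with columns `line, chrom, start_index, end_index`
#'   (0-based inclusive marker indices within the chromosome),
#'   `start_marker, end_marker, source, n_markers`.
#' @export
compile_segments <- function(origin_row, map, line_id = "line") {
  stopifnot(inherits(map, "genetic_map"), length(origin_row) == nrow(map))
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    lab <- unname(origin_row[idx])
    r <- rle(lab)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    res[[ch]] <- data.frame(
      line = line_id, chrom = ch,
      start_index = start - 1L, end_index = end - 1L,
      start_marker = map$marker[idx[start]], end_marker = map$marker[idx[end]],
      source = r$values, n_markers = r$lengths,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compile segments for every line of an origin matrix
#'
#' @param origins origin matrix.
#' @param map the `genetic_map`.
#' @return row-bound [compile_segments()] tables for all lines.
#' @export
compile_all_segments <- function(origins, map) {
  out <- lapply(rownames(origins), function(ln) {
    compile_segments(origins[ln, ], map, line_id = ln)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count recombination events in one line's segments
#'
#' Per chromosome, the ordered SOURCE segments are scanned and each adjacent
#' pair with different sources counts as one event; an intervening
#' AMBIGUOUS/CONFLICT/MISSING run between two different sources therefore
#' counts as exactly one event (the breakpoint lies somewhere in that run),
#' and between two identical sources as zero.
#'
#' @param segments a [compile_segments()] table for one line.
#' @return integer event count summed over chromosomes.
#' @export
count_recombinations <- function(segments) {
  stopifnot(length(unique(segments$line)) <= 1L)
  total <- 0L
  for (ch in unique(segments$chrom)) {
    s <- segments$source[segments$chrom == ch]
    s <- s[is_source(s)]
    if (length(s) >= 2L) total <- total + sum(s[-1L] != s[-length(s)])
  }
  total
}

#' Recombination events with breakpoint uncertainty intervals
#'
#' For each adjacent pair of SOURCE segments with different sources, the
#' breakpoint is reported as the interval between the last marker of the
#' left source segment and the first marker of the right source segment.
#' The two bounding indices are never equal: the crossover could not be
#' delimited more finely than this interval.
#'
#' @param segments a [compile_segments()] table (one or many lines).
#' @return data.frame with columns `line, chrom, left_anchor_index,
#'   right_anchor_index, left_marker, right_marker, source_left, source_right`.
#' @export
recombination_events <- function(segments) {
  res <- list()
  for (ln in unique(segments$line)) {
    for (ch in unique(segments$chrom[segments$line == ln])) {
      seg <- segments[segments$line == ln & segments$chrom == ch, , drop = FALSE]
      src <- seg[is_source(seg$source), , drop = FALSE]
      if (nrow(src) < 2L) next
      for (i in seq_len(nrow(src) - 1L)) {
        if (src$source[i] == src$source[i + 1L]) next
        res[[length(res) + 1L]] <- data.frame(
          line = ln, chrom = ch,
          left_anchor_index = src$end_index[i],
          right_anchor_index = src$start_index[i + 1L],
          left_marker = src$end_marker[i],
          right_marker = src$start_marker[i + 1L],
          source_left = src$source[i], source_right = src$source[i + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(line = character(0), chrom = character(0),
                      left_anchor_index = integer(0), right_anchor_index = integer(0),
                      left_marker = character(0), right_marker = character(0),
                      source_left = character(0), source_right = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Intact-chromosome statistics
#'
#' A chromosome is inherited intact by a line when exactly one distinct
#' SOURCE appears among its labels — i.e. every traceable marker resolves
#' to the same parent and no recombination was observed.  AMBIGUOUS,
#' CONFLICT and MISSING labels are transparent for intactness.
#'
#' @param origins origin matrix.
#' @param map the `genetic_map`.
#' @return list with `per_line` (data.frame: line, n_intact, n_chrom),
#'   `fraction_intact` (intact / (lines x chromosomes)) and
#'   `lines_with_intact` (number of lines with >= 1 intact chromosome).
#' @export
intact_chromosome_stats <- function(origins, map) {
  stopifnot(inherits(map, "genetic_map"), ncol(origins) == nrow(map))
  chroms <- unique(map$chrom)
  idx_by_ch <- lapply(chroms, function(ch) which(map$chrom == ch))
  n_intact <- vapply(rownames(origins), function(ln) {
    sum(vapply(idx_by_ch, function(idx) {
      lab <- origins[ln, idx]
      srcs <- unique(lab[is_source(lab)])
      length(srcs) == 1L
    }, logical(1L)))
  }, integer(1L))
  per_line <- data.frame(line = rownames(origins), n_intact = n_intact,
                         n_chrom = length(chroms), row.names = NULL,
                         stringsAsFactors = FALSE)
  list(per_line = per_line,
       fraction_intact = sum(n_intact) / (nrow(origins) * length(chroms)),
       lines_with_intact = sum(n_intact >= 1L))
}

#' Export IBD segments as BED4
#'
#' Uses the 0-based half-open BED convention: `start` = position of the
#' segment's first marker, `end` = position of its last marker + 1, so
#' single-marker segments are non-empty.  For cM maps, marker indices are
#' exported instead of positions and the track header notes it.
#'
#' @param segments a [compile_segments()] table.
#' @param map the `genetic_map` (bp positions preferred).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_segments_bed <- function(segments, map, path) {
  unit <- attr(map, "unit")
  header <- if (identical(unit, "bp")) {
    "track name=ibd_segments"
  } else {
    "track name=ibd_segments note=\"cM map: coordinates are marker indices\""
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(segments) > 0L) {
    if (identical(unit, "bp")) {
      start <- map$pos[match(segments$start_marker, map$marker)]
      end <- map$pos[match(segments$end_marker, map$marker)] + 1
    } else {
      start <- segments$start_index
      end <- segments$end_index + 1
    }
    lines <- sprintf("%s\t%d\t%d\t%s:%s", segments$chrom, as.integer(start),
                     as.integer(end), segments$line, segments$source)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Call an untyped locus by flanking IBD labels
#'
#' Genotypes a gene with no assay of its own by descent: for each line, if
#' the origin labels at both flanking markers are the same SOURCE, the gene
#' is called as inherited from that parent; otherwise NO-CALL (`NA`).
#'
#' @param origins origin matrix.
#' @param map the `genetic_map`.
#' @param chrom chromosome of the locus.
#' @param left_marker,right_marker ids of the flanking markers.
#' @return named character vector of per-line source calls (`NA` = no call).
#' @export
call_allele_by_flanks <- function(origins, map, chrom, left_marker, right_marker) {
  stopifnot(left_marker %in% map$marker, right_marker %in% map$marker)
  if (!all(map$chrom[match(c(left_marker, right_marker), map$marker)] == chrom)) {
    stop("call_allele_by_flanks: flanking markers not on the stated chromosome",
         call. = FALSE)
  }
  l <- origins[, left_marker]
  r <- origins[, right_marker]
  out <- ifelse(is_source(l) & is_source(r) & l == r, l, NA_character_)
  names(out) <- rownames(origins)
  out
}

#' Minimal chromosome-painting plot of IBD segments
#'
#' Draws each requested line's chromosomes as stacked horizontal bars,
#' colored by origin label — a quick visual of inheritance and
#' recombination, not a publication graphic.
#'
#' @param origins origin matrix.
#' @param map the `genetic_map`.
#' @param lines lines to paint; default all (capped at 20).
#' @param main plot title.
#' @return invisibly, the named color vector used.
#' @export
paint_segments <- function(origins, map, lines = NULL, main = "IBD segment painting") {
  if (is.null(lines)) lines <- utils::head(rownames(origins), 20L)
  segs <- do.call(rbind, lapply(lines, function(ln) {
    compile_segments(origins[ln, ], map, line_id = ln)
  }))
  labels <- sort(unique(segs$source))
  pal <- grDevices::hcl.colors(max(3L, length(labels)), "Dark 3")[seq_along(labels)]
  names(pal) <- labels
  pal[CONFLICT_LABEL] <- "black"
  pal[MISSING_LABEL] <- "grey80"
  chroms <- unique(map$chrom)
  n_row <- length(lines) * length(chroms)
  graphics::plot(NULL, xlim = c(0, max(tapply(seq_len(nrow(map)), map$chrom, length))),
                 ylim = c(0, n_row), xlab = "marker index (within chromosome)",
                 ylab = "", yaxt = "n", main = main)
  y <- n_row
  ylab <- character(0)
  for (ln in lines) {
    for (ch in chroms) {
      seg <- segs[segs$line == ln & segs$chrom == ch, , drop = FALSE]
      graphics::rect(seg$start_index, y - 0.8, seg$end_index + 1L, y,
                     col = pal[seg$source], border = NA)
      ylab <- c(ylab, paste(ln, ch, sep = ":"))
      y <- y - 1
    }
  }
  graphics::axis(2, at = seq(n_row, 1) - 0.4, labels = ylab, las = 2, cex.axis = 0.5)
  invisible(pal)
}
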