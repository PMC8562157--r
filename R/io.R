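#' Read and validate a pedigree file
#'
#' The pedigree is a delimited text file with header columns `line`,
#' `parent1`, `parent2`.  Unknown parents are encoded as `"-"`, `"NA"` or an
#' empty field and are kept as `NA`.  Validation enforces unique line ids,
#' forbids self-parentage and checks that the parent relation is acyclic.
#'
#' @param path path to a CSV (or other `sep`-delimited) pedigree file.
#' @param sep field separator, default comma.
#' @return a `pedigree` object: a data.frame with columns `line`, `parent1`,
#'   `parent2` (character; `NA` = unknown parent).
#' @export
read_pedigree <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("line", "parent1", "parent2")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have header columns line,parent1,parent2", call. = FALSE)
  }
  pedigree(df$line, df$parent1, df$parent2)
}

#' Construct a pedigree from vectors
#'
#' @param line,parent1,parent2 character vectors of equal length; parents may
#'   be `NA`, `""`, `"-"` or `"NA"` for unknown.
#' @return a validated `pedigree` data.frame.
#' @export
pedigree <- function(line, parent1, parent2) {
  unk <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "-", "NA", "unknown", "UNKNOWN")] <- NA_character_
    x
  }
  ped <- data.frame(line = as.character(line), parent1 = unk(parent1),
                    parent2 = unk(parent2), stringsAsFactors = FALSE)
  if (any(ped$line == "" | is.na(ped$line))) {
    stop("pedigree: empty line id", call. = FALSE)
  }
  check_ids(ped$line, "line")
  dup <- ped$line[duplicated(ped$line)]
  if (length(dup) > 0L) {
    stop(sprintf("pedigree: duplicate line id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  self <- ped$line == ped$parent1 | ped$line == ped$parent2
  if (any(self, na.rm = TRUE)) {
    stop(sprintf("pedigree: line(s) listed as their own parent: %s",
                 paste(ped$line[which(self)], collapse = ", ")), call. = FALSE)
  }
  cyc <- pedigree_cycle(ped)
  if (!is.null(cyc)) {
    stop(sprintf("pedigree: parentage cycle: %s", paste(cyc, collapse = " -> ")),
         call. = FALSE)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Depth-first search for a cycle in the line -> parent relation.
# Returns the cycle as a character vector, or NULL.
pedigree_cycle <- function(ped) {
  parents <- function(id) {
    i <- match(id, ped$line)
    if (is.na(i)) character(0) else
      stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
  }
  state <- new.env(parent = emptyenv()) # 1 = in stack, 2 = done
  visit <- function(id, stack) {
    st <- get0(id, envir = state, ifnotfound = 0L)
    if (st == 2L) return(NULL)
    if (st == 1L) return(c(stack[match(id, stack):length(stack)], id))
    assign(id, 1L, envir = state)
    for (p in parents(id)) {
      cyc <- visit(p, c(stack, id))
      if (!is.null(cyc)) return(cyc)
    }
    assign(id, 2L, envir = state)
    NULL
  }
  for (id in ped$line) {
    cyc <- visit(id, character(0))
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' Collapse backcross chains to a single cross
#'
#' A backcross-derived line whose non-recurrent parent shares the recurrent
#' parent (e.g. BC2 = BC1 x R with BC1 = F1 x R and F1 = D x R) is recoded
#' as if it originated from the single cross D x R.  The rewrite is applied
#' until a fixed point, so arbitrarily deep chains collapse, and is a no-op
#' on pedigrees without backcross patterns.
#'
#' @param ped a `pedigree`.
#' @return the rewritten `pedigree`.
#' @export
normalize_backcrosses <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  row_of <- function(id) match(id, ped$line)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ped))) {
      p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
      if (is.na(p1) || is.na(p2)) next
      # parent1 is itself a cross involving parent2 => parent2 is recurrent
      r1 <- row_of(p1)
      if (!is.na(r1) && !is.na(ped$parent1[r1]) && !is.na(ped$parent2[r1]) &&
          p2 %in% c(ped$parent1[r1], ped$parent2[r1])) {
        donor <- setdiff(c(ped$parent1[r1], ped$parent2[r1]), p2)
        if (length(donor) == 1L && donor != ped$parent1[i]) {
          ped$parent1[i] <- donor
          changed <- TRUE
          next
        }
      }
      r2 <- row_of(p2)
      if (!is.na(r2) && !is.na(ped$parent1[r2]) && !is.na(ped$parent2[r2]) &&
          p1 %in% c(ped$parent1[r2], ped$parent2[r2])) {
        donor <- setdiff(c(ped$parent1[r2], ped$parent2[r2]), p1)
        if (length(donor) == 1L && donor != ped$parent2[i]) {
          ped$parent2[i] <- donor
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ped
}

#' Genetic map constructor and reader
#'
#' A genetic map is the ordered list of markers used by every downstream
#' stage.  Only marker ORDER within chromosomes matters to the tracer, so the
#' position unit (cM or bp) is metadata.  Within a chromosome positions must
#' be non-decreasing in list order; list order is authoritative on ties.
#'
#' @param marker,chrom,pos parallel vectors of marker id, chromosome and
#'   position.
#' @param unit `"cM"` or `"bp"`.
#' @return a `genetic_map` data.frame with columns `marker`, `chrom`, `pos`.
#' @export
genetic_map <- function(marker, chrom, pos, unit = c("cM", "bp")) {
  unit <- match.arg(unit)
  map <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                    pos = as.numeric(pos), stringsAsFactors = FALSE)
  check_ids(map$marker, "marker")
  if (anyDuplicated(map$marker)) {
    stop("genetic map: duplicate marker id(s)", call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) {
      stop(sprintf("genetic map: positions on %s not non-decreasing in list order", ch),
           call. = FALSE)
    }
  }
  attr(map, "unit") <- unit
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname genetic_map
#' @param path CSV file with header `marker,chrom,pos`.
#' @export
read_genetic_map <- function(path, unit = c("cM", "bp")) {
  df <- utils::read.csv(path, colClasses = c(marker = "character", chrom = "character"))
  genetic_map(df$marker, df$chrom, df$pos, unit = match.arg(unit))
}

# -- genotype matrices --------------------------------------------------------

GENO_CODES <- c("A", "B", "H")

#' Read a genotype matrix
#'
#' Calls are mapped onto the canonical four-code alphabet: `"A"`
#' (REF-homozygote), `"B"` (ALT-homozygote), `"H"` (heterozygote) and `NA`
#' (missing).  Matrix input accepts `{A,B,H,NA}` or `{0,1,2,NA}` (0 = A,
#' 1 = H, 2 = B).  VCF input (via the VariantAnnotation package) keeps
#' biallelic SNPs only; multi-allelic records are skipped with a warning.
#' Markers are reordered to match the map; markers absent from the map are
#' dropped with a message.
#'
#' @param path input file.
#' @param format `"matrix"` (TSV, rows = lines, columns = markers) or `"vcf"`.
#' @param map a `genetic_map`; output columns follow map order.
#' @return a character matrix lines x markers with values in
#'   `c("A","B","H",NA)`; markers on the map but absent from the file are
#'   `NA` columns.
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"), map) {
  format <- match.arg(format)
  stopifnot(inherits(map, "genetic_map"))
  if (format == "matrix") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                            colClasses = "character", check.names = FALSE,
                            na.strings = c("NA", ""))
    calls <- as.matrix(df)
    calls[calls == "0"] <- "A"
    calls[calls == "1"] <- "H"
    calls[calls == "2"] <- "B"
    bad <- calls[!is.na(calls) & !(calls %in% GENO_CODES)]
    if (length(bad) > 0L) {
      stop(sprintf("genotype matrix: unrecognized call code(s): %s",
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
    }
  } else {
    calls <- read_vcf_calls(path)
  }
  align_to_map(calls, map)
}

# VCF import: biallelic SNP GT field -> A/B/H/NA, samples as rows.
read_vcf_calls <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF import requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    warning(sprintf("skipping %d multi-allelic VCF record(s)", sum(nalt != 1L)))
    vcf <- vcf[nalt == 1L, ]
  }
  gt <- VariantAnnotation::geno(vcf)$GT # variants x samples
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_character_, length(g))
    out[g %in% c("0/0")] <- "A"
    out[g %in% c("1/1")] <- "B"
    out[g %in% c("0/1", "1/0")] <- "H"
    out
  }
  calls <- apply(gt, 2L, code)
  rownames(calls) <- rownames(gt)
  t(calls) # lines x markers
}

# Reorder genotype columns to map order; drop markers not on the map.
align_to_map <- function(calls, map) {
  known <- colnames(calls) %in% map$marker
  if (any(!known)) {
    message(sprintf("dropping %d marker(s) absent from the genetic map", sum(!known)))
    calls <- calls[, known, drop = FALSE]
  }
  out <- matrix(NA_character_, nrow = nrow(calls), ncol = nrow(map),
                dimnames = list(rownames(calls), map$marker))
  out[, colnames(calls)] <- calls
  check_ids(rownames(out), "line")
  out
}

#' Write a genotype matrix as TSV
#'
#' @param calls character genotype matrix.
#' @param path output file.
#' @export
write_genotypes <- function(calls, path) {
  df <- data.frame(line = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- phenotypes ---------------------------------------------------------------

#' Read a phenotype table
#'
#' @param path CSV with header `line,env,trait,value`.
#' @return data.frame with those columns; `value` numeric.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, colClasses = c(line = "character", env = "character",
                                             trait = "character"))
  need <- c("line", "env", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have header columns line,env,trait,value", call. = FALSE)
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))) & !is.na(df$value))
    stop(sprintf("phenotypes: non-numeric value in row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  df[need]
}

#' Collapse replicated phenotype records
#'
#' Replicated (line, environment, trait) records from a single environment
#' are combined into one value per line; unreplicated records pass through
#' unchanged under both modes.
#'
#' `mode = "mean"` takes the arithmetic mean of replicates.  `mode =
#' "shrunken"` shrinks each line's replicate mean toward the environment
#' mean with the one-way random-effects factor
#' \eqn{b = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / r)}, where the variance
#' components come from a one-way ANOVA decomposition over lines within the
#' (environment, trait) cell and `r` is the line's replicate count.  This is
#' a deliberately simple stand-in for a full BLUP of entry means.
#'
#' @param raw data.frame with columns `line,env,trait,value`; may contain
#'   replicated rows.
#' @param mode `"mean"` or `"shrunken"`.
#' @return data.frame with at most one row per (line, env, trait).
#' @export
preprocess_phenotypes <- function(raw, mode = c("mean", "shrunken")) {
  mode <- match.arg(mode)
  if (!is.numeric(raw$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$value))))
    stop(sprintf("phenotypes: non-numeric value in row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  pieces <- split(raw, list(raw$env, raw$trait), drop = TRUE)
  out <- lapply(pieces, function(cell) {
    agg <- stats::aggregate(value ~ line, data = cell, FUN = mean)
    cnt <- stats::aggregate(value ~ line, data = cell, FUN = length)
    names(cnt)[2L] <- "r"
    agg <- merge(agg, cnt, by = "line")
    if (mode == "shrunken" && any(agg$r > 1L)) {
      vc <- oneway_varcomp(cell$value, cell$line)
      grand <- mean(agg$value) # mean of line means
      b <- vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2 / agg$r)
      val <- ifelse(agg$r > 1L, grand + b * (agg$value - grand), agg$value)
    } else {
      val <- agg$value
    }
    data.frame(line = agg$line, env = cell$env[1L], trait = cell$trait[1L],
               value = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$trait, out$env, out$line), , drop = FALSE]
}

# Method-of-moments one-way random effects decomposition (lines as groups).
# Balanced-design formula with the standard unbalanced n0 correction.
oneway_varcomp <- function(y, group) {
  group <- as.factor(group)
  n <- length(y)
  k <- nlevels(group)
  if (k >= n || k < 2L) {
    return(list(sigma_g2 = stats::var(y), sigma_e2 = 0))
  }
  means <- tapply(y, group, mean)
  ni <- tabulate(group)
  sse <- sum((y - means[group])^2)
  ssg <- sum(ni * (means - mean(y))^2)
  mse <- sse / (n - k)
  msg <- ssg / (k - 1L)
  n0 <- (n - sum(ni^2) / n) / (k - 1L)
  list(sigma_g2 = max(0, (msg - mse) / n0), sigma_e2 = mse)
}

# -- origin matrices on disk --------------------------------------------------

#' Read/write origin matrices
#'
#' Disk layout: TSV, first column `line`, remaining columns one per marker in
#' map order; cells are origin labels (see [origin-labels]): a parent id,
#' `"id1|id2"` for AMBIGUOUS, `"!"` for CONFLICT, `"."` for MISSING.
#'
#' @param origins character origin matrix (lines x markers).
#' @param path file path.
#' @return `read_origins()` returns the character matrix.
#' @export
write_origins <- function(origins, path) {
  df <- data.frame(line = rownames(origins), origins, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_origins
#' @export
read_origins <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  as.matrix(df)
}
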