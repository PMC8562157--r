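#' Fit per-marker, per-source allele effect estimates
#'
#' For one (trait, environment) cell: let \eqn{\mu} be the mean phenotype of
#' the training lines.  For each marker and each parental source \eqn{j}
#' observed there, the allele effect estimate is the raw class-mean
#' deviation \eqn{\alpha_j = \bar{y}_j - \mu}, where \eqn{\bar{y}_j} is the
#' mean phenotype of the \eqn{n_j} training lines that inherited the marker
#' from source \eqn{j}.  No shrinkage toward the mean is applied — each
#' \eqn{\alpha_j} is computed in a separate calculation.  Sources with
#' \eqn{n_j < n_{min}} get \eqn{\alpha_j = 0}.
#'
#' @param origins origin matrix; its rows define the traceable lines.
#' @param phenotypes preprocessed phenotype data.frame
#'   (`line,env,trait,value`, one row per line in the cell).
#' @param trait,environment which phenotype cell to fit.
#' @param n_min minimum class size for a non-zero alpha (default 1).
#' @param lines training lines; default all phenotyped-and-traced lines.
#'   Alphas and \eqn{\mu} are computed from these lines only.
#' @return an `aee_table`: list with `trait`, `env`, `mu`, `lines` and
#'   `alphas` (data.frame `marker, source, n, alpha`).
#' @export
fit_aee <- function(origins, phenotypes, trait, environment, n_min = 1L,
                    lines = NULL) {
  cell <- phenotypes[phenotypes$trait == trait & phenotypes$env == environment, ]
  if (anyDuplicated(cell$line)) {
    stop("fit_aee: replicated phenotype records; run preprocess_phenotypes() first",
         call. = FALSE)
  }
  if (is.null(lines)) lines <- intersect(rownames(origins), cell$line)
  lines <- intersect(lines, intersect(rownames(origins), cell$line))
  if (length(lines) == 0L) {
    stop("fit_aee: no phenotyped training lines among the traced lines", call. = FALSE)
  }
  y <- cell$value[match(lines, cell$line)]
  mu <- mean(y)
  lab <- origins[lines, , drop = FALSE]

  alphas <- list()
  for (j in seq_len(ncol(lab))) {
    col <- lab[, j]
    src <- is_source(col)
    if (!any(src)) next
    cls <- tapply(y[src], col[src], mean)
    n <- tapply(y[src], col[src], length)
    a <- cls - mu
    a[n < n_min] <- 0
    alphas[[length(alphas) + 1L]] <- data.frame(
      marker = colnames(lab)[j], source = names(cls),
      n = as.integer(n), alpha = as.numeric(a), stringsAsFactors = FALSE)
  }
  alphas <- if (length(alphas)) do.call(rbind, alphas) else
    data.frame(marker = character(0), source = character(0),
               n = integer(0), alpha = numeric(0), stringsAsFactors = FALSE)
  rownames(alphas) <- NULL
  structure(list(trait = trait, env = environment, mu = mu, lines = lines,
                 alphas = alphas),
            class = "aee_table")
}

#' @export
print.aee_table <- function(x, ...) {
  cat(sprintf("Allele effect table: trait '%s', environment '%s'\n", x$trait, x$env))
  cat(sprintf("  training lines: %d   mu = %.4g\n", length(x$lines), x$mu))
  cat(sprintf("  %d (marker, source) classes over %d markers\n",
              nrow(x$alphas), length(unique(x$alphas$marker))))
  invisible(x)
}

#' Build the numeric AEE matrix from origin labels
#'
#' Replaces each origin label with its allele effect estimate:
#' SOURCE(j) becomes \eqn{\alpha_j}; AMBIGUOUS(j,k) becomes
#' \eqn{(\alpha_j + \alpha_k)/2}; MISSING and CONFLICT become 0; a source
#' never seen in training also contributes 0 (the neutral deviation), so
#' predictions for unknown material default toward the population mean.
#' The matrix may include lines (e.g. a test set) that did not contribute
#' to the fit.
#'
#' @param origins origin matrix (any set of lines over the fitted markers).
#' @param aee an `aee_table` from [fit_aee()].
#' @return numeric matrix lines x markers in trait units.
#' @export
build_aee_matrix <- function(origins, aee) {
  stopifnot(inherits(aee, "aee_table"))
  out <- matrix(0, nrow = nrow(origins), ncol = ncol(origins),
                dimnames = dimnames(origins))
  by_marker <- split(aee$alphas[c("source", "alpha")], aee$alphas$marker)
  for (j in seq_len(ncol(origins))) {
    tab <- by_marker[[colnames(origins)[j]]]
    if (is.null(tab)) next
    lookup <- stats::setNames(tab$alpha, tab$source)
    col <- origins[, j]
    src <- is_source(col)
    if (any(src)) {
      a <- lookup[col[src]]
      a[is.na(a)] <- 0 # source unseen in training
      out[src, j] <- a
    }
    amb <- is_ambiguous(col)
    if (any(amb)) {
      pp <- ambiguous_parents(col[amb])
      a1 <- lookup[pp[, 1L]]; a1[is.na(a1)] <- 0
      a2 <- lookup[pp[, 2L]]; a2[is.na(a2)] <- 0
      out[amb, j] <- (a1 + a2) / 2
    }
  }
  out
}

#' Fit AEE matrices for several traits and environments
#'
#' Origin tracing is independent of trait and environment, so a single
#' origin matrix feeds one AEE fit per (trait, environment) combination
#' present in the phenotypes.
#'
#' @param origins origin matrix.
#' @param phenotypes preprocessed phenotype table.
#' @param traits,environments subsets to fit; default all present.
#' @param n_min forwarded to [fit_aee()].
#' @return named list `"trait/env" -> list(table = aee_table, matrix =
#'   AEE matrix)`.
#' @export
aee_pipeline <- function(origins, phenotypes, traits = NULL, environments = NULL,
                         n_min = 1L) {
  if (is.null(traits)) traits <- unique(phenotypes$trait)
  if (is.null(environments)) environments <- unique(phenotypes$env)
  out <- list()
  for (tr in traits) {
    for (env in environments) {
      if (!any(phenotypes$trait == tr & phenotypes$env == env)) next
      tab <- fit_aee(origins, phenotypes, tr, env, n_min = n_min)
      out[[paste(tr, env, sep = "/")]] <-
        list(table = tab, matrix = build_aee_matrix(origins, tab))
    }
  }
  out
}
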