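#' Ridge-regression BLUP with REML variance components
#'
#' Fits the mixed model \eqn{y = 1\beta + Xu + e} with
#' \eqn{u \sim (0, \sigma_u^2 I)} and \eqn{e \sim (0, \sigma_e^2 I)}.
#' Columns of `X` are centered internally.  The variance ratio
#' \eqn{\lambda = \sigma_e^2/\sigma_u^2} is estimated by REML: the
#' restricted likelihood is profiled onto \eqn{\lambda} through the
#' eigenvalue spectrum of the (column-centered) cross-product and maximized
#' by 1-D search over \eqn{\log\lambda} on the bracket
#' \eqn{[10^{-9}, 10^{9}]} with tolerance `1e-8`.  Marker effects are the
#' BLUPs at the optimum, equal to the closed-form ridge solution
#' \eqn{(X_c'X_c + \lambda I)^{-1} X_c'(y - \bar y)}.
#'
#' @param X numeric design matrix (raw marker codes or AEE values), rows
#'   aligned with `y`.
#' @param y numeric phenotype vector.
#' @param lambda fix the variance ratio instead of estimating it (used by
#'   oracle tests); default `NULL` = REML.
#' @return a `ridge_model`: list with `intercept` (so that predictions are
#'   `intercept + X_new %*% effects` on the original scale), `effects`,
#'   `lambda`, `sigma_u2`, `sigma_e2`, `loglik` (restricted), `train_mean`,
#'   `column_ids`.
#' @export
ridge_fit <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("ridge_fit: need at least 2 observations", call. = FALSE)
  if (length(y) != n) stop("ridge_fit: X rows and y length differ", call. = FALSE)
  if (stats::var(y) == 0) stop("ridge_fit: zero-variance phenotype", call. = FALSE)
  col_means <- colMeans(X)
  Zc <- sweep(X, 2L, col_means)
  sp <- reml_spectrum(Zc, y)

  if (is.null(lambda)) {
    obj <- function(loglam) reml_profile_loglik(exp(loglam), sp)
    opt <- stats::optimize(obj, interval = log(c(1e-9, 1e9)),
                           maximum = TRUE, tol = 1e-8)
    lambda <- exp(opt$maximum)
  }
  f <- sum(sp$eta2 / (sp$xi + lambda)) + if (sp$n0 > 0L) sp$eta0sq / lambda else 0
  sigma_u2 <- f / sp$df
  sigma_e2 <- lambda * sigma_u2

  # BLUP effects via the smaller of the two normal-equation forms
  yc <- y - mean(y)
  m <- ncol(Zc)
  u <- if (m <= n) {
    solve(crossprod(Zc) + diag(lambda, m), crossprod(Zc, yc))
  } else {
    crossprod(Zc, solve(tcrossprod(Zc) + diag(lambda, n), yc))
  }
  u <- drop(u)
  names(u) <- colnames(X)
  structure(list(
    intercept = mean(y) - sum(col_means * u),
    effects = u,
    lambda = lambda,
    sigma_u2 = sigma_u2,
    sigma_e2 = sigma_e2,
    loglik = reml_profile_loglik(lambda, sp),
    train_mean = mean(y),
    col_means = col_means,
    column_ids = colnames(X)
  ), class = "ridge_model")
}

# Eigen-spectrum summary used by the profiled restricted likelihood.
# With S = I - 11'/n, SZZ'S = ZcZc' (columns of Zc centered), whose nonzero
# eigenvalues xi and rotated responses eta are computed on the cheaper side
# (m x m crossprod when m < n).  eta0sq collects the squared response mass in
# the (n - 1 - r)-dimensional zero-eigenvalue subspace orthogonal to 1.
reml_spectrum <- function(Zc, y) {
  n <- nrow(Zc)
  m <- ncol(Zc)
  tol <- 1e-10
  if (m < n) {
    E <- eigen(crossprod(Zc), symmetric = TRUE)
    keep <- E$values > tol * max(E$values, 1)
    xi <- E$values[keep]
    U <- Zc %*% E$vectors[, keep, drop = FALSE]
    U <- sweep(U, 2L, sqrt(xi), "/")
    eta <- drop(crossprod(U, y))
  } else {
    E <- eigen(tcrossprod(Zc), symmetric = TRUE)
    keep <- E$values > tol * max(E$values, 1)
    xi <- E$values[keep]
    eta <- drop(crossprod(E$vectors[, keep, drop = FALSE], y))
  }
  ys <- y - mean(y)
  eta0sq <- max(0, sum(ys^2) - sum(eta^2))
  n0 <- (n - 1L) - length(xi)
  if (n0 <= 0L) {
    n0 <- 0L
    eta0sq <- 0
  }
  list(xi = xi, eta2 = eta^2, eta0sq = eta0sq, n0 = n0, df = n - 1L, n = n)
}

# Full profiled restricted log-likelihood at variance ratio lambda,
# including constants, so it can be compared 1:1 against a dense
# determinant-based evaluation.
reml_profile_loglik <- function(lambda, sp) {
  f <- sum(sp$eta2 / (sp$xi + lambda)) + if (sp$n0 > 0L) sp$eta0sq / lambda else 0
  g <- sum(log(sp$xi + lambda)) + sp$n0 * log(lambda)
  -0.5 * (sp$df * log(f / sp$df) + g + log(sp$n) + sp$df * (1 + log(2 * pi)))
}

#' Profiled restricted log-likelihood of the ridge mixed model
#'
#' Exposed for oracle testing: evaluates the REML criterion (profiled over
#' \eqn{\sigma_u^2}) at a given variance ratio via the eigenvalue spectrum.
#'
#' @inheritParams ridge_fit
#' @param lambda variance ratio \eqn{\sigma_e^2/\sigma_u^2}.
#' @return restricted log-likelihood (a scalar, constants included).
#' @export
ridge_reml_loglik <- function(X, y, lambda) {
  Zc <- sweep(as.matrix(X), 2L, colMeans(X))
  reml_profile_loglik(lambda, reml_spectrum(Zc, y))
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: %d effects, lambda = %.4g (sigma_u2 = %.4g, sigma_e2 = %.4g)\n",
              length(x$effects), x$lambda, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Predict phenotypes from a fitted ridge model
#'
#' @param model a `ridge_model`.
#' @param X_new matrix with the model's columns (checked by name when both
#'   are named).
#' @return numeric vector `intercept + X_new %*% effects`.
#' @export
ridge_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model$column_ids)) {
    if (!identical(colnames(X_new), model$column_ids)) {
      stop("ridge_predict: X_new columns do not match the fitted model", call. = FALSE)
    }
  }
  drop(model$intercept + X_new %*% model$effects)
}

#' Raw marker coding of a genotype matrix
#'
#' Codes calls as allele dosage 0/1/2 (`A` = 0, `H` = 1, `B` = 2); missing
#' calls are replaced by the column mean so they are neutral after
#' centering.
#'
#' @param calls character genotype matrix.
#' @return numeric matrix of the same shape.
#' @export
raw_marker_matrix <- function(calls) {
  X <- matrix(NA_real_, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  X[calls == "A"] <- 0
  X[calls == "H"] <- 1
  X[calls == "B"] <- 2
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na) > 0L) X[na] <- cm[na[, 2L]]
  X
}

#' Marker-based heritability
#'
#' Fits the ridge mixed model by REML on the supplied matrix and returns
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)} with the genomic
#' variance on the phenotype scale,
#' \eqn{\sigma_g^2 = \sigma_u^2 \cdot \mathrm{mean\,diag}(X_c X_c')}.
#'
#' @inheritParams ridge_fit
#' @return heritability in `[0, 1]`.
#' @export
marker_heritability <- function(X, y) {
  X <- as.matrix(X)
  fit <- ridge_fit(X, y)
  Zc <- sweep(X, 2L, colMeans(X))
  sigma_g2 <- fit$sigma_u2 * mean(rowSums(Zc^2))
  h2 <- sigma_g2 / (sigma_g2 + fit$sigma_e2)
  min(1, max(0, h2))
}

#' Train/test split evaluation
#'
#' Fits on a seeded random training fraction, predicts the held-out lines,
#' and reports the evaluation protocol used throughout: accuracy (Pearson
#' correlation of predicted vs observed in the test set), the mean observed
#' phenotype of the top-`q` predicted lines, the selection differential
#' against the test-set mean, the bottom-`q` observed mean, and the
#' marker-based heritability of the training set.
#'
#' @inheritParams ridge_fit
#' @param train_fraction fraction of lines used for training (default 0.8).
#' @param q selected fraction (default 0.10).
#' @param seed RNG seed; the same seed yields the same split, so competing
#'   methods can be compared on an identical test set.
#' @param strata optional factor: the split is sampled within each stratum
#'   (e.g. family).
#' @return an `eval_report` list.
#' @export
evaluate_split <- function(X, y, train_fraction = 0.8, q = 0.10, seed = 1L,
                           strata = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  if (is.null(strata)) {
    train <- sort(sample.int(n, max(2L, round(train_fraction * n))))
  } else {
    strata <- as.factor(strata)
    train <- sort(unlist(lapply(split(seq_len(n), strata), function(i) {
      sample(i, max(1L, round(train_fraction * length(i))))
    }), use.names = FALSE))
  }
  test <- setdiff(seq_len(n), train)
  fit <- ridge_fit(X[train, , drop = FALSE], y[train])
  pred <- ridge_predict(fit, X[test, , drop = FALSE])
  report_metrics(pred, y[test], q,
                 heritability = marker_heritability(X[train, , drop = FALSE], y[train]),
                 train = train, test = test, model = fit)
}

report_metrics <- function(pred, obs, q, heritability = NA_real_,
                           train = NULL, test = NULL, model = NULL) {
  ntop <- max(1L, round(q * length(obs)))
  ord <- order(pred, decreasing = TRUE)
  top_mean <- mean(obs[ord[seq_len(ntop)]])
  bottom_mean <- mean(obs[rev(ord)[seq_len(ntop)]])
  structure(list(
    accuracy = stats::cor(pred, obs),
    top_q_mean = top_mean,
    bottom_q_mean = bottom_mean,
    selection_differential = top_mean - mean(obs),
    test_mean = mean(obs),
    q = q,
    heritability = heritability,
    n_train = length(train), n_test = length(obs),
    train = train, test = test, model = model
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: accuracy %.3f | top-%d%% mean %.4g (diff %+.4g) | h2 %.3f\n",
    x$accuracy, round(100 * x$q), x$top_q_mean, x$selection_differential,
    x$heritability))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Lines are partitioned into `k` seeded disjoint folds; each line is
#' predicted exactly once from a model trained on the other folds.  Pooled
#' accuracy is the correlation over all out-of-fold predictions.
#'
#' @inheritParams evaluate_split
#' @param k number of folds (default 5).
#' @return list with `reports` (per-fold `eval_report`s), `pooled_accuracy`,
#'   `predictions` (out-of-fold, in input order) and `fold` assignments.
#' @export
cross_validate <- function(X, y, k = 5L, q = 0.10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    fit <- ridge_fit(X[train, , drop = FALSE], y[train])
    pred[test] <- ridge_predict(fit, X[test, , drop = FALSE])
    reports[[f]] <- report_metrics(pred[test], y[test], q,
                                   train = train, test = test)
  }
  list(reports = reports, pooled_accuracy = stats::cor(pred, y),
       predictions = pred, fold = fold)
}

#' Compare AEE-based and raw-marker genomic prediction
#'
#' Runs both prediction arms on an identical seeded train/test split: the
#' raw arm fits ridge BLUP on 0/1/2 marker codes; the tracing arm fits the
#' allele-effect table on the training lines only, rebuilds the AEE matrix
#' for all lines, and fits ridge BLUP on it.  Reports both accuracies and
#' their ratio (accuracy improvement), both top-`q` observed means and
#' their ratio (selection effectiveness), and the bottom-`q` means.
#'
#' @param origins origin matrix for the candidate lines.
#' @param genotypes character genotype matrix.
#' @param phenotypes preprocessed phenotype table.
#' @param trait,environment phenotype cell to evaluate.
#' @param seed split seed, shared by both arms.
#' @param mode `"split"` for a single 80/20 hold-out or `"cv"` for k-fold
#'   cross-validation with pooled out-of-fold accuracy (the protocol used
#'   for yield, reducing sampling bias in the accuracy estimate).  The AEE
#'   table is refit inside every training set, so test lines never leak
#'   into the class means.
#' @param k folds for `mode = "cv"`.
#' @param train_fraction,q evaluation protocol parameters.
#' @param n_min forwarded to [fit_aee()].
#' @return list with per-arm `eval_report`s and the comparison ratios.
#' @export
compare_methods <- function(origins, genotypes, phenotypes, trait, environment,
                            seed = 1L, mode = c("split", "cv"), k = 5L,
                            train_fraction = 0.8, q = 0.10, n_min = 1L) {
  mode <- match.arg(mode)
  cell <- phenotypes[phenotypes$trait == trait & phenotypes$env == environment, ]
  lines <- intersect(intersect(rownames(origins), rownames(genotypes)), cell$line)
  if (length(lines) < 5L) {
    stop("compare_methods: too few lines traced, genotyped and phenotyped", call. = FALSE)
  }
  y <- cell$value[match(lines, cell$line)]
  n <- length(lines)
  X_raw <- raw_marker_matrix(genotypes[lines, , drop = FALSE])

  # one arm evaluation on a fixed train/test partition
  eval_arm <- function(kind, train, test) {
    X <- if (kind == "raw") X_raw else {
      tab <- fit_aee(origins, phenotypes, trait, environment, n_min = n_min,
                     lines = lines[train])
      build_aee_matrix(origins[lines, , drop = FALSE], tab)
    }
    fit <- ridge_fit(X[train, , drop = FALSE], y[train])
    list(pred = ridge_predict(fit, X[test, , drop = FALSE]), model = fit)
  }

  set.seed(seed)
  if (mode == "split") {
    train <- sort(sample.int(n, max(2L, round(train_fraction * n))))
    test <- setdiff(seq_len(n), train)
    arm_raw <- eval_arm("raw", train, test)
    arm_aee <- eval_arm("aee", train, test)
    rep_raw <- report_metrics(arm_raw$pred, y[test], q, train = train,
                              test = test, model = arm_raw$model)
    rep_aee <- report_metrics(arm_aee$pred, y[test], q, train = train,
                              test = test, model = arm_aee$model)
    n_train <- length(train); n_test <- length(test)
  } else {
    fold <- sample(rep_len(seq_len(k), n))
    pred_raw <- pred_aee <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      pred_raw[test] <- eval_arm("raw", train, test)$pred
      pred_aee[test] <- eval_arm("aee", train, test)$pred
    }
    # pooled out-of-fold predictions, whole population as the test set
    rep_raw <- report_metrics(pred_raw, y, q, test = seq_len(n))
    rep_aee <- report_metrics(pred_aee, y, q, test = seq_len(n))
    n_train <- n - floor(n / k); n_test <- n
  }

  list(
    raw = rep_raw,
    aee = rep_aee,
    accuracy_ratio = rep_aee$accuracy / rep_raw$accuracy,
    top_q_ratio = rep_aee$top_q_mean / rep_raw$top_q_mean,
    bottom_q_ratio = rep_aee$bottom_q_mean / rep_raw$bottom_q_mean,
    mode = mode, n_train = n_train, n_test = n_test, seed = seed
  )
}
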