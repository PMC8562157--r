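# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by the most direct method available
# and must stay independent of the implementation paths they check.

# Nearest-anchor imputation by exhaustive per-marker search.
oracle_impute_flanks <- function(row, map) {
  out <- row
  for (i in seq_along(row)) {
    if (is_source(row[i])) next
    same <- which(map$chrom == map$chrom[i])
    lefts <- same[same < i & is_source(row[same])]
    rights <- same[same > i & is_source(row[same])]
    if (length(lefts) > 0L && length(rights) > 0L) {
      l <- row[max(lefts)]
      r <- row[min(rights)]
      if (l == r) out[i] <- l
    }
  }
  out
}

# Dense closed-form ridge solution at fixed lambda.
oracle_ridge_effects <- function(X, y, lambda) {
  Zc <- sweep(X, 2L, colMeans(X))
  drop(solve(crossprod(Zc) + diag(lambda, ncol(X)), crossprod(Zc, y - mean(y))))
}

# Determinant-based profiled restricted log-likelihood (V* = ZcZc' + lambda I,
# intercept-only fixed effects), evaluated without any eigendecomposition.
oracle_reml_loglik <- function(X, y, lambda) {
  n <- length(y)
  Zc <- sweep(X, 2L, colMeans(X))
  Vs <- tcrossprod(Zc) + diag(lambda, n)
  Vi <- solve(Vs)
  one <- rep(1, n)
  q <- drop(crossprod(one, Vi) %*% one)
  P <- Vi - (Vi %*% one %*% crossprod(one, Vi)) / q
  f <- drop(crossprod(y, P) %*% y)
  -0.5 * ((n - 1) * log(f / (n - 1)) + determinant(Vs)$modulus[1] + log(q) +
            (n - 1) * (1 + log(2 * pi)))
}

# Recombination count by direct pairwise scan of SOURCE labels.
oracle_recomb_count <- function(row, map) {
  total <- 0L
  for (ch in unique(map$chrom)) {
    s <- row[map$chrom == ch]
    s <- s[is_source(s)]
    if (length(s) >= 2L) total <- total + sum(s[-1L] != s[-length(s)])
  }
  total
}

# Small two-chromosome map.
tiny_map <- function(n1 = 5L, n2 = 5L, spacing = 10) {
  genetic_map(
    marker = c(sprintf("c1_m%d", seq_len(n1)), sprintf("c2_m%d", seq_len(n2))),
    chrom = rep(c("c1", "c2"), c(n1, n2)),
    pos = c(seq_len(n1), seq_len(n2)) * spacing - spacing)
}

# Fully informative biparental founders: P1 all-A, P2 all-B.
informative_parents <- function(map, ids = c("P1", "P2")) {
  g <- rbind(rep("A", nrow(map)), rep("B", nrow(map)))
  dimnames(g) <- list(ids, map$marker)
  g
}

# Random origin-label row over a map (seeded by the caller).
random_origin_row <- function(map, sources = c("p1", "p2")) {
  labels <- c(sources, ambiguous_label(sources[1], sources[2]), "!", ".")
  row <- sample(labels, nrow(map), replace = TRUE,
                prob = c(0.3, 0.3, 0.25, 0.05, 0.1))
  names(row) <- map$marker
  row
}

# Small simulated population (fast defaults for unit tests, overridable).
quick_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, lines_per_family = 15L, n_chromosomes = 2L,
         markers_per_chromosome = 40L),
    list(...))
  simulate_population(do.call(sim_config, args))
}
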