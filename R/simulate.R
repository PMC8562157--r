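#' Simulation configuration
#'
#' Desk-scale defaults emulate a nested association mapping (NAM) panel of
#' recombinant inbred lines: one hub founder crossed to each other founder,
#' F5-selfed RILs, evenly spaced SNP markers on chromosomes of realistic
#' genetic length, and founder-specific QTL alleles — the confounding that
#' parental allele tracing is designed to resolve (several founders can
#' share a SNP allele around a gene without sharing the causal allele).
#'
#' @param n_founders number of founder lines (NAM: hub + families).
#' @param design `"nam"` (hub crossed to each other founder) or
#'   `"biparental"` (founder 1 x founder 2 only).
#' @param lines_per_family RILs per cross.
#' @param n_chromosomes,markers_per_chromosome marker panel shape.
#' @param map_length_cM genetic length per chromosome (recycled).
#' @param selfing_generations selfing rounds after the F1 (5 = F5-like RIL);
#'   `0` doubles a single recombinant gamete.
#' @param alt_freq_range range of the per-marker ALT allele frequency from
#'   which ancestral haplotype alleles are drawn (uniform).
#' @param n_ancestral_haplotypes size of the ancestral haplotype pool each
#'   founder's genome is a mosaic of.  Modern crop founders descend from a
#'   handful of ancestors, so unrelated founders share long identical
#'   haplotypes; a pool smaller than `n_founders` reproduces that sharing
#'   (set `>= n_founders` for independent founders).
#' @param haplotype_block_cM length of the ancestral mosaic blocks in cM.
#' @param n_qtl number of additive QTL, placed on markers.
#' @param qtl_allele_mode `"founder-specific"` (each founder carries its own
#'   causal allele effect) or `"biallelic"` (effect rides on the SNP allele).
#' @param h2_target heritability the residual noise is scaled to.
#' @param error_rate probability a homozygous progeny call is flipped
#'   (genotyping error; default 0).
#' @param n_environments environments; each gets independent residual noise.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 6L, design = c("nam", "biparental"),
                       lines_per_family = 40L, n_chromosomes = 3L,
                       markers_per_chromosome = 60L, map_length_cM = 120,
                       selfing_generations = 5L, alt_freq_range = c(0.2, 0.8),
                       n_ancestral_haplotypes = 3L, haplotype_block_cM = 25,
                       n_qtl = 12L, qtl_allele_mode = c("founder-specific", "biallelic"),
                       h2_target = 0.5, error_rate = 0, n_environments = 1L,
                       seed = 1L) {
  design <- match.arg(design)
  qtl_allele_mode <- match.arg(qtl_allele_mode)
  stopifnot(n_founders >= 1L, lines_per_family >= 1L, n_chromosomes >= 1L,
            markers_per_chromosome >= 2L, all(map_length_cM >= 0),
            selfing_generations >= 0L, n_ancestral_haplotypes >= 1L,
            haplotype_block_cM > 0, n_qtl >= 1L,
            h2_target > 0, h2_target <= 1, error_rate >= 0, error_rate < 1)
  structure(list(
    n_founders = as.integer(n_founders), design = design,
    lines_per_family = as.integer(lines_per_family),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    map_length_cM = rep_len(map_length_cM, n_chromosomes),
    selfing_generations = as.integer(selfing_generations),
    alt_freq_range = alt_freq_range,
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    haplotype_block_cM = haplotype_block_cM,
    n_qtl = as.integer(n_qtl), qtl_allele_mode = qtl_allele_mode,
    h2_target = h2_target, error_rate = error_rate,
    n_environments = as.integer(n_environments), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Evenly spaced marker map for a simulation
#'
#' @param config a `sim_config`.
#' @return a `genetic_map` in cM.
#' @export
sim_map <- function(config) {
  maps <- lapply(seq_len(config$n_chromosomes), function(c_i) {
    mpc <- config$markers_per_chromosome
    data.frame(marker = sprintf("chr%d_m%03d", c_i, seq_len(mpc)),
               chrom = sprintf("chr%d", c_i),
               pos = seq(0, config$map_length_cM[c_i], length.out = mpc),
               stringsAsFactors = FALSE)
  })
  maps <- do.call(rbind, maps)
  genetic_map(maps$marker, maps$chrom, maps$pos, unit = "cM")
}

#' Simulate founder genotypes from a narrow ancestral base
#'
#' Founders are fully homozygous mosaics of a small pool of ancestral
#' haplotypes, emulating the narrow genetic base of modern crop germplasm:
#' within each mosaic block (of `haplotype_block_cM`), each founder copies
#' one of `n_ancestral_haplotypes` block haplotypes, whose alleles are
#' drawn with a per-marker ALT frequency from the configured uniform
#' range.  Founders that pick the same ancestral haplotype in a block are
#' identical-by-state over that whole block — yet may still carry different
#' causal alleles at a QTL inside it (founder-specific QTL mode), which is
#' exactly the confounding that origin tracing resolves and raw marker
#' codes cannot.
#'
#' @param config a `sim_config`.
#' @param seed optional seed (set when called standalone; [simulate_population()]
#'   manages the RNG itself).
#' @return character genotype matrix founders x markers (values `"A"`/`"B"`).
#' @export
simulate_founders <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- sim_map(config)
  m <- nrow(map)
  k <- config$n_ancestral_haplotypes
  p_alt <- stats::runif(m, config$alt_freq_range[1L], config$alt_freq_range[2L])
  ids <- sprintf("F%02d", seq_len(config$n_founders))
  calls <- matrix(NA_character_, nrow = config$n_founders, ncol = m,
                  dimnames = list(ids, map$marker))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    block <- floor(map$pos[idx] / config$haplotype_block_cM)
    for (b in unique(block)) {
      j <- idx[block == b]
      anc <- vapply(p_alt[j], function(p) {
        ifelse(stats::runif(k) < p, "B", "A")
      }, character(k))
      anc <- matrix(anc, nrow = k) # ancestral haplotypes x block markers
      pick <- sample.int(k, config$n_founders, replace = TRUE)
      calls[, j] <- anc[pick, , drop = FALSE]
    }
  }
  calls
}

# One gamete from a pair of origin haplotypes.  Crossovers per chromosome
# are Poisson with mean = map length in Morgans (Haldane, no interference),
# positions uniform; xo_positions overrides the draw (list keyed by chrom).
sim_gamete <- function(hapA, hapB, map, xo_positions = NULL) {
  out <- hapA
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    L <- max(pos) - min(pos)
    xo <- if (!is.null(xo_positions) && !is.null(xo_positions[[ch]])) {
      sort(xo_positions[[ch]])
    } else {
      sort(stats::runif(stats::rpois(1L, L / 100), min(pos), max(pos)))
    }
    phase <- (sample.int(2L, 1L) - 1L + findInterval(pos, xo, left.open = TRUE)) %% 2L
    out[idx] <- ifelse(phase == 0L, hapA[idx], hapB[idx])
  }
  out
}

#' Simulate one RIL genome by iterated meiosis and selfing
#'
#' Starts from the F1 of two inbred parents (haplotypes = parent ids at
#' every marker), applies `selfing_generations` rounds of selfing with
#' Poisson/Haldane crossovers, then forces homozygosity by resolving each
#' residual heterozygous run to one of its two haplotypes at random.  With
#' `selfing_generations = 0` a single recombinant gamete is doubled.
#'
#' @param parents 2-row character genotype matrix (rownames = parent ids),
#'   columns in map order; parents must be homozygous.
#' @param map the `genetic_map` (cM).
#' @param selfing_generations selfing rounds after the F1.
#' @param xo_positions optional scripted crossover positions for the first
#'   gamete (list `chrom -> numeric positions`); only meaningful with
#'   `selfing_generations = 0`.
#' @param seed optional seed.
#' @return list with `genotype` (character row), `origin` (parent id per
#'   marker) and `crossovers` (data.frame of origin switch intervals:
#'   `chrom, left_index, right_index` 0-based within-chromosome indices).
#' @export
simulate_meiosis <- function(parents, map, selfing_generations,
                             xo_positions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(parents) == 2L, ncol(parents) == nrow(map))
  ids <- rownames(parents)
  m <- nrow(map)
  hapA <- rep(ids[1L], m)
  hapB <- rep(ids[2L], m)
  if (selfing_generations == 0L) {
    origin <- sim_gamete(hapA, hapB, map, xo_positions)
  } else {
    h1 <- hapA; h2 <- hapB
    for (g in seq_len(selfing_generations)) {
      new1 <- sim_gamete(h1, h2, map)
      new2 <- sim_gamete(h1, h2, map)
      h1 <- new1; h2 <- new2
    }
    origin <- resolve_het_runs(h1, h2, map)
  }
  geno <- ifelse(origin == ids[1L], parents[1L, ], parents[2L, ])
  names(geno) <- map$marker
  names(origin) <- map$marker
  list(genotype = geno, origin = origin, crossovers = origin_switches(origin, map))
}

# Random whole-run resolution of residual heterozygosity: each maximal run
# where the two haplotypes disagree collapses to one of them by coin flip.
resolve_het_runs <- function(h1, h2, map) {
  out <- h1
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    het <- h1[idx] != h2[idx]
    if (!any(het)) next
    r <- rle(het)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    for (k in which(r$values)) {
      run <- idx[start[k]:end[k]]
      if (stats::runif(1L) < 0.5) out[run] <- h2[run]
    }
  }
  out
}

# Origin switch intervals (ground-truth breakpoints) of a resolved genome.
origin_switches <- function(origin, map) {
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    o <- origin[idx]
    sw <- which(o[-1L] != o[-length(o)])
    if (length(sw) > 0L) {
      res[[ch]] <- data.frame(chrom = ch, left_index = sw - 1L, right_index = sw,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(chrom = character(0), left_index = integer(0),
                      right_index = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate phenotypes with founder-specific or biallelic QTL
#'
#' QTL are placed on randomly chosen markers.  In `founder-specific` mode
#' each founder carries its own causal allele effect at each QTL (drawn
#' N(0,1)) and a line's genetic value sums the effects of its TRUE founder
#' origins at the QTL — so two founders can share the SNP allele yet give
#' opposite phenotypic effects, which raw marker regression cannot separate.
#' In `biallelic` mode the effect rides on the SNP allele itself (dosage
#' coding).  Residual noise is scaled so the realized heritability
#' var(g)/var(y) approximates `h2_target`.
#'
#' @param truth_origins character matrix lines x markers of true founder
#'   origins.
#' @param genotypes character genotype matrix for the same lines.
#' @param map the `genetic_map`.
#' @param config a `sim_config`.
#' @param seed optional seed.
#' @return list with `phenotypes` (data.frame `line,env,trait,value`),
#'   `qtl` (data.frame of positions and effects), `genetic_values`.
#' @export
simulate_phenotypes <- function(truth_origins, genotypes, map, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lines <- rownames(truth_origins)
  n <- length(lines)
  qtl_idx <- sort(sample.int(nrow(map), config$n_qtl))
  founders <- sort(unique(as.vector(truth_origins)))

  if (config$qtl_allele_mode == "founder-specific") {
    eff <- matrix(stats::rnorm(length(founders) * config$n_qtl),
                  nrow = length(founders),
                  dimnames = list(founders, map$marker[qtl_idx]))
    g <- rowSums(vapply(seq_along(qtl_idx), function(k) {
      eff[truth_origins[, qtl_idx[k]], k]
    }, numeric(n)))
    qtl <- data.frame(marker = map$marker[qtl_idx], chrom = map$chrom[qtl_idx],
                      pos = map$pos[qtl_idx], stringsAsFactors = FALSE)
    qtl <- cbind(qtl, t(eff)[, founders, drop = FALSE])
  } else {
    a <- stats::rnorm(config$n_qtl)
    dosage <- (genotypes[lines, qtl_idx, drop = FALSE] == "B") * 2
    g <- drop(dosage %*% a)
    qtl <- data.frame(marker = map$marker[qtl_idx], chrom = map$chrom[qtl_idx],
                      pos = map$pos[qtl_idx], effect = a, stringsAsFactors = FALSE)
  }
  names(g) <- lines

  var_g <- stats::var(g)
  sigma_e <- if (config$h2_target >= 1 || var_g == 0) 0 else
    sqrt(var_g * (1 - config$h2_target) / config$h2_target)
  envs <- sprintf("env%d", seq_len(config$n_environments))
  pheno <- do.call(rbind, lapply(envs, function(e) {
    data.frame(line = lines, env = e, trait = "trait1",
               value = g + stats::rnorm(n, 0, sigma_e), stringsAsFactors = FALSE)
  }))
  rownames(pheno) <- NULL
  list(phenotypes = pheno, qtl = qtl, genetic_values = g)
}

#' Simulate a full pedigreed population with ground truth
#'
#' Generates founders, the pedigree (NAM hub design or biparental), RIL
#' genomes by iterated meiosis, genotypes (with optional uniform genotyping
#' error), phenotypes, and the ground truth every module is tested against.
#'
#' @param config a `sim_config`.
#' @return a `sim_population` list: `config`, `map`, `pedigree`,
#'   `genotypes` (founders + RILs), `phenotypes`, and `truth` (list with
#'   `origins`, `crossovers`, `qtl`, `genetic_values`).
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- sim_map(config)
  founders <- simulate_founders(config)
  fids <- rownames(founders)

  if (config$design == "nam") {
    if (config$n_founders < 2L) stop("NAM design needs >= 2 founders", call. = FALSE)
    crosses <- lapply(fids[-1L], function(f) c(fids[1L], f))
  } else {
    if (config$n_founders < 2L) stop("biparental design needs 2 founders", call. = FALSE)
    crosses <- list(c(fids[1L], fids[2L]))
  }

  line_ids <- character(0)
  p1s <- character(0); p2s <- character(0)
  geno_rows <- list()
  origin_rows <- list()
  xo <- list()
  for (fam in seq_along(crosses)) {
    pr <- crosses[[fam]]
    for (i in seq_len(config$lines_per_family)) {
      ln <- sprintf("RIL%02d_%03d", fam, i)
      sim <- simulate_meiosis(founders[pr, , drop = FALSE], map,
                              config$selfing_generations)
      geno_rows[[ln]] <- sim$genotype
      origin_rows[[ln]] <- sim$origin
      xo[[ln]] <- sim$crossovers
      line_ids <- c(line_ids, ln)
      p1s <- c(p1s, pr[1L]); p2s <- c(p2s, pr[2L])
    }
  }
  truth_origins <- do.call(rbind, origin_rows)
  dimnames(truth_origins) <- list(line_ids, map$marker)
  line_geno <- do.call(rbind, geno_rows)
  dimnames(line_geno) <- list(line_ids, map$marker)

  if (config$error_rate > 0) {
    flip <- matrix(stats::runif(length(line_geno)) < config$error_rate,
                   nrow = nrow(line_geno))
    line_geno[flip & line_geno == "A"] <- "B"
    line_geno[flip & line_geno == "B"] <- "A"
  }

  ped <- pedigree(c(fids, line_ids),
                  c(rep(NA_character_, length(fids)), p1s),
                  c(rep(NA_character_, length(fids)), p2s))
  genotypes <- rbind(founders, line_geno)
  ph <- simulate_phenotypes(truth_origins, line_geno, map, config)

  structure(list(config = config, map = map, pedigree = ped,
                 genotypes = genotypes, phenotypes = ph$phenotypes,
                 truth = list(origins = truth_origins, crossovers = xo,
                              qtl = ph$qtl, genetic_values = ph$genetic_values)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d founders, %d lines, %d markers on %d chromosomes\n",
              x$config$n_founders, nrow(x$truth$origins), nrow(x$map),
              x$config$n_chromosomes))
  invisible(x)
}

#' Write a simulated population to plain-text files
#'
#' Writes `pedigree.csv`, `genotypes.tsv`, `map.csv`, `phenotypes.csv`,
#' `truth_origins.tsv` and `truth_qtl.tsv` into `dir`.
#'
#' @param sim a `sim_population`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(sim$pedigree)
  ped[is.na(ped)] <- "-"
  utils::write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE, quote = FALSE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.csv(as.data.frame(sim$map), file.path(dir, "map.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_origins(sim$truth$origins, file.path(dir, "truth_origins.tsv"))
  utils::write.table(sim$truth$qtl, file.path(dir, "truth_qtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Analytic linked-marker selection scenario
#'
#' A worked example of why tracking the parental segment beats selecting on
#' a linked SNP allele.  A single gene (effect 1 unit) sits 1 cM from a
#' biallelic SNP in a wild population with haplotype frequencies: A/Desired
#' 0.30, A/Wild 0.20, G/Desired 0.20, G/Wild 0.30.  All reported values are
#' computed from this table and the recombination fraction:
#' \itemize{
#'   \item base expected phenotype = P(Desired) = 0.5 units;
#'   \item selecting SNP allele A keeps P(A) = 50% of the population with
#'     expected phenotype P(Desired | A) = 0.6 units;
#'   \item intermating with IBD tracking of the marker-gene segment keeps
#'     the gene unless recombination separates it, giving 1 - c = 0.99
#'     units at c = 0.01.
#' }
#'
#' @param c recombination fraction between marker and gene (default 0.01,
#'   i.e. 1 cM).
#' @return list with the haplotype frequency table and the expected values.
#' @export
simulate_table4_scenario <- function(c = 0.01) {
  freq <- data.frame(
    marker = c("A", "A", "G", "G"),
    gene = c("Desired", "Wild", "Desired", "Wild"),
    freq = c(0.30, 0.20, 0.20, 0.30),
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(freq$freq) - 1) < 1e-12)
  gene_effect <- 1 # unit phenotype increase from the desired allele
  base <- sum(freq$freq[freq$gene == "Desired"]) * gene_effect
  p_sel <- sum(freq$freq[freq$marker == "A"])
  sel_pheno <- sum(freq$freq[freq$marker == "A" & freq$gene == "Desired"]) /
    p_sel * gene_effect
  ibd_pheno <- (1 - c) * gene_effect
  list(frequencies = freq,
       base_phenotype = base,
       selected_fraction = p_sel,
       selected_phenotype = sel_pheno,
       ibd_tracked_phenotype = ibd_pheno,
       recombination_fraction = c)
}
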