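test_that("founder genotypes follow the configured diversity", {
  # independent founders (pool >= founders), allele frequency fixed at 0.5:
  # two founders differ at a marker with probability 2 * 0.5 * 0.5 = 0.5
  cfg <- sim_config(n_founders = 2L, n_chromosomes = 4L,
                    markers_per_chromosome = 250L,
                    alt_freq_range = c(0.5, 0.5), n_ancestral_haplotypes = 99L)
  f <- simulate_founders(cfg, seed = 3)
  expect_equal(dim(f), c(2L, 1000L))
  expect_true(all(f %in% c("A", "B")))
  informative <- mean(f[1, ] != f[2, ])
  expect_equal(informative, 0.5, tolerance = 0.1)
  # seed determinism
  expect_identical(simulate_founders(cfg, seed = 3), f)
})

test_that("a narrow ancestral pool makes founders share haplotype blocks", {
  cfg <- sim_config(n_founders = 6L, n_ancestral_haplotypes = 2L,
                    haplotype_block_cM = 1000, markers_per_chromosome = 50L)
  f <- simulate_founders(cfg, seed = 4)
  # with one block per chromosome and 2 ancestral haplotypes, each pair of
  # founders is either identical or complementary over a whole chromosome
  idx <- 1:50 # chromosome 1
  patterns <- unique(apply(f[, idx], 1, paste, collapse = ""))
  expect_lte(length(patterns), 2L)
})

test_that("identical parents yield clonal progeny", {
  # degenerate diversity: a single ancestral haplotype makes both parents
  # copies of one genome, so every RIL is identical to it
  cfg <- sim_config(design = "biparental", n_founders = 2L,
                    n_ancestral_haplotypes = 1L, lines_per_family = 5L,
                    n_chromosomes = 1L, markers_per_chromosome = 20L)
  sim <- simulate_population(cfg)
  f1 <- sim$genotypes["F01", ]
  for (ln in rownames(sim$truth$origins)) {
    expect_equal(unname(sim$genotypes[ln, ]), unname(f1))
  }
  expect_error(simulate_population(sim_config(n_founders = 1L, design = "biparental")),
               "founders")
})

test_that("zero map length means no crossovers, intact chromosomes", {
  map <- genetic_map(sprintf("m%d", 1:10), rep("c1", 10), rep(0, 10))
  parents <- informative_parents(map)
  sim <- simulate_meiosis(parents, map, selfing_generations = 3L, seed = 5)
  expect_equal(nrow(sim$crossovers), 0L)
  expect_equal(length(unique(sim$origin)), 1L)
})

test_that("gamete crossover count matches the Poisson expectation", {
  # 1 Morgan chromosome, dense markers: mean origin switches per doubled
  # gamete ~ Poisson mean 1.0 (multiple hits between adjacent markers are
  # negligible at 1 cM spacing)
  map <- genetic_map(sprintf("m%d", 1:101), rep("c1", 101), 0:100)
  parents <- informative_parents(map)
  set.seed(31)
  n_gam <- 2000
  switches <- replicate(n_gam, {
    nrow(simulate_meiosis(parents, map, selfing_generations = 0L)$crossovers)
  })
  se <- sd(switches) / sqrt(n_gam)
  expect_lt(abs(mean(switches) - 1), 3 * se + 0.02)
})

test_that("scripted crossover injection switches origin exactly there", {
  map <- genetic_map(sprintf("m%d", 1:10), rep("c1", 10), seq(0, 90, by = 10))
  parents <- informative_parents(map)
  sim <- simulate_meiosis(parents, map, selfing_generations = 0L,
                          xo_positions = list(c1 = 35), seed = 8)
  expect_equal(sim$crossovers$left_index, 3L) # between m4 (pos 30) and m5 (pos 40)
  expect_equal(sim$crossovers$right_index, 4L)
  expect_equal(length(unique(sim$origin[1:4])), 1L)
  expect_equal(length(unique(sim$origin[5:10])), 1L)
})

test_that("genotypes and truth origins are mutually consistent", {
  sim <- quick_sim(seed = 44)
  founders <- sim$genotypes[sprintf("F%02d", 1:6), ]
  lines <- rownames(sim$truth$origins)
  for (ln in sample(lines, 10)) {
    origin <- sim$truth$origins[ln, ]
    expected <- founders[cbind(origin, colnames(founders))]
    expect_equal(unname(sim$genotypes[ln, ]), unname(expected))
  }
})

test_that("simulated populations are seed-deterministic", {
  s1 <- quick_sim(seed = 12)
  s2 <- quick_sim(seed = 12)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$origins, s2$truth$origins)
})

test_that("noiseless phenotypes equal the genetic values", {
  sim <- quick_sim(seed = 9, h2_target = 1)
  ph <- sim$phenotypes
  expect_equal(ph$value, unname(sim$truth$genetic_values[ph$line]))
})

test_that("realized heritability is calibrated to the target", {
  # decoupled from meiosis: draw many lines' founder origins directly
  cfg <- sim_config(h2_target = 0.5, n_qtl = 15L)
  map <- sim_map(cfg)
  set.seed(77)
  h2 <- replicate(5, {
    lines <- sprintf("L%04d", 1:1000)
    origins <- matrix(sample(sprintf("F%02d", 1:6), 1000 * nrow(map), TRUE),
                      nrow = 1000, dimnames = list(lines, map$marker))
    geno <- matrix(sample(c("A", "B"), 1000 * nrow(map), TRUE),
                   nrow = 1000, dimnames = list(lines, map$marker))
    out <- simulate_phenotypes(origins, geno, map, cfg)
    g <- out$genetic_values[out$phenotypes$line]
    var(g) / var(out$phenotypes$value)
  })
  expect_equal(mean(h2), 0.5, tolerance = 0.1)
})

test_that("founder-specific QTL defeat dosage regression but not class means", {
  # two founders share the SNP allele at the QTL but carry opposite causal
  # effects: the allele-dosage effect cancels while per-founder class means
  # separate - the confounding origin tracing is designed to resolve
  set.seed(202)
  n <- 400
  origin <- sample(c("F01", "F02"), n, TRUE)
  dosage <- rep(2, n)                      # both founders carry allele B
  y <- ifelse(origin == "F01", 1, -1) + rnorm(n, sd = 0.3)
  expect_lt(abs(coef(lm(y ~ dosage))[1]), Inf) # dosage column is constant
  expect_true(is.na(coef(lm(y ~ dosage))[2]))
  class_means <- tapply(y, origin, mean)
  expect_gt(abs(class_means["F01"] - class_means["F02"]), 1.5)
})

test_that("the linked-marker selection scenario computes the expected values", {
  sc <- simulate_table4_scenario()
  expect_equal(sc$base_phenotype, 0.5)
  expect_equal(sc$selected_fraction, 0.5)
  expect_equal(sc$selected_phenotype, 0.6)
  expect_equal(sc$ibd_tracked_phenotype, 0.99)
  # the values respond to the recombination fraction, they are not constants
  sc2 <- simulate_table4_scenario(c = 0.1)
  expect_equal(sc2$ibd_tracked_phenotype, 0.9)
})

test_that("write_simulation round-trips through the text formats", {
  sim <- quick_sim(seed = 2, lines_per_family = 5L)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("pedigree.csv", "genotypes.tsv", "map.csv",
                    "phenotypes.csv", "truth_origins.tsv", "truth_qtl.tsv"))
  map <- read_genetic_map(file.path(dir, "map.csv"))
  expect_equal(map$marker, sim$map$marker)
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"), "matrix", map)
  expect_identical(geno, sim$genotypes)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(ped$line, sim$pedigree$line)
  orig <- read_origins(file.path(dir, "truth_origins.tsv"))
  expect_identical(orig, sim$truth$origins)
})
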