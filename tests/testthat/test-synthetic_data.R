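# Population, phenotype, annotation-bundle and diallel generators:
# Mendelian selfing expectations, Haldane closed forms, seed determinism
# and construction bookkeeping.

test_that("selfing halves heterozygosity: F7 residual het near (1/2)^6", {
  cfg <- sim_config(n_lines = 800, chr_lengths_cM = c(100, 100),
                    marker_spacing_cM = 10, traits = list(), seed = 21)
  pop <- simulate_ril_population(cfg)
  het <- mean(pop$genotypes == 1L)
  expected <- 0.5^6
  n_calls <- length(pop$genotypes)
  se <- sqrt(expected * (1 - expected) / n_calls)
  expect_lt(abs(het - expected), 4 * se + 1e-12)
})

test_that("parental allele frequency is 0.5 within binomial bounds", {
  cfg <- sim_config(n_lines = 2000, chr_lengths_cM = c(60),
                    marker_spacing_cM = 20, traits = list(), seed = 31)
  pop <- simulate_ril_population(cfg)
  freq <- colMeans(pop$genotypes) / 2
  se <- sqrt(0.5 * 0.5 / nrow(pop$genotypes))
  expect_true(all(abs(freq - 0.5) < 3 * se * 2))  # dosage var ~2x binomial
})

test_that("gamete recombination fraction matches the Haldane closed form", {
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(haldane_r(0), 0)
  # measured on simulated gametes from a fully heterozygous parent
  set.seed(55)
  pos <- c(0, 10)
  hap <- rbind(c(0L, 0L), c(1L, 1L))
  n <- 20000
  rec <- replicate(n, {
    g <- qtlprior:::sim_gamete_chr(hap, pos, 10)
    g[1L] != g[2L]
  })
  r_hat <- mean(rec)
  r_true <- haldane_r(10)
  expect_lt(abs(r_hat - r_true), 4 * sqrt(r_true * (1 - r_true) / n))
})

test_that("generators are seed-deterministic", {
  cfg <- sim_config(n_lines = 40, chr_lengths_cM = c(50),
                    marker_spacing_cM = 5,
                    traits = list(sim_trait("T", qtls = list(
                      qtl_spec(1, 25, pvar = 0.3)))), seed = 9)
  a <- simulate_ril_population(cfg)
  b <- simulate_ril_population(cfg)
  expect_identical(a$genotypes, b$genotypes)
  pa <- simulate_phenotypes(a$genotypes, a$map, cfg)
  pb <- simulate_phenotypes(b$genotypes, b$map, cfg)
  expect_identical(pa, pb)
  da <- simulate_diallel_panel(6, "s1", 1, seed = 3)
  db <- simulate_diallel_panel(6, "s1", 1, seed = 3)
  expect_identical(da, db)
})

test_that("config validation rejects impossible inputs", {
  expect_error(sim_config(chr_lengths_cM = c(0, 50), traits = list(),
                          seed = 1), "zero-length")
  expect_error(sim_config(traits = list(), seed = NULL), "seed")
  expect_error(
    sim_config(traits = list(sim_trait("T", qtls = list(
      qtl_spec(1, 500, pvar = 0.1)))), seed = 1),
    "outside")
  expect_error(
    sim_config(traits = list(sim_trait("T", qtls = list(
      qtl_spec(1, 10, pvar = 0.7), qtl_spec(1, 50, pvar = 0.6)))),
      seed = 1),
    "exceed")
})

test_that("opposite-sign QTLs produce transgressive segregation", {
  cfg <- sim_config(n_lines = 300, chr_lengths_cM = c(80, 80),
                    marker_spacing_cM = 4, n_replicates = 2,
                    traits = list(sim_trait("T", h2 = 0.9, qtls = list(
                      qtl_spec(1, 40, a = 1), qtl_spec(2, 40, a = -1)))),
                    seed = 13)
  pop <- simulate_ril_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$map, cfg)
  y <- line_means(ph, "T", "env1")
  # parental expectations: P1 (all dosage 0) = -a1 - a2 = 0; P2 = 0;
  # recombinants stack both increasing (or both decreasing) alleles
  expect_gt(max(y), 1)
  expect_lt(min(y), -1)
})

test_that("large-sample ANOVA heritability recovers the target", {
  cfg <- sim_config(n_lines = 2000, chr_lengths_cM = c(60),
                    marker_spacing_cM = 10, n_environments = 1,
                    n_replicates = 2, gxe_sd = 0,
                    traits = list(sim_trait("T", h2 = 0.6, qtls = list(
                      qtl_spec(1, 30, pvar = 0.3)))), seed = 17)
  pop <- simulate_ril_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$map, cfg)
  h2 <- estimate_heritability(ph, "T", "env1")
  expect_lt(abs(h2 - 0.6), 0.05)
})

test_that("null phenotypes rarely clear the permutation threshold", {
  cfg <- sim_config(n_lines = 120, chr_lengths_cM = c(80, 80),
                    marker_spacing_cM = 4, n_environments = 1,
                    traits = list(sim_trait("T", h2 = 0.5, qtls = list())),
                    seed = 23)
  pop <- simulate_ril_population(cfg)
  hits <- 0L
  n_sims <- 40L
  set.seed(77)
  for (s in seq_len(n_sims)) {
    y <- rnorm(nrow(pop$genotypes))
    names(y) <- rownames(pop$genotypes)
    th <- permutation_threshold(pop$genotypes, pop$map, y, n_perm = 300,
                                seed = 1000 + s)
    sc <- marker_scan(pop$genotypes, pop$map, y)
    if (max(sc$lod, na.rm = TRUE) > th) hits <- hits + 1L
  }
  expect_lte(hits / n_sims, 0.20)  # 5% nominal; generous bound at tiny n
})

test_that("half-diallel combinatorics and additive construction hold", {
  d20 <- simulate_diallel_panel(20, "snp1", 2, seed = 2)
  expect_equal(nrow(d20$genotypes), 190L)
  d10 <- simulate_diallel_panel(10, "snp1", 2, seed = 2)
  expect_equal(nrow(d10$genotypes), 45L)
  expect_error(simulate_diallel_panel(2, "s", 1, seed = 1), ">= 3")
  # additive SNP effect 2u: homozygote groups differ by 2 x 2u; het at
  # midpoint when d = 0 (check on noiseless construction)
  d <- simulate_diallel_panel(16, "snp1", effects = 2, noise_sd = 1e-9,
                              seed = 8)
  y <- setNames(d$phenotypes$value, d$phenotypes$line)[rownames(d$genotypes)]
  g <- d$genotypes[, 1L]
  if (all(c(0, 1, 2) %in% g)) {
    expect_equal(mean(y[g == 2]) - mean(y[g == 0]), 4, tolerance = 1e-6)
    expect_equal(mean(y[g == 1]), (mean(y[g == 0]) + mean(y[g == 2])) / 2,
                 tolerance = 1e-6)
  }
})

test_that("annotation bundle bookkeeping matches its construction", {
  cfg <- sim_config(n_lines = 30, chr_lengths_cM = c(40, 40),
                    marker_spacing_cM = 5,
                    traits = list(sim_trait("T", qtls = list(
                      qtl_spec(1, 20, pvar = 0.2)))), seed = 41)
  pop <- simulate_ril_population(cfg)
  bundle <- simulate_annotation_bundle(pop$map, pop$truth,
                                       n_genes_per_cM = 0.5, seed = 42)
  expect_length(bundle$gene_models, round(80 * 0.5))
  expect_equal(length(unique(bundle$expression$gene_id)),
               length(bundle$gene_models))
  expect_equal(nrow(bundle$descriptions), length(bundle$gene_models))
  # the planted causal variant classifies HIGH / stop_gained
  ann <- classify_variants(bundle$variants, bundle$gene_models, bundle$ref)
  cg <- bundle$truth_genes
  hit <- ann[!is.na(ann$gene_id) & ann$gene_id == cg$gene_id[1L] &
               ann$snp_id == cg$snp_id[1L], ]
  expect_equal(hit$term, "stop_gained")
  expect_equal(hit$impact, "HIGH")
})
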