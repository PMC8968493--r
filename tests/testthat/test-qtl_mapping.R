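# Marker scans against the regression oracle, permutation thresholds,
# composite scans, LOD-drop intervals, robust-QTL logic, epistasis, joint
# models, gene action and heritability.

test_that("marker_scan equals the closed-form regression oracle", {
  map <- tiny_map(c("M01", "M02"))
  g <- tiny_geno(cbind(c(0, 0, 0, 0, 2, 2, 2, 2),
                       c(0, 2, 0, 2, 0, 2, 0, 2)),
                 markers = c("M01", "M02"))
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)
  names(y) <- rownames(g)
  sc <- marker_scan(g, map, y, min_n = 2)
  expect_equal(sc$lod[sc$marker == "M01"], oracle_lod(g[, 1], y),
               tolerance = 1e-9)
  expect_equal(sc$lod[sc$marker == "M02"], oracle_lod(g[, 2], y),
               tolerance = 1e-9)
})

test_that("scan LOD matches lm oracle on many random instances with NAs", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    m <- sample(3:8, 1)
    map <- tiny_map(sprintf("M%02d", 1:m), pos_cM = seq(0, by = 5,
                                                        length.out = m))
    g <- tiny_geno(matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE,
                                 prob = c(.49, .02, .49)), n),
                   markers = map$marker)
    g[sample(length(g), round(0.05 * length(g)))] <- NA
    y <- rnorm(n) + g[, 1] %% 3 * rnorm(1, 0, 0.5)
    names(y) <- rownames(g)
    sc <- marker_scan(g, map, y, min_n = 5)
    for (j in 1:m) {
      expect_equal(sc$lod[sc$marker == map$marker[j]],
                   oracle_lod(g[, j], y), tolerance = 1e-9)
    }
  }
})

test_that("monomorphic markers get LOD 0; duplicates get identical LOD", {
  map <- tiny_map(c("M01", "M02", "M03"))
  g <- tiny_geno(cbind(rep(0L, 30), sample(c(0L, 2L), 30, TRUE),
                       rep(NA_integer_, 30)), markers = map$marker)
  g[, 3] <- g[, 2]
  y <- rnorm(30); names(y) <- rownames(g)
  sc <- marker_scan(g, map, y, min_n = 5)
  expect_equal(sc$lod[sc$marker == "M01"], 0)
  expect_identical(sc$flag[sc$marker == "M01"], "monomorphic")
  expect_equal(sc$lod[sc$marker == "M02"], sc$lod[sc$marker == "M03"])
})

test_that("log transform offsets non-positive phenotypes before scanning", {
  map <- tiny_map("M01")
  set.seed(3)
  g <- tiny_geno(matrix(sample(c(0L, 2L), 40, TRUE), 40),
                 markers = "M01")
  y <- 10^(rnorm(40) + (g[, 1] - 1)) - 5  # has negatives
  names(y) <- rownames(g)
  expect_silent(sc <- marker_scan(g, map, y, log_transform = TRUE,
                                  min_n = 5))
  expect_true(is.finite(sc$lod))
})

test_that("permutation threshold: extremes, determinism, and relabel order", {
  map <- tiny_map(sprintf("M%02d", 1:10),
                  pos_cM = seq(0, 90, by = 10))
  set.seed(7)
  g <- tiny_geno(matrix(sample(c(0L, 2L), 50 * 10, TRUE), 50),
                 markers = map$marker)
  y <- rnorm(50); names(y) <- rownames(g)
  t1 <- permutation_threshold(g, map, y, n_perm = 200, seed = 5, min_n = 5)
  t2 <- permutation_threshold(g, map, y, n_perm = 200, seed = 5, min_n = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_identical(attr(t1, "max_lods"), attr(t2, "max_lods"))
  # alpha = 1 -> the minimum of the permuted maxima
  t_min <- permutation_threshold(g, map, y, n_perm = 200, alpha = 1,
                                 seed = 5, min_n = 5)
  expect_equal(as.numeric(t_min), min(attr(t_min, "max_lods")))
  expect_warning(permutation_threshold(g, map, y, n_perm = 50, seed = 1,
                                       min_n = 5), "unstable")
})

test_that("composite scan reduces to marker scan and honors the window", {
  cfg <- sim_config(n_lines = 150, chr_lengths_cM = c(100),
                    marker_spacing_cM = 5,
                    traits = list(sim_trait("T", h2 = 0.7, qtls = list(
                      qtl_spec(1, 50, pvar = 0.4)))), seed = 19)
  pop <- simulate_ril_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$map, cfg)
  y <- line_means(ph, "T", "env1", rownames(pop$genotypes))
  plain <- marker_scan(pop$genotypes, pop$map, y)
  comp0 <- composite_scan(pop$genotypes, pop$map, y,
                          cofactors = character(0))
  expect_equal(comp0$lod, plain$lod, tolerance = 1e-12)
  # cofactor within the window of the test position is excluded there:
  # conditioning on a marker 5 cM away must NOT null the QTL peak itself
  peak_marker <- plain$marker[which.max(plain$lod)]
  near <- pop$map$marker[abs(pop$map$pos_cM -
                               plain$pos_cM[which.max(plain$lod)]) == 5][1]
  comp <- composite_scan(pop$genotypes, pop$map, y, cofactors = near,
                         window_cM = 10)
  expect_gt(comp$lod[comp$marker == peak_marker],
            0.8 * plain$lod[plain$marker == peak_marker])
})

test_that("conditioning on the true QTL removes a linked decoy peak", {
  cfg <- sim_config(n_lines = 250, chr_lengths_cM = c(100),
                    marker_spacing_cM = 2,
                    traits = list(sim_trait("T", h2 = 0.8, qtls = list(
                      qtl_spec(1, 30, pvar = 0.5)))), seed = 29)
  pop <- simulate_ril_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$map, cfg)
  y <- line_means(ph, "T", "env1", rownames(pop$genotypes))
  plain <- marker_scan(pop$genotypes, pop$map, y)
  # decoy region 26 cM away shows an inflated shoulder in the plain scan
  decoy <- pop$map$marker[pop$map$pos_cM == 56]
  true_mk <- pop$truth$qtls$marker[1]
  comp <- composite_scan(pop$genotypes, pop$map, y, cofactors = true_mk,
                         window_cM = 10)
  expect_lt(comp$lod[comp$marker == decoy],
            0.4 * plain$lod[plain$marker == decoy] + 0.5)
})

test_that("LOD-drop interval geometry, truncation and nesting", {
  # symmetric triangle: slope 1 LOD/cM on a 1-cM grid, peak 10 at 50 cM
  pos <- 40:60
  prof <- data.frame(marker = sprintf("M%02d", pos), chrom = "chr1",
                     pos_cM = pos, lod = 10 - abs(pos - 50),
                     n = 100, flag = "", stringsAsFactors = FALSE)
  class(prof) <- c("lod_profile", "data.frame")
  expect_equal(unname(lod_drop_interval(prof, "M50", 1.5)), c(48, 52))
  # at drop 2 the walk stops where LOD first touches peak - drop (48/52),
  # so on this grid the flanking-marker rule gives the same endpoints
  expect_equal(unname(lod_drop_interval(prof, "M50", 2.0)), c(48, 52))
  # a shallower slope separates the two drops
  prof3 <- prof
  prof3$lod <- 10 - abs(pos - 50) * 0.6
  expect_equal(unname(lod_drop_interval(prof3, "M50", 1.5)), c(47, 53))
  expect_equal(unname(lod_drop_interval(prof3, "M50", 2.0)), c(46, 54))
  # monotone rise to the chromosome end truncates there
  prof2 <- prof
  prof2$lod <- seq(0, 10, length.out = nrow(prof2))
  expect_equal(unname(lod_drop_interval(prof2, "M60", 1.5))[2], 60)
  expect_error(lod_drop_interval(prof, "nope", 1.5), "not on profile")
  # property: 1.5-LOD interval nested in the 2-LOD interval
  set.seed(83)
  for (k in 1:200) {
    lods <- abs(cumsum(rnorm(40)))
    p <- data.frame(marker = sprintf("R%02d", 1:40), chrom = "chr1",
                    pos_cM = seq(1, 40), lod = lods, n = 50, flag = "",
                    stringsAsFactors = FALSE)
    pk <- p$marker[which.max(p$lod)]
    i15 <- lod_drop_interval(p, pk, 1.5)
    i20 <- lod_drop_interval(p, pk, 2.0)
    expect_lte(i20[1], i15[1])
    expect_gte(i20[2], i15[2])
    expect_gte(p$pos_cM[which.max(p$lod)], i15[1])
    expect_lte(p$pos_cM[which.max(p$lod)], i15[2])
  }
})

test_that("robust-QTL rule: >= 2 environments, clustered within window", {
  mk <- sprintf("M%02d", 1:21)
  mkpos <- seq(0, 100, by = 5)
  mkprof <- function(peak_cM, peak_lod, env) {
    p <- data.frame(marker = mk, chrom = "chr1", pos_cM = mkpos,
                    lod = pmax(0, peak_lod - abs(mkpos - peak_cM) / 2),
                    n = 100, flag = "", stringsAsFactors = FALSE)
    class(p) <- c("lod_profile", "data.frame")
    p
  }
  thr <- c(env1 = 3, env2 = 3, env3 = 3)
  # same QTL significant in 2 of 3 environments -> one robust QTL
  scans <- list(env1 = mkprof(50, 8), env2 = mkprof(55, 6),
                env3 = mkprof(50, 1))
  q <- find_robust_qtls(scans, thr, colocalization_cM = 10, trait = "T")
  expect_equal(nrow(q), 1L)
  expect_equal(q$n_envs, 2L)
  expect_identical(q$name, "T1.1")
  expect_equal(q$peak_cM, 50)
  # significant in one environment only -> excluded but kept in all_peaks
  scans1 <- list(env1 = mkprof(50, 8), env2 = mkprof(50, 1),
                 env3 = mkprof(50, 1))
  q1 <- find_robust_qtls(scans1, thr, 10, "T")
  expect_equal(nrow(q1), 0L)
  expect_equal(nrow(attr(q1, "all_peaks")), 1L)
  # two QTLs 40 cM apart stay distinct at a 10 cM window
  two <- function(env) {
    p <- mkprof(30, 7, env)
    p$lod <- p$lod + pmax(0, 7 - abs(mkpos - 70) / 2)
    p
  }
  scans2 <- list(env1 = two("env1"), env2 = two("env2"))
  q2 <- find_robust_qtls(scans2, c(env1 = 3, env2 = 3), 10, "T")
  expect_equal(nrow(q2), 2L)
  expect_identical(q2$name, c("T1.1", "T1.2"))
})

test_that("epistasis test: degenerate, null and powered cases", {
  # identical phenotype in all cells -> F = 0
  g1 <- rep(c(0, 2), each = 20)
  g2 <- rep(c(0, 2), times = 20)
  ep0 <- test_epistasis(g1, g2, rep(5, 40))
  expect_true(is.na(ep0$F_interaction) || ep0$F_interaction < 1e-10)
  # purely additive simulation: interaction p roughly uniform
  set.seed(91)
  ps <- replicate(60, {
    a <- sample(c(0, 2), 120, TRUE); b <- sample(c(0, 2), 120, TRUE)
    y <- a + b + rnorm(120)
    test_epistasis(a, b, y)$p_interaction
  })
  expect_lt(mean(ps < 0.05), 0.15)  # near the nominal false-positive rate
  expect_gt(mean(ps > 0.5), 0.3)
  # planted interaction >= residual SD is detected most of the time
  set.seed(92)
  hits <- mean(replicate(40, {
    a <- sample(c(0, 2), 200, TRUE); b <- sample(c(0, 2), 200, TRUE)
    y <- 1 * (a - 1) * (b - 1) + rnorm(200)
    test_epistasis(a, b, y)$p_interaction < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("joint QTL model recovers limits and rejects empty input", {
  set.seed(97)
  g <- cbind(q1 = sample(c(0L, 2L), 400, TRUE),
             q2 = sample(c(0L, 2L), 400, TRUE))
  # single QTL, no noise -> ~100% variance
  y1 <- 2 * (g[, 1] - 1)
  expect_equal(suppressWarnings(
    fit_qtl_model(g[, 1, drop = FALSE], y1)$pct_var), 100,
    tolerance = 1e-9)
  # two orthogonal QTLs of ~15% each -> joint ~30%
  v <- 0.15
  a <- sqrt(v / (1 - 2 * v))
  y2 <- a * (g[, 1] - 1) + a * (g[, 2] - 1) + rnorm(400)
  fit <- fit_qtl_model(g, y2)
  expect_lt(abs(fit$pct_var - 30), 8)
  expect_error(fit_qtl_model(g[, 0], y2), "no QTL")
  # collinear marker is dropped with a warning
  expect_warning(f3 <- fit_qtl_model(cbind(g, q3 = g[, 1]), y2),
                 "collinear")
  expect_identical(f3$dropped, "q3")
})

test_that("gene action statistics reproduce their definitions", {
  ga <- gene_action(10, 20, 15)
  expect_equal(ga$a, 5)
  expect_equal(ga$d, 0)
  expect_equal(ga$d_over_a, 0)
  ga0 <- gene_action(7, 7, 9)
  expect_true(ga0$undefined_ratio)
  expect_true(is.na(ga0$d_over_a))
  # asymmetric case: d/a independent of parent order
  expect_equal(gene_action(4, 10, 5)$d_over_a,
               gene_action(10, 4, 5)$d_over_a)
})

test_that("heritability estimator hits its limits and errors", {
  lines <- rep(sprintf("L%02d", 1:40), each = 3)
  base <- rep(rnorm(40), each = 3)
  mk <- function(v) data.frame(line = lines, trait = "T",
                               environment = "e", replicate = rep(1:3, 40),
                               value = v)
  expect_equal(estimate_heritability(mk(base)), 1)
  set.seed(5)
  h0 <- estimate_heritability(mk(rnorm(120)))
  expect_lt(h0, 0.3)
  one_rep <- data.frame(line = sprintf("L%02d", 1:40), trait = "T",
                        environment = "e", replicate = 1,
                        value = rnorm(40))
  expect_error(estimate_heritability(one_rep), "replicates")
})

test_that("planted QTLs are recovered with peaks near the truth", {
  # moderate-size spot check; the acceptance suite runs the full version
  found <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_lines = 200, chr_lengths_cM = rep(100, 3),
                      marker_spacing_cM = 2,
                      traits = list(sim_trait("T", h2 = 0.6, qtls = list(
                        qtl_spec(1, 40, pvar = 0.15),
                        qtl_spec(2, 60, pvar = 0.15)))), seed = 100 + s)
    pop <- simulate_ril_population(cfg)
    ph <- simulate_phenotypes(pop$genotypes, pop$map, cfg)
    y <- line_means(ph, "T", "env1", rownames(pop$genotypes))
    sc <- marker_scan(pop$genotypes, pop$map, y)
    th <- permutation_threshold(pop$genotypes, pop$map, y, n_perm = 300,
                                seed = s)
    pks <- qtlprior:::find_peaks(sc, th, 10)
    ok <- all(vapply(1:2, function(k) {
      tq <- pop$truth$qtls[k, ]
      any(pks$chrom == tq$chrom & abs(pks$pos_cM - tq$pos_cM) <= 10)
    }, TRUE))
    if (ok) found <- found + 1L
  }
  expect_gte(found, 4L)
})
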