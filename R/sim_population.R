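# Forward simulation of biparental selfing (RIL) populations.  Meiosis is
# modelled as a crossover Poisson process along each chromosome with no
# interference, i.e. the Haldane map function: two points d cM apart
# recombine in a gamete with probability r = (1 - exp(-2d/100))/2.

#' Haldane map function
#'
#' Recombination fraction between two points separated by `d_cM`
#' centimorgans under a no-interference crossover process.
#'
#' @param d_cM Genetic distance in cM (non-negative).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulation configuration for a biparental selfing population
#'
#' The defaults emulate a melon-style F7 RIL study: 164 lines from a
#' biparental cross, 12 chromosomes, two trial environments with replicated
#' plots, and traits controlled by a few QTLs plus a polygenic background.
#'
#' @param n_lines Number of inbred lines (default 164).
#' @param n_generations Filial generation; F7 means six selfing rounds
#'   after the F1 (default 7, must be >= 2).
#' @param chr_lengths_cM Numeric vector of chromosome lengths in cM.
#' @param marker_spacing_cM Marker grid spacing in cM.
#' @param bp_per_cM Physical bp per cM for the colinear synthetic physical
#'   axis (default 250000).
#' @param n_environments Number of environments (default 2).
#' @param n_replicates Replicated plot observations per line per
#'   environment (default 5, emulating five plants per plot).
#' @param env_effect_sd SD of the fixed per-environment shift.
#' @param gxe_sd SD of line-by-environment interaction noise.
#' @param missing_rate Fraction of genotype calls masked to `NA` in emitted
#'   datasets (default 0).
#' @param traits List of trait specifications from [sim_trait()].
#' @param seed Mandatory integer seed; every stochastic call derives from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_lines = 164, n_generations = 7,
                       chr_lengths_cM = rep(120, 12),
                       marker_spacing_cM = 2, bp_per_cM = 250000,
                       n_environments = 2, n_replicates = 5,
                       env_effect_sd = 0.5, gxe_sd = 0.2,
                       missing_rate = 0, traits = list(), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_generations < 2) stop("n_generations must be >= 2")
  if (any(chr_lengths_cM <= 0)) stop("zero-length chromosome")
  cfg <- list(n_lines = n_lines, n_generations = n_generations,
              chr_lengths_cM = chr_lengths_cM,
              marker_spacing_cM = marker_spacing_cM, bp_per_cM = bp_per_cM,
              n_environments = n_environments, n_replicates = n_replicates,
              env_effect_sd = env_effect_sd, gxe_sd = gxe_sd,
              missing_rate = missing_rate, traits = traits,
              seed = as.integer(seed))
  for (tr in traits) {
    for (q in tr$qtls) {
      if (q$chrom > length(chr_lengths_cM) ||
          q$pos_cM > chr_lengths_cM[q$chrom] || q$pos_cM < 0)
        stop("QTL position outside declared chromosome lengths (trait ",
             tr$name, ")")
    }
    pv <- vapply(tr$qtls, function(q) q$pvar %||% NA_real_, 1)
    if (!anyNA(pv) && sum(pv) > 1)
      stop("trait ", tr$name,
           ": QTL %variance targets jointly exceed 100%")
    if (tr$h2 <= 0 || tr$h2 > 1) stop("h2_target must be in (0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Trait specification for the phenotype simulator
#'
#' @param name Trait name.
#' @param mean Grand mean on the analysis (possibly log) scale.
#' @param h2 Broad-sense heritability target per environment, in (0, 1].
#' @param qtls List of [qtl_spec()] entries.
#' @param epistasis List of `list(i =, j =, effect =)` entries indexing
#'   into `qtls`; the term is `effect * (dos_i - 1) * (dos_j - 1)`.
#' @param log_scale If `TRUE` the emitted phenotype is `10^value`, so
#'   analysis must log-transform (as for ethylene-type traits).
#' @return A trait spec list.
#' @export
sim_trait <- function(name, mean = 0, h2 = 0.6, qtls = list(),
                      epistasis = list(), log_scale = FALSE) {
  list(name = name, mean = mean, h2 = h2, qtls = qtls,
       epistasis = epistasis, log_scale = log_scale)
}

#' QTL specification
#'
#' Either `pvar` (fraction of the trait's genetic variance explained,
#' converted internally to an additive effect on a unit-genetic-variance
#' scale) or a raw additive effect `a` must be given.
#'
#' @param chrom Chromosome index.
#' @param pos_cM Genetic position.
#' @param pvar Fraction of genetic variance in `[0, 1]`.
#' @param a Additive effect (half the homozygote difference); derived from
#'   `pvar` when `NULL`.  Sign follows the parent-B-increases convention.
#' @param d Dominance deviation of heterozygotes (default 0).
#' @return A QTL spec list.
#' @export
qtl_spec <- function(chrom, pos_cM, pvar = NULL, a = NULL, d = 0) {
  if (is.null(pvar) && is.null(a)) stop("give either pvar or a")
  list(chrom = chrom, pos_cM = pos_cM, pvar = pvar, a = a, d = d)
}

# one meiotic gamete for one chromosome; haplos is a 2 x m 0/1 matrix,
# pos_cM the marker positions, len_cM the chromosome length
sim_gamete_chr <- function(haplos, pos_cM, len_cM) {
  k <- stats::rpois(1L, len_cM / 100)
  cur <- sample.int(2L, 1L) - 1L
  if (k > 0L) {
    xo <- sort(stats::runif(k, 0, len_cM))
    idx <- (cur + findInterval(pos_cM, xo)) %% 2L
  } else {
    idx <- rep(cur, length(pos_cM))
  }
  ifelse(idx == 0L, haplos[1L, ], haplos[2L, ])
}

#' Build a regular synthetic genetic map
#'
#' Markers on a fixed cM grid per chromosome, with a colinear physical axis
#' (`pos_bp = pos_cM * bp_per_cM`).
#'
#' @param chr_lengths_cM Chromosome lengths.
#' @param spacing_cM Marker spacing.
#' @param bp_per_cM Physical scale.
#' @return A `genetic_map` data frame.
#' @export
make_genetic_map <- function(chr_lengths_cM, spacing_cM, bp_per_cM = 250000) {
  rows <- lapply(seq_along(chr_lengths_cM), function(ch) {
    pos <- seq(0, chr_lengths_cM[ch], by = spacing_cM)
    data.frame(
      marker = sprintf("S%02d_%d", ch, as.integer(round(pos * bp_per_cM)) + 1L),
      chrom = paste0("chr", ch), pos_cM = pos,
      pos_bp = round(pos * bp_per_cM) + 1, stringsAsFactors = FALSE)
  })
  validate_genetic_map(do.call(rbind, rows))
}

#' Simulate a recombinant inbred line population
#'
#' Starts from a uniformly heterozygous F1 and performs
#' `n_generations - 1` rounds of single-seed-descent selfing, with
#' per-chromosome meiosis under the Haldane (no interference) crossover
#' model.  Parent A contributes allele 0, parent B allele 1; line dosages
#' are the haplotype sums (0/1/2).
#'
#' @param config A [sim_config()] object.
#' @return List with `map` (genetic map), `genotypes` (lines x markers
#'   integer dosage matrix) and `truth` (per-trait QTL marker assignments
#'   and effects, for downstream planted-truth checks).
#' @export
simulate_ril_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- make_genetic_map(config$chr_lengths_cM, config$marker_spacing_cM,
                          config$bp_per_cM)
  chroms <- unique(map$chrom)
  pos_by_chr <- lapply(chroms, function(ch) map$pos_cM[map$chrom == ch])
  len_by_chr <- config$chr_lengths_cM
  n_self <- config$n_generations - 1L
  geno <- with_seed(config$seed, {
    g <- matrix(NA_integer_, config$n_lines, nrow(map),
                dimnames = list(sprintf("RIL%03d", seq_len(config$n_lines)),
                                map$marker))
    for (l in seq_len(config$n_lines)) {
      # F1: haplotype 1 all parent-A, haplotype 2 all parent-B
      ind <- lapply(seq_along(chroms), function(ci)
        rbind(rep(0L, length(pos_by_chr[[ci]])),
              rep(1L, length(pos_by_chr[[ci]]))))
      for (g_i in seq_len(n_self)) {
        ind <- lapply(seq_along(chroms), function(ci)
          rbind(sim_gamete_chr(ind[[ci]], pos_by_chr[[ci]], len_by_chr[ci]),
                sim_gamete_chr(ind[[ci]], pos_by_chr[[ci]], len_by_chr[ci])))
      }
      g[l, ] <- unlist(lapply(ind, colSums))
    }
    g
  })
  truth <- planted_qtl_truth(map, config)
  list(map = map, genotypes = geno, truth = truth)
}

# resolve each configured QTL to its nearest simulated marker
planted_qtl_truth <- function(map, config) {
  qtl_rows <- list()
  for (tr in config$traits) {
    for (k in seq_along(tr$qtls)) {
      q <- tr$qtls[[k]]
      chname <- paste0("chr", q$chrom)
      sub <- map[map$chrom == chname, ]
      near <- sub[which.min(abs(sub$pos_cM - q$pos_cM)), ]
      a <- q$a %||% sqrt(q$pvar)
      qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
        trait = tr$name, chrom = chname, pos_cM = q$pos_cM,
        marker = near$marker, marker_cM = near$pos_cM,
        a = a, d = q$d, pvar = q$pvar %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  qtls <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    data.frame(trait = character(0), chrom = character(0),
               pos_cM = numeric(0), marker = character(0),
               marker_cM = numeric(0), a = numeric(0), d = numeric(0),
               pvar = numeric(0))
  list(qtls = qtls,
       h2 = stats::setNames(vapply(config$traits, `[[`, 1, "h2"),
                            vapply(config$traits, `[[`, "", "name")))
}

#' Simulate replicated phenotypes for a RIL population
#'
#' Per trait, the genetic value of a line is
#' `sum(a_i * (dos_i - 1)) + sum(d_i * [dos_i == 1]) + epistatic terms +
#' polygenic effect`, scaled so the configured QTLs explain their target
#' fractions of a unit genetic variance.  Each plot value adds a fixed
#' environment shift, line-by-environment noise, and a residual whose
#' variance is solved per environment so the realized broad-sense
#' heritability matches the target.  Traits flagged `log_scale` are emitted
#' as `10^value` so analysis must log-transform.
#'
#' @param genotypes Dosage matrix from [simulate_ril_population()].
#' @param map Genetic map (marker positions used to anchor QTLs).
#' @param config A [sim_config()] object (its `seed` is offset internally
#'   so genotype and phenotype draws are independent streams).
#' @return A `phenotype_table` data frame.
#' @export
simulate_phenotypes <- function(genotypes, map, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$traits)) stop("config has no traits")
  lines <- rownames(genotypes)
  n <- length(lines)
  with_seed(config$seed + 1L, {
    out <- list()
    for (tr in config$traits) {
      truth <- planted_qtl_truth(map, config)$qtls
      tq <- truth[truth$trait == tr$name, , drop = FALSE]
      g <- rep(0, n)
      dos <- NULL
      if (nrow(tq)) {
        dos <- genotypes[, tq$marker, drop = FALSE]
        for (k in seq_len(nrow(tq)))
          g <- g + tq$a[k] * (dos[, k] - 1) + tq$d[k] * (dos[, k] == 1)
        for (ep in tr$epistasis)
          g <- g + ep$effect * (dos[, ep$i] - 1) * (dos[, ep$j] - 1)
      }
      pv <- sum(vapply(tr$qtls, function(q)
        q$pvar %||% (q$a^2), 1))
      poly_sd <- sqrt(max(0, 1 - pv))
      g <- g + stats::rnorm(n, 0, poly_sd)
      env_shift <- stats::rnorm(config$n_environments, 0, config$env_effect_sd)
      for (e in seq_len(config$n_environments)) {
        gxe <- stats::rnorm(n, 0, config$gxe_sd)
        line_val <- g + gxe
        v_line <- stats::var(line_val)
        sd_res <- sqrt(v_line * (1 - tr$h2) / tr$h2)
        for (r in seq_len(config$n_replicates)) {
          val <- tr$mean + env_shift[e] + line_val +
            stats::rnorm(n, 0, sd_res)
          if (tr$log_scale) val <- 10^val
          out[[length(out) + 1L]] <- data.frame(
            line = lines, trait = tr$name,
            environment = paste0("env", e),
            replicate = paste0("rep", r), value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
    validate_phenotypes(do.call(rbind, out))
  })
}

#' Simulate a half-diallel F1 panel
#'
#' All `n(n-1)/2` unordered founder pairs (no selfs, no reciprocals).
#' Founders are homozygous at each candidate SNP (dosage 0 or 2 with
#' probability 1/2); an F1's dosage is the parental mean, so heterozygote
#' trait expectation is the homozygote midpoint plus any dominance
#' deviation.
#'
#' @param n_founders Number of founders (>= 3).
#' @param candidate_snps Character vector of SNP ids.
#' @param effects Numeric additive effects per SNP (per-allele, applied to
#'   `dosage - 1`).
#' @param d Dominance deviations per SNP (default 0).
#' @param noise_sd Residual SD of the trait (default 1).
#' @param seed Integer seed.
#' @return List with `genotypes` (hybrids x SNPs dosage matrix, values in
#'   0/1/2), `phenotypes` (a `phenotype_table` with one trait
#'   `"trait"`/`env1`/`rep1`), and `founders` (founder dosage matrix).
#' @export
simulate_diallel_panel <- function(n_founders, candidate_snps, effects,
                                   d = 0, noise_sd = 1, seed) {
  if (n_founders < 3) stop("n_founders must be >= 3")
  stopifnot(length(effects) == length(candidate_snps))
  if (length(d) == 1L) d <- rep(d, length(candidate_snps))
  with_seed(seed, {
    founders <- matrix(
      2L * stats::rbinom(n_founders * length(candidate_snps), 1L, 0.5),
      n_founders, length(candidate_snps),
      dimnames = list(sprintf("P%02d", seq_len(n_founders)), candidate_snps))
    pairs <- utils::combn(n_founders, 2L)
    hyb <- (founders[pairs[1L, ], , drop = FALSE] +
              founders[pairs[2L, ], , drop = FALSE]) / 2L
    rownames(hyb) <- sprintf("F1_%02dx%02d", pairs[1L, ], pairs[2L, ])
    val <- as.vector(
      (hyb - 1) %*% effects + (hyb == 1) %*% d) +
      stats::rnorm(nrow(hyb), 0, noise_sd)
    ph <- validate_phenotypes(data.frame(
      line = rownames(hyb), trait = "trait", environment = "env1",
      replicate = "rep1", value = val, stringsAsFactors = FALSE))
    list(genotypes = hyb, phenotypes = ph, founders = founders)
  })
}
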