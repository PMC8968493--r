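# Gene-action statistics, epistasis tests, joint QTL models and
# ANOVA-based heritability.

#' Two-way epistasis test at peak markers
#'
#' Fixed-effects two-way ANOVA of the phenotype on the genotype classes of
#' two peak markers, returning the interaction p-value and the cell-mean
#' grid for interaction plots.  Empty genotype cells are dropped and
#' flagged.
#'
#' @param g_i,g_j Dosage vectors at the two loci (0/1/2, NA allowed).
#' @param phenotype Numeric phenotype vector.
#' @return List with `p_interaction`, `F_interaction`, `cell_means`
#'   (matrix, rows = locus i classes), `cell_n`, `dropped_cells`, `anova`.
#' @export
test_epistasis <- function(g_i, g_j, phenotype) {
  cc <- !is.na(g_i) & !is.na(g_j) & !is.na(phenotype)
  fi <- factor(g_i[cc]); fj <- factor(g_j[cc]); y <- phenotype[cc]
  tab <- table(fi, fj)
  dropped <- which(tab == 0, arr.ind = TRUE)
  dropped_cells <- if (nrow(dropped))
    paste0(rownames(tab)[dropped[, 1L]], "x",
           colnames(tab)[dropped[, 2L]]) else character(0)
  if (stats::var(y) < .Machine$double.eps) {
    # constant phenotype: no interaction signal by definition
    cm <- tapply(y, list(fi, fj), mean)
    return(list(p_interaction = 1, F_interaction = 0, cell_means = cm,
                cell_n = tab, dropped_cells = dropped_cells, anova = NULL))
  }
  fit <- stats::aov(y ~ fi * fj)
  an <- summary(fit)[[1L]]
  ia <- grep("fi:fj", rownames(an))
  p <- if (length(ia)) an[ia, "Pr(>F)"] else NA_real_
  Fv <- if (length(ia)) an[ia, "F value"] else NA_real_
  cm <- tapply(y, list(fi, fj), mean)
  list(p_interaction = unname(p), F_interaction = unname(Fv),
       cell_means = cm, cell_n = tab, dropped_cells = dropped_cells,
       anova = an)
}

#' Joint multi-QTL model at robust peak markers
#'
#' Least squares of the phenotype on all robust-QTL peak-marker dosages
#' jointly.  Collinear peak markers are dropped (later marker loses) and
#' reported.  Effects follow the parent-B-increases sign convention
#' (positive when the dosage-2 allele raises the trait).
#'
#' @param genotypes Lines x peak-markers dosage matrix (at least one
#'   column).
#' @param phenotype Numeric line-mean phenotype.
#' @return List with `pct_var` (model R-squared x 100), `effects` (named
#'   additive effects per retained marker) and `dropped` (collinear
#'   markers removed).
#' @export
fit_qtl_model <- function(genotypes, phenotype) {
  genotypes <- as.matrix(genotypes)
  if (!ncol(genotypes)) stop("no QTL peak markers supplied")
  cc <- stats::complete.cases(genotypes) & !is.na(phenotype)
  X <- genotypes[cc, , drop = FALSE] - 1
  fit <- stats::lm(phenotype[cc] ~ X)
  cf <- stats::coef(fit)[-1L]
  names(cf) <- colnames(genotypes)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning("collinear peak marker(s) dropped: ",
            paste(dropped, collapse = ", "))
  list(pct_var = summary(fit)$r.squared * 100,
       effects = cf[!is.na(cf)], dropped = dropped)
}

#' Gene-action statistics from parental and F1 means
#'
#' Additive component `a = |p1 - p2| / 2`, dominance deviation
#' `d = f1 - (p1 + p2)/2` (deviation of the F1 from the midparent), and
#' dominance ratio `d/a` (undefined when `a = 0`).
#'
#' @param p1_mean,p2_mean,f1_mean Parental and F1 trait means.
#' @return List with `a`, `d`, `d_over_a`, and `undefined_ratio` flag.
#' @export
gene_action <- function(p1_mean, p2_mean, f1_mean) {
  a <- abs(p1_mean - p2_mean) / 2
  d <- f1_mean - (p1_mean + p2_mean) / 2
  undef <- a == 0
  list(a = a, d = d,
       d_over_a = if (undef) NA_real_ else d / a,
       undefined_ratio = undef)
}

#' ANOVA-based heritability for one trait in one environment
#'
#' One-way ANOVA over lines with replicated observations:
#' `sigma2_G = (MS_line - MS_error) / r` (clipped at 0) and
#' `h2 = sigma2_G / (sigma2_G + MS_error)`, clipped to `[0, 1]`.  With
#' unbalanced replication `r` is the expected-mean-squares coefficient
#' `r0 = (N - sum(n_i^2)/N) / (n_lines - 1)`, which equals the replicate
#' count in the balanced case.
#'
#' @param phenotypes Phenotype table restricted (or restrictable) to one
#'   trait and environment.
#' @param trait,environment Selection when the table has several.
#' @return Numeric heritability in `[0, 1]`.
#' @export
estimate_heritability <- function(phenotypes, trait = NULL,
                                  environment = NULL) {
  df <- phenotypes
  if (!is.null(trait)) df <- df[df$trait == trait, , drop = FALSE]
  if (!is.null(environment))
    df <- df[df$environment == environment, , drop = FALSE]
  df <- df[!is.na(df$value), , drop = FALSE]
  n_i <- table(df$line)
  if (all(n_i < 2L)) stop("fewer than 2 replicates for every line")
  fit <- stats::aov(value ~ factor(line), data = df)
  an <- summary(fit)[[1L]]
  ms_line <- an[1L, "Mean Sq"]
  ms_err <- an[2L, "Mean Sq"]
  N <- sum(n_i)
  r0 <- (N - sum(n_i^2) / N) / (length(n_i) - 1L)
  sigma_g <- max(0, (ms_line - ms_err) / r0)
  min(1, max(0, sigma_g / (sigma_g + ms_err)))
}

#' Trait summary statistics
#'
#' Mean, SD, range and heritability for one trait in one environment, plus
#' gene-action statistics when parental/F1 means are supplied.
#'
#' @param phenotypes Phenotype table.
#' @param trait,environment Selection.
#' @param p1_mean,p2_mean,f1_mean Optional parental and F1 means.
#' @return One-row data frame: trait, environment, mean, sd, min, max, h2,
#'   a, d, d_over_a.
#' @export
summarize_trait <- function(phenotypes, trait, environment,
                            p1_mean = NA, p2_mean = NA, f1_mean = NA) {
  lm_ <- line_means(phenotypes, trait, environment)
  h2 <- tryCatch(estimate_heritability(phenotypes, trait, environment),
                 error = function(e) NA_real_)
  ga <- if (!is.na(p1_mean) && !is.na(p2_mean) && !is.na(f1_mean))
    gene_action(p1_mean, p2_mean, f1_mean)
  else list(a = NA_real_, d = NA_real_, d_over_a = NA_real_)
  data.frame(trait = trait, environment = environment,
             mean = mean(lm_, na.rm = TRUE), sd = stats::sd(lm_, na.rm = TRUE),
             min = min(lm_, na.rm = TRUE), max = max(lm_, na.rm = TRUE),
             h2 = h2, a = ga$a, d = ga$d, d_over_a = ga$d_over_a,
             stringsAsFactors = FALSE)
}
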