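# Expression and multi-allelic association evidence layers.

#' Differential expression between parents, per stage
#'
#' Per developmental stage, `log2FC = log2((mean1 + 1)/(mean2 + 1))` and a
#' two-sample t-test on `log2(FPKM + 1)`.  A stage is called
#' differentially expressed when `|log2FC| >= 1` and `p < 0.05`.  With
#' fewer than two replicates in either parent the p-value is undefined and
#' the stage is flagged.
#'
#' @param expression Expression table (long format) for one gene, with
#'   `genotype` distinguishing the parents.
#' @param parent1,parent2 Genotype labels (default `"P1"`, `"P2"`).
#' @return Data frame: `stage`, `mean1`, `mean2`, `log2fc`, `p`, `de_call`,
#'   `flag`.
#' @export
differential_expression_between_parents <- function(expression,
                                                    parent1 = "P1",
                                                    parent2 = "P2") {
  stages <- unique(expression$stage)
  rows <- lapply(stages, function(st) {
    x1 <- expression$fpkm[expression$stage == st &
                            expression$genotype == parent1]
    x2 <- expression$fpkm[expression$stage == st &
                            expression$genotype == parent2]
    m1 <- mean(x1); m2 <- mean(x2)
    lfc <- log2((m1 + 1) / (m2 + 1))
    if (length(x1) < 2L || length(x2) < 2L) {
      p <- NA_real_; flag <- "insufficient_replicates"
    } else if (stats::var(log2(x1 + 1)) + stats::var(log2(x2 + 1)) == 0) {
      p <- if (abs(lfc) > 0) 0 else 1; flag <- "zero_variance"
    } else {
      p <- stats::t.test(log2(x1 + 1), log2(x2 + 1))$p.value; flag <- ""
    }
    data.frame(stage = st, mean1 = m1, mean2 = m2, log2fc = lfc, p = p,
               de_call = !is.na(p) & abs(lfc) >= 1 & p < 0.05,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression-trait correlation across lines
#'
#' Pearson correlation of `log10(FPKM + 1)` against the (optionally
#' log-transformed) trait, with a two-sided test.
#'
#' @param expression_per_line Named numeric FPKM vector, one value per line.
#' @param trait_per_line Named numeric trait vector.
#' @param log_trait If `TRUE`, `log10(x + offset)` is applied to the trait.
#' @return List with `r`, `p`, `n`.
#' @export
expression_trait_correlation <- function(expression_per_line,
                                         trait_per_line,
                                         log_trait = FALSE) {
  if (!is.null(names(expression_per_line)) && !is.null(names(trait_per_line)))
    trait_per_line <- trait_per_line[names(expression_per_line)]
  cc <- !is.na(expression_per_line) & !is.na(trait_per_line)
  if (sum(cc) < 5L) stop("fewer than 5 paired observations")
  x <- log10(expression_per_line[cc] + 1)
  y <- trait_per_line[cc]
  if (log_trait) {
    offset <- if (min(y) > 0) 0 else -min(y) + 1
    y <- log10(y + offset)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(cc))
}

#' Single-SNP association across genotype classes
#'
#' One-way ANOVA of the trait on genotype classes (including
#' heterozygotes): `R2 = SS_model / SS_total`; all-pairs Tukey HSD
#' comparisons produce a compact letter display (groups with fewer than
#' two observations are excluded from the letters); the additivity flag is
#' set when the heterozygote mean lies strictly between the homozygote
#' means and within the inner half of their span.
#'
#' @param genotypes Dosage (0/1/2) or class labels (`AA`/`AB`/`BB`).
#' @param trait Numeric trait values.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `association_result`: `group_means`, `group_n`,
#'   `F`, `p`, `R2`, `letters`, `additive`.
#' @export
candidate_snp_association <- function(genotypes, trait, alpha = 0.05) {
  cls <- as.character(genotypes)
  cls[cls %in% "0"] <- "AA"; cls[cls %in% "1"] <- "AB"
  cls[cls %in% "2"] <- "BB"
  cc <- !is.na(cls) & !is.na(trait)
  f <- factor(cls[cc], levels = intersect(c("AA", "AB", "BB"),
                                          unique(cls[cc])))
  y <- trait[cc]
  if (nlevels(f) < 2L) stop("monomorphic SNP: only one genotype class present")
  fit <- stats::aov(y ~ f)
  an <- summary(fit)[[1L]]
  ss_model <- an[1L, "Sum Sq"]
  r2 <- ss_model / (ss_model + an[2L, "Sum Sq"])
  grp_n <- table(f)
  big <- names(grp_n)[grp_n >= 2L]
  letters_out <- stats::setNames(rep(NA_character_, nlevels(f)), levels(f))
  if (length(big) >= 2L) {
    tk <- stats::TukeyHSD(fit)$f
    pmat <- matrix(NA_real_, length(big), length(big),
                   dimnames = list(big, big))
    for (rn in rownames(tk)) {
      pr <- strsplit(rn, "-", fixed = TRUE)[[1L]]
      if (all(pr %in% big)) {
        pmat[pr[1L], pr[2L]] <- tk[rn, "p adj"]
        pmat[pr[2L], pr[1L]] <- tk[rn, "p adj"]
      }
    }
    letters_out[big] <- letter_groups(pmat, alpha)
  } else if (length(big) == 1L) {
    letters_out[big] <- "a"
  }
  gm <- tapply(y, f, mean)
  additive <- FALSE
  if (all(c("AA", "AB", "BB") %in% names(gm)) && !anyNA(gm)) {
    lo <- min(gm["AA"], gm["BB"]); hi <- max(gm["AA"], gm["BB"])
    mid <- (lo + hi) / 2; span <- hi - lo
    additive <- gm["AB"] > lo && gm["AB"] < hi &&
      abs(gm["AB"] - mid) <= span / 4
  }
  structure(list(group_means = gm, group_n = grp_n,
                 F = an[1L, "F value"], p = an[1L, "Pr(>F)"],
                 R2 = unname(r2), letters = letters_out,
                 additive = unname(additive)),
            class = "association_result")
}

#' Two-locus association with interaction
#'
#' Two-way ANOVA with interaction on genotype-class factors: joint model
#' R-squared, interaction p-value and the cell-mean grid.  Supplying the
#' same SNP twice (aliased factors) is an error; empty cells are dropped
#' with a flag.
#'
#' @param g1,g2 Genotypes at the two SNPs (dosage or class labels).
#' @param trait Numeric trait values.
#' @return List: `R2_joint`, `p_interaction`, `cell_means`, `cell_n`,
#'   `dropped_cells`.
#' @export
two_locus_association <- function(g1, g2, trait) {
  cc <- !is.na(g1) & !is.na(g2) & !is.na(trait)
  f1 <- factor(g1[cc]); f2 <- factor(g2[cc]); y <- trait[cc]
  if (identical(as.integer(f1), as.integer(f2)))
    stop("the two SNPs are identical: second factor is aliased")
  tab <- table(f1, f2)
  dr <- which(tab == 0, arr.ind = TRUE)
  dropped <- if (nrow(dr)) paste0(rownames(tab)[dr[, 1L]], "x",
                                  colnames(tab)[dr[, 2L]]) else character(0)
  if (stats::var(y) < .Machine$double.eps) {
    return(list(R2_joint = 0, p_interaction = 1,
                cell_means = tapply(y, list(f1, f2), mean), cell_n = tab,
                dropped_cells = dropped))
  }
  fit <- stats::aov(y ~ f1 * f2)
  an <- summary(fit)[[1L]]
  res_row <- grep("Residuals", rownames(an))
  ss_tot <- sum(an[, "Sum Sq"])
  r2 <- if (ss_tot <= 0) 0 else (ss_tot - an[res_row, "Sum Sq"]) / ss_tot
  ia <- grep("f1:f2", rownames(an))
  list(R2_joint = unname(r2),
       p_interaction = if (length(ia)) unname(an[ia, "Pr(>F)"]) else NA_real_,
       cell_means = tapply(y, list(f1, f2), mean), cell_n = tab,
       dropped_cells = dropped)
}
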