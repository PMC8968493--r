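# Single-marker and composite LOD scans and genome-wide permutation
# thresholds.  The scan statistic is the RSS-ratio LOD of a
# single-predictor dosage regression, LOD = (n/2) log10(RSS0/RSS1),
# equivalently -(n/2) log10(1 - r^2).  The vectorized core handles missing
# dosages with exact pairwise-complete sums.

# LOD matrix for dosage matrix G (n x m) against phenotype columns Y
# (n x p).  Rows of Y with NA must be removed by the caller.  Monomorphic
# markers get LOD 0; markers with fewer than min_n informative lines get NA.
lod_core <- function(G, Y, min_n = 20L) {
  Y <- as.matrix(Y)
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  Mn <- matrix(as.numeric(M), nrow(G))
  n_j <- colSums(Mn)
  Sg <- colSums(G0)
  Sgg <- colSums(G0^2)
  S1 <- crossprod(Mn, Y)            # m x p
  S2 <- crossprod(Mn, Y^2)
  Sxy <- crossprod(G0, Y)
  num <- Sxy - (Sg / n_j) * S1
  vg <- Sgg - Sg^2 / n_j
  vy <- S2 - S1^2 / n_j
  r2 <- num^2 / (pmax(vg, .Machine$double.eps) * pmax(vy, .Machine$double.eps))
  r2 <- pmin(r2, 1 - 1e-15)
  lod <- -(n_j / 2) * log10(1 - r2)
  mono <- vg <= 1e-9
  lod[mono, ] <- 0
  lod[n_j < min_n, ] <- NA_real_
  attr(lod, "monomorphic") <- mono
  attr(lod, "n") <- n_j
  lod
}

#' Genome scan by single-marker dosage regression
#'
#' Per marker, least squares of the line-mean phenotype on dosage over
#' pairwise-complete observations; `LOD = -(n/2) log10(1 - r^2)`.
#' Monomorphic markers get LOD 0 and are flagged; markers with fewer than
#' `min_n` informative lines are omitted (NA) with a warning.
#'
#' @param genotypes Lines x markers dosage matrix (0/1/2, NA allowed).
#' @param map Genetic map covering the markers.
#' @param phenotype Named numeric vector of line means (names matched to
#'   genotype rownames when present).
#' @param log_transform If `TRUE`, `log10(x + offset)` is applied first;
#'   `offset` 0 when all values are positive, otherwise `-min(x) + 1`.
#' @param min_n Minimum informative lines per marker (default 20).
#' @param trait,environment Labels stored on the profile.
#' @return A `lod_profile` data frame: `marker`, `chrom`, `pos_cM`, `lod`,
#'   `n`, `flag`.
#' @export
marker_scan <- function(genotypes, map, phenotype, log_transform = FALSE,
                        min_n = 20L, trait = NA_character_,
                        environment = NA_character_) {
  y <- phenotype
  if (!is.null(names(y)) && !is.null(rownames(genotypes)))
    y <- y[rownames(genotypes)]
  if (log_transform) {
    offset <- if (min(y, na.rm = TRUE) > 0) 0 else -min(y, na.rm = TRUE) + 1
    y <- log10(y + offset)
  }
  ok <- !is.na(y)
  G <- genotypes[ok, , drop = FALSE]
  mk <- intersect(colnames(G), map$marker)
  if (!length(mk)) stop("no genotype markers found in the map")
  G <- G[, mk, drop = FALSE]
  lod <- lod_core(G, y[ok], min_n = min_n)
  if (anyNA(lod))
    warning(sum(is.na(lod[, 1L])),
            " marker(s) with fewer than ", min_n,
            " informative lines omitted")
  idx <- match(mk, map$marker)
  prof <- data.frame(marker = mk, chrom = map$chrom[idx],
                     pos_cM = map$pos_cM[idx], lod = lod[, 1L],
                     n = attr(lod, "n"),
                     flag = ifelse(attr(lod, "monomorphic"), "monomorphic",
                                   ""),
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$chrom, prof$pos_cM), ]
  rownames(prof) <- NULL
  attr(prof, "trait") <- trait
  attr(prof, "environment") <- environment
  class(prof) <- c("lod_profile", "data.frame")
  prof
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes phenotype labels `n_perm` times, records the genome-wide
#' maximum LOD per permutation, and returns the empirical `1 - alpha`
#' quantile (type-7 linear interpolation).
#'
#' @inheritParams marker_scan
#' @param n_perm Number of permutations (default 1000; below 100 warns).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed (mandatory for replayability).
#' @return Numeric threshold with attribute `max_lods` (the permuted
#'   maxima).
#' @export
permutation_threshold <- function(genotypes, map, phenotype,
                                  n_perm = 1000L, alpha = 0.05, seed,
                                  log_transform = FALSE, min_n = 20L) {
  if (n_perm < 100L) warning("n_perm < 100: threshold tail is unstable")
  y <- phenotype
  if (!is.null(names(y)) && !is.null(rownames(genotypes)))
    y <- y[rownames(genotypes)]
  if (log_transform) {
    offset <- if (min(y, na.rm = TRUE) > 0) 0 else -min(y, na.rm = TRUE) + 1
    y <- log10(y + offset)
  }
  ok <- !is.na(y)
  G <- genotypes[ok, , drop = FALSE]
  G <- G[, intersect(colnames(G), map$marker), drop = FALSE]
  y <- y[ok]
  n <- length(y)
  with_seed(seed, {
    Yp <- vapply(seq_len(n_perm), function(k) y[sample.int(n)],
                 numeric(n))
    lod <- lod_core(G, Yp, min_n = min_n)
    maxima <- apply(lod, 2L, max, na.rm = TRUE)
    thr <- unname(stats::quantile(maxima, 1 - alpha, type = 7))
    attr(thr, "max_lods") <- maxima
    thr
  })
}

#' Composite scan with cofactor markers
#'
#' At each test position the model includes the cofactor markers, excluding
#' any cofactor within `window_cM` of the test position (on the same
#' chromosome) and any cofactor identical to the test marker column.  LOD
#' is `(n/2) log10(RSS0/RSS1)` comparing models with and without the test
#' marker, given the retained cofactors.
#'
#' @inheritParams marker_scan
#' @param cofactors Character vector of cofactor marker names.
#' @param window_cM Exclusion window around the test position (default 10).
#' @return A `lod_profile` data frame.
#' @export
composite_scan <- function(genotypes, map, phenotype, cofactors = character(0),
                           window_cM = 10, log_transform = FALSE,
                           min_n = 20L, trait = NA_character_,
                           environment = NA_character_) {
  if (!length(cofactors))
    return(marker_scan(genotypes, map, phenotype, log_transform, min_n,
                       trait, environment))
  y <- phenotype
  if (!is.null(names(y)) && !is.null(rownames(genotypes)))
    y <- y[rownames(genotypes)]
  if (log_transform) {
    offset <- if (min(y, na.rm = TRUE) > 0) 0 else -min(y, na.rm = TRUE) + 1
    y <- log10(y + offset)
  }
  mk <- intersect(colnames(genotypes), map$marker)
  idx <- match(mk, map$marker)
  chrom <- map$chrom[idx]; pos <- map$pos_cM[idx]
  cof_idx <- match(cofactors, mk)
  if (anyNA(cof_idx)) stop("cofactor marker(s) not in genotypes/map")
  out <- data.frame(marker = mk, chrom = chrom, pos_cM = pos,
                    lod = NA_real_, n = NA_integer_, flag = "",
                    stringsAsFactors = FALSE)
  for (j in seq_along(mk)) {
    keep <- cof_idx[!(chrom[cof_idx] == chrom[j] &
                        abs(pos[cof_idx] - pos[j]) <= window_cM)]
    # drop cofactors with a column identical to the test marker
    keep <- keep[vapply(keep, function(k)
      !identical(genotypes[, mk[k]], genotypes[, mk[j]]), TRUE)]
    dat <- cbind(genotypes[, mk[j]], genotypes[, mk[keep], drop = FALSE])
    cc <- stats::complete.cases(dat) & !is.na(y)
    n <- sum(cc)
    out$n[j] <- n
    if (n < min_n) { out$flag[j] <- "low_n"; next }
    X0 <- cbind(1, dat[cc, -1L, drop = FALSE])
    X1 <- cbind(X0, dat[cc, 1L])
    rss0 <- sum(stats::lm.fit(X0, y[cc])$residuals^2)
    rss1 <- sum(stats::lm.fit(X1, y[cc])$residuals^2)
    if (stats::var(dat[cc, 1L]) <= 1e-12) {
      out$lod[j] <- 0; out$flag[j] <- "monomorphic"
    } else {
      out$lod[j] <- (n / 2) * log10(max(rss0, 1e-300) / max(rss1, 1e-300))
    }
  }
  out <- out[order(out$chrom, out$pos_cM), ]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "environment") <- environment
  class(out) <- c("lod_profile", "data.frame")
  out
}
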