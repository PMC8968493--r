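# LOD-drop support intervals and robust-QTL consolidation across
# environments.

#' LOD-drop support interval around a peak
#'
#' Walks outward from the peak to the first positions where LOD falls to
#' `peak_LOD - drop` or below.  The interval endpoints are the last
#' positions still above the drop line, extended to the flanking marker
#' beyond, and truncated at chromosome ends.
#'
#' @param profile A `lod_profile` data frame.
#' @param peak_marker Marker name of the peak (must be on the profile).
#' @param drop LOD drop, conventionally 1.5 or 2.0.
#' @return Numeric `c(lo_cM, hi_cM)`.
#' @export
lod_drop_interval <- function(profile, peak_marker, drop = 1.5) {
  i_all <- match(peak_marker, profile$marker)
  if (is.na(i_all)) stop("peak marker '", peak_marker, "' not on profile")
  ch <- profile$chrom[i_all]
  sub <- profile[profile$chrom == ch, , drop = FALSE]
  sub <- sub[order(sub$pos_cM), ]
  i <- match(peak_marker, sub$marker)
  thr <- sub$lod[i] - drop
  above <- !is.na(sub$lod) & sub$lod > thr
  lo_i <- i
  while (lo_i > 1L && above[lo_i - 1L]) lo_i <- lo_i - 1L
  hi_i <- i
  while (hi_i < nrow(sub) && above[hi_i + 1L]) hi_i <- hi_i + 1L
  lo <- if (lo_i > 1L) sub$pos_cM[lo_i - 1L] else sub$pos_cM[1L]
  hi <- if (hi_i < nrow(sub)) sub$pos_cM[hi_i + 1L] else sub$pos_cM[nrow(sub)]
  c(lo_cM = lo, hi_cM = hi)
}

# significant-run peak finding within one profile: cluster significant
# markers into runs separated by more than gap_cM, peak = max LOD per run
find_peaks <- function(profile, threshold, gap_cM = 10) {
  sig <- profile[!is.na(profile$lod) & profile$lod > threshold, ,
                 drop = FALSE]
  if (!nrow(sig)) return(sig[0, ])
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos_cM), ]
    run <- cumsum(c(0, diff(s$pos_cM) > gap_cM))
    for (r in unique(run)) {
      blk <- s[run == r, , drop = FALSE]
      best <- blk[which.max(blk$lod), , drop = FALSE]
      # leftmost position wins ties
      best <- blk[blk$lod == max(blk$lod), , drop = FALSE][1L, , drop = FALSE]
      out[[length(out) + 1L]] <- best
    }
  }
  do.call(rbind, out)
}

#' Consolidate robust QTLs across environments
#'
#' Peaks above their environment's threshold are clustered across
#' environments when within `colocalization_cM` on the same chromosome;
#' clusters backed by at least two environments become robust QTLs.  The
#' reported peak is the highest-LOD member; 1.5- and 2-LOD support
#' intervals are computed on that member's profile.  Names are composed as
#' trait + chromosome number + QTL index along the chromosome.
#'
#' @param scans Named list of `lod_profile`s, one per environment.
#' @param thresholds Named numeric vector of per-environment thresholds.
#' @param colocalization_cM Clustering window (default 10).
#' @param trait Trait name used for QTL naming.
#' @param genotypes Optional dosage matrix to compute the additive effect
#'   and percent variance at the peak marker.
#' @param phenotypes Optional named list (by environment) of line-mean
#'   vectors matching `genotypes` rows.
#' @return Data frame of class `qtl_intervals` with one row per robust
#'   QTL, and attribute `all_peaks` (every significant peak, including
#'   single-environment ones).
#' @export
find_robust_qtls <- function(scans, thresholds, colocalization_cM = 10,
                             trait = "trait", genotypes = NULL,
                             phenotypes = NULL) {
  peaks <- list()
  for (env in names(scans)) {
    p <- find_peaks(scans[[env]], thresholds[[env]], colocalization_cM)
    if (nrow(p)) {
      p$environment <- env
      peaks[[env]] <- p
    }
  }
  all_peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(marker = character(0), chrom = character(0),
               pos_cM = numeric(0), lod = numeric(0),
               environment = character(0))
  rownames(all_peaks) <- NULL
  empty <- data.frame(name = character(0), trait = character(0),
                      chrom = character(0), peak_marker = character(0),
                      peak_cM = numeric(0), peak_lod = numeric(0),
                      n_envs = integer(0), env_best = character(0),
                      lo_1p5 = numeric(0), hi_1p5 = numeric(0),
                      lo_2p0 = numeric(0), hi_2p0 = numeric(0),
                      additive_effect = numeric(0), pct_var = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(all_peaks)) {
    attr(empty, "all_peaks") <- all_peaks
    class(empty) <- c("qtl_intervals", "data.frame")
    return(empty)
  }
  # greedy clustering by descending LOD
  remaining <- all_peaks[order(-all_peaks$lod), , drop = FALSE]
  clusters <- list()
  while (nrow(remaining)) {
    seedp <- remaining[1L, ]
    memb <- remaining$chrom == seedp$chrom &
      abs(remaining$pos_cM - seedp$pos_cM) <= colocalization_cM
    clusters[[length(clusters) + 1L]] <- remaining[memb, , drop = FALSE]
    remaining <- remaining[!memb, , drop = FALSE]
  }
  rows <- list()
  for (cl in clusters) {
    if (length(unique(cl$environment)) < 2L) next
    best <- cl[which.max(cl$lod), ]
    prof <- scans[[best$environment]]
    s15 <- lod_drop_interval(prof, best$marker, 1.5)
    s20 <- lod_drop_interval(prof, best$marker, 2.0)
    eff <- pv <- NA_real_
    if (!is.null(genotypes) && !is.null(phenotypes)) {
      y <- phenotypes[[best$environment]]
      d <- genotypes[, best$marker]
      cc <- !is.na(y) & !is.na(d)
      fit <- stats::lm(y[cc] ~ I(d[cc] - 1))
      eff <- unname(stats::coef(fit)[2L])
      pv <- summary(fit)$r.squared * 100
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = NA_character_, trait = trait, chrom = best$chrom,
      peak_marker = best$marker, peak_cM = best$pos_cM,
      peak_lod = best$lod, n_envs = length(unique(cl$environment)),
      env_best = best$environment,
      lo_1p5 = s15[["lo_cM"]], hi_1p5 = s15[["hi_cM"]],
      lo_2p0 = s20[["lo_cM"]], hi_2p0 = s20[["hi_cM"]],
      additive_effect = eff, pct_var = pv, stringsAsFactors = FALSE)
  }
  qtls <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(qtls)) {
    qtls <- qtls[order(qtls$chrom, qtls$peak_cM), , drop = FALSE]
    rownames(qtls) <- NULL
    chrnum <- sub("^chr", "", qtls$chrom)
    idx <- stats::ave(seq_len(nrow(qtls)), qtls$chrom,
                      FUN = seq_along)
    qtls$name <- paste0(trait, chrnum, ".", idx)
  }
  attr(qtls, "all_peaks") <- all_peaks
  class(qtls) <- c("qtl_intervals", "data.frame")
  qtls
}
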