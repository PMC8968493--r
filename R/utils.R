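# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily fixed RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' stream afterwards, so seeded package functions never perturb user-level
#' random sequences.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Convert genetic positions to physical positions by linear interpolation
#'
#' Piecewise-linear interpolation between map markers carrying bp anchors.
#' Positions beyond the anchored range are extrapolated from the terminal
#' segment slope (clamped to the flanking anchor when only one exists).
#'
#' @param map A genetic map data frame (see [read_genetic_map()]).
#' @param chrom Chromosome name (exact match).
#' @param cm Numeric vector of genetic positions (cM).
#' @return Numeric vector of physical positions (bp).
#' @export
cm_to_bp <- function(map, chrom, cm) {
  m <- map[map$chrom == chrom & !is.na(map$pos_bp), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("chromosome '", chrom, "' has fewer than two bp-anchored markers")
  m <- m[order(m$pos_cM), ]
  stats::approx(m$pos_cM, m$pos_bp, xout = cm, rule = 2, ties = "ordered")$y
}

#' @rdname cm_to_bp
#' @param bp Numeric vector of physical positions (bp).
#' @export
bp_to_cm <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom & !is.na(map$pos_bp), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("chromosome '", chrom, "' has fewer than two bp-anchored markers")
  m <- m[order(m$pos_bp), ]
  stats::approx(m$pos_bp, m$pos_cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups not significantly different share at
#' least one letter.  The grouping is a pure function of the significance
#' matrix, so permuting input order only relabels the letters.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
letter_groups <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  if (k == 0L) return(character(0))
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      new_cols <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          new_cols <- c(new_cols, list(cl))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  # deterministic letter order: by smallest member index
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(cl) g %in% cl, TRUE))],
           collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

# stop() wrapper used by pipeline stages so failures name their stage
stage_stop <- function(stage, ...) {
  stop("[stage: ", stage, "] ", ..., call. = FALSE)
}
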