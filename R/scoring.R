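# Multi-layer candidate-gene scoring within QTL support intervals: five
# evidence layers (proximity, polymorphism impact, description relevance,
# expression, multi-allelic association) summed to a raw total and indexed
# to a 1-10 general score within each interval.

#' Scoring weights for the five evidence layers
#'
#' Defaults follow the convention: proximity by LOD drop from the peak
#' (`< 0.5 -> 2`, `0.5-1.0 -> 1`, `1.0-1.5 -> 0.5`, `> 1.5 -> 0`);
#' polymorphism impact (`MODIFIER 0.5`, `LOW 1.0`, `MODERATE 1.5`,
#' `HIGH 2.0`); relevance keyword match `1`; expression `+1` for a
#' trait-concordant profile peak and `+1` for parental differential
#' expression, capped at 2; association `2` for `p < 1e-4`, `1` for
#' `p < 0.01`, else 0.
#'
#' @param proximity Named tier weights.
#' @param impact Named impact weights.
#' @param relevance_match Relevance weight.
#' @param expression_concordant,expression_de,expression_cap Expression
#'   layer weights and cap.
#' @param assoc_strong_p,assoc_strong,assoc_moderate_p,assoc_moderate
#'   Association thresholds and weights.
#' @return A `scoring_weights` list.
#' @export
scoring_weights <- function(proximity = c(near = 2, mid = 1, far = 0.5,
                                          out = 0),
                            impact = c(MODIFIER = 0.5, LOW = 1,
                                       MODERATE = 1.5, HIGH = 2),
                            relevance_match = 1,
                            expression_concordant = 1, expression_de = 1,
                            expression_cap = 2,
                            assoc_strong_p = 1e-4, assoc_strong = 2,
                            assoc_moderate_p = 0.01, assoc_moderate = 1) {
  w <- list(proximity = proximity, impact = impact,
            relevance_match = relevance_match,
            expression_concordant = expression_concordant,
            expression_de = expression_de, expression_cap = expression_cap,
            assoc_strong_p = assoc_strong_p, assoc_strong = assoc_strong,
            assoc_moderate_p = assoc_moderate_p,
            assoc_moderate = assoc_moderate)
  stopifnot(all(unlist(w[c("proximity", "impact")]) >= 0))
  class(w) <- "scoring_weights"
  w
}

#' Trait specification for candidate scoring
#'
#' @param name Trait name.
#' @param keywords Non-empty character vector of relevance keywords.
#' @param relevant_stages Non-empty character vector of expression
#'   stages/tissues concordant with the trait.
#' @param log_scale Whether the trait is analyzed on the log scale.
#' @param direction Optional direction of interest (free text).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, keywords, relevant_stages, log_scale = FALSE,
                       direction = NA_character_) {
  stopifnot(length(keywords) > 0, length(relevant_stages) > 0)
  structure(list(name = name, keywords = keywords,
                 relevant_stages = relevant_stages, log_scale = log_scale,
                 direction = direction), class = "trait_spec")
}

#' Genes inside a 2-LOD support interval, with per-gene LOD drop
#'
#' The interval's cM bounds are converted to the physical axis by
#' piecewise-linear interpolation of the map's bp anchors; genes whose
#' physical midpoint falls inside are returned, each annotated with
#' `lod_drop = peak_LOD - LOD` interpolated at the gene midpoint.
#'
#' @param interval One row of a `qtl_intervals` data frame.
#' @param models `gene_models` object.
#' @param map Genetic map with bp anchors on the interval's chromosome.
#' @param profile The `lod_profile` the interval was derived from.
#' @return Data frame: `gene_id`, `midpoint_bp`, `midpoint_cM`, `lod_drop`.
#' @export
genes_in_interval <- function(interval, models, map, profile) {
  ch <- interval$chrom
  lo_bp <- cm_to_bp(map, ch, interval$lo_2p0)
  hi_bp <- cm_to_bp(map, ch, interval$hi_2p0)
  prof <- profile[profile$chrom == ch & !is.na(profile$lod), , drop = FALSE]
  prof <- prof[order(prof$pos_cM), ]
  rows <- list()
  for (m in models) {
    if (m$chrom != ch) next
    mid_bp <- (m$start0 + m$end0) / 2
    if (mid_bp < lo_bp || mid_bp > hi_bp) next
    mid_cM <- bp_to_cm(map, ch, mid_bp)
    lod_here <- stats::approx(prof$pos_cM, prof$lod, xout = mid_cM,
                              rule = 2, ties = "ordered")$y
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = m$gene_id, midpoint_bp = mid_bp, midpoint_cM = mid_cM,
      lod_drop = max(0, interval$peak_lod - lod_here),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), midpoint_bp = numeric(0),
                      midpoint_cM = numeric(0), lod_drop = numeric(0)))
  do.call(rbind, rows)
}

#' Proximity score from a gene's LOD drop below the QTL peak
#'
#' @param lod_drop Non-negative LOD drop at the gene midpoint.
#' @param weights [scoring_weights()].
#' @return Numeric score.
#' @export
proximity_score <- function(lod_drop, weights = scoring_weights()) {
  if (any(lod_drop < 0)) stop("negative LOD drop")
  w <- weights$proximity
  ifelse(lod_drop < 0.5, w[["near"]],
         ifelse(lod_drop <= 1.0, w[["mid"]],
                ifelse(lod_drop <= 1.5, w[["far"]], w[["out"]])))
}

#' Polymorphism score from a gene's maximum variant impact
#'
#' @param max_impact One of `"none"`, `"MODIFIER"`, `"LOW"`, `"MODERATE"`,
#'   `"HIGH"`.
#' @param weights [scoring_weights()].
#' @return Numeric score (0 for `"none"`).
#' @export
polymorphism_score <- function(max_impact, weights = scoring_weights()) {
  ifelse(max_impact == "none", 0, unname(weights$impact[max_impact]))
}

#' Relevance score from a gene description
#'
#' Case-insensitive keyword match against the description.  Descriptions
#' matching an unknown/uncharacterized pattern are flagged; flagged genes
#' are retained and scored 0 by default.
#'
#' @param description Gene description text (may be `NA`).
#' @param spec [trait_spec()].
#' @param weights [scoring_weights()].
#' @param unknown_patterns Regexes marking uninformative descriptions.
#' @return List with `score` and `excluded` flag.
#' @export
relevance_score <- function(description, spec,
                            weights = scoring_weights(),
                            unknown_patterns = c("unknown",
                                                 "uncharacterized",
                                                 "hypothetical")) {
  if (is.na(description %||% NA) || !nzchar(trimws(description %||% "")))
    return(list(score = 0, excluded = TRUE))
  d <- tolower(description)
  if (any(vapply(unknown_patterns, grepl, TRUE, x = d, fixed = TRUE)))
    return(list(score = 0, excluded = TRUE))
  hit <- any(vapply(tolower(spec$keywords), grepl, TRUE, x = d,
                    fixed = TRUE))
  list(score = if (hit) weights$relevance_match else 0, excluded = FALSE)
}

#' Expression score from profile concordance and parental DE
#'
#' `+1` when the profile's peak stage (argmax of mean FPKM) is in the
#' trait's relevant set; `+1` when a parental differential-expression call
#' is positive at any relevant stage; capped.
#'
#' @param expression Expression table rows for one gene (may be empty).
#' @param spec [trait_spec()].
#' @param weights [scoring_weights()].
#' @return List with `score` and `flag` (`"absent"` when the gene has no
#'   expression data).
#' @export
expression_score <- function(expression, spec,
                             weights = scoring_weights()) {
  if (is.null(expression) || !nrow(expression))
    return(list(score = 0, flag = "absent"))
  stage_means <- tapply(expression$fpkm, expression$stage, mean)
  sc <- 0
  if (any(stage_means > 0) &&
      names(stage_means)[which.max(stage_means)] %in% spec$relevant_stages)
    sc <- sc + weights$expression_concordant
  de <- differential_expression_between_parents(expression)
  if (any(de$de_call & de$stage %in% spec$relevant_stages))
    sc <- sc + weights$expression_de
  list(score = min(sc, weights$expression_cap), flag = "")
}

#' Association score from the best validation p-value
#'
#' Threshold lookup on the smallest p among the gene's tested candidate
#' polymorphisms across validation populations.
#'
#' @param best_p Smallest association p-value, or `NULL`/`NA` when
#'   untested.
#' @param weights [scoring_weights()].
#' @return List with `score` and `flag` (`"untested"` when no data).
#' @export
association_score <- function(best_p, weights = scoring_weights()) {
  if (is.null(best_p) || is.na(best_p))
    return(list(score = 0, flag = "untested"))
  sc <- if (best_p < weights$assoc_strong_p) weights$assoc_strong
  else if (best_p < weights$assoc_moderate_p) weights$assoc_moderate
  else 0
  list(score = sc, flag = "")
}

#' Index raw candidate scores to a 1-10 general score
#'
#' Within one interval, `general = 1 + 9 (raw - min) / (max - min)`; when
#' all raw totals are equal every gene gets 5.5.  Ties in raw totals get
#' equal general scores, so ranking by general equals ranking by raw.
#'
#' @param cards Data frame of score cards for one QTL interval with a
#'   `raw_total` column.
#' @return The cards with a `general_score` column, sorted by descending
#'   raw total.
#' @export
aggregate_and_index <- function(cards) {
  if (is.null(cards) || !nrow(cards)) stop("empty score-card set")
  rng <- range(cards$raw_total)
  cards$general_score <- if (diff(rng) == 0) rep(5.5, nrow(cards)) else
    1 + 9 * (cards$raw_total - rng[1L]) / diff(rng)
  cards[order(-cards$raw_total, cards$gene_id), , drop = FALSE]
}

#' Score all genes of one QTL interval
#'
#' Assembles the five layer scores per gene and the indexed general score.
#'
#' @param interval One row of a `qtl_intervals` data frame.
#' @param genes Output of [genes_in_interval()].
#' @param annotations [classify_variants()] output (all genes).
#' @param descriptions Data frame `gene_id`, `description`.
#' @param expression Expression table (all genes).
#' @param assoc_p Named numeric: best association p per gene id (absent
#'   genes untested).
#' @param spec [trait_spec()] of the interval's trait.
#' @param weights [scoring_weights()].
#' @return `candidate_scorecards` data frame, one row per gene.
#' @export
score_qtl_genes <- function(interval, genes, annotations, descriptions,
                            expression, assoc_p = numeric(0), spec,
                            weights = scoring_weights()) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    ann_g <- annotations[!is.na(annotations$gene_id) &
                           annotations$gene_id == gid, , drop = FALSE]
    vs <- summarize_gene_variants(ann_g)
    desc <- descriptions$description[match(gid, descriptions$gene_id)]
    rel <- relevance_score(desc, spec, weights)
    expr <- expression_score(
      expression[expression$gene_id == gid, , drop = FALSE], spec, weights)
    assoc <- association_score(
      if (gid %in% names(assoc_p)) assoc_p[[gid]] else NULL, weights)
    data.frame(
      gene_id = gid, qtl_name = interval$name,
      lod_drop = genes$lod_drop[i],
      proximity_score = proximity_score(genes$lod_drop[i], weights),
      polymorphism_score = polymorphism_score(vs$max_impact, weights),
      max_impact = vs$max_impact,
      relevance_score = rel$score, relevance_excluded = rel$excluded,
      expression_score = expr$score,
      association_score = assoc$score,
      association_flag = assoc$flag,
      stringsAsFactors = FALSE)
  })
  cards <- do.call(rbind, rows)
  cards$raw_total <- cards$proximity_score + cards$polymorphism_score +
    cards$relevance_score + cards$expression_score + cards$association_score
  cards <- aggregate_and_index(cards)
  class(cards) <- c("candidate_scorecards", "data.frame")
  cards
}
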