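# End-to-end orchestration: scans -> thresholds -> robust QTLs -> support
# intervals -> genes -> evidence layers -> indexed score cards.  Plus the
# one-call synthetic study generator that feeds it.

#' Simulate a complete synthetic QTL study
#'
#' Bundles [simulate_ril_population()], [simulate_phenotypes()],
#' [simulate_annotation_bundle()] and (optionally) a half-diallel
#' validation panel into one planted-truth dataset ready for
#' [run_pipeline()].
#'
#' @param config A [sim_config()] object (must have traits).
#' @param n_genes_per_cM Gene density for the annotation bundle.
#' @param with_validation If `TRUE`, a half-diallel panel typed at the
#'   causal SNPs is generated per trait, with SNP effects aligned to the
#'   planted QTL effects.
#' @param n_founders Founders of the validation panel (default 20).
#' @return List: `map`, `genotypes`, `phenotypes`, `gene_models`,
#'   `variants`, `expression`, `descriptions`, `ref`, `validation`,
#'   `truth` (including `truth$genes`).
#' @export
simulate_qtl_study <- function(config, n_genes_per_cM = 1,
                               with_validation = TRUE, n_founders = 20) {
  pop <- simulate_ril_population(config)
  phen <- simulate_phenotypes(pop$genotypes, pop$map, config)
  bundle <- simulate_annotation_bundle(pop$map, pop$truth,
                                       n_genes_per_cM = n_genes_per_cM,
                                       seed = config$seed + 2L,
                                       bp_per_cM = config$bp_per_cM)
  validation <- NULL
  if (with_validation && nrow(bundle$truth_genes)) {
    tg <- bundle$truth_genes[!duplicated(bundle$truth_genes$snp_id), ,
                             drop = FALSE]
    dia <- simulate_diallel_panel(
      n_founders, candidate_snps = tg$snp_id,
      effects = rep(1, nrow(tg)), noise_sd = 1,
      seed = config$seed + 3L)
    # one validation trait per planted trait; all that trait's causal
    # SNPs contribute additively
    val_ph <- list()
    traits <- unique(bundle$truth_genes$trait)
    for (i in seq_along(traits)) {
      tr <- traits[i]
      snps <- unique(bundle$truth_genes$snp_id[
        bundle$truth_genes$trait == tr])
      ph <- dia$phenotypes
      ph$trait <- tr
      ph$value <- rowSums(dia$genotypes[, snps, drop = FALSE] - 1) +
        with_seed(config$seed + 4L + i,
                  stats::rnorm(nrow(dia$genotypes), 0, 1))
      val_ph[[i]] <- ph
    }
    snp_pos <- data.frame(snp_id = tg$snp_id,
                          chrom = tg$chrom,
                          pos = as.integer(sub(".*_", "", tg$snp_id)),
                          stringsAsFactors = FALSE)
    validation <- list(genotypes = dia$genotypes,
                       phenotypes = validate_phenotypes(do.call(rbind, val_ph)),
                       snp_pos = snp_pos)
  }
  geno <- pop$genotypes
  if (config$missing_rate > 0) {
    geno <- with_seed(config$seed + 9L, {
      mask <- stats::runif(length(geno)) < config$missing_rate
      geno[mask] <- NA_integer_
      geno
    })
  }
  truth <- pop$truth
  truth$genes <- bundle$truth_genes
  list(map = pop$map, genotypes = geno, phenotypes = phen,
       gene_models = bundle$gene_models, variants = bundle$variants,
       expression = bundle$expression, descriptions = bundle$descriptions,
       ref = bundle$ref, validation = validation, truth = truth)
}

#' Pipeline configuration
#'
#' @param traits List of [trait_spec()] objects (one per analyzed trait).
#' @param n_perm Permutations for the genome-wide threshold.
#' @param alpha Genome-wide significance level.
#' @param colocalization_cM Cross-environment clustering window.
#' @param min_n Minimum informative lines per marker.
#' @param weights [scoring_weights()].
#' @param general_cutoff General-score cutoff for the high-priority list.
#' @param seed Integer seed (mandatory).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traits, n_perm = 1000L, alpha = 0.05,
                            colocalization_cM = 10, min_n = 20L,
                            weights = scoring_weights(),
                            general_cutoff = 7, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(traits = traits, n_perm = n_perm, alpha = alpha,
                 colocalization_cM = colocalization_cM, min_n = min_n,
                 weights = weights, general_cutoff = general_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full candidate-gene prioritization pipeline
#'
#' Orchestrates, per trait: per-environment line means and marker scans,
#' permutation thresholds, robust-QTL consolidation, 2-LOD interval gene
#' lists, the five evidence layers, and the indexed score cards.  Also
#' fits the joint robust-QTL model and tests pairwise epistasis among
#' robust QTLs per trait.  Deterministic given the config seed.
#'
#' @param dataset A dataset list as from [simulate_qtl_study()] (or
#'   assembled from the readers).
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `status`, `thresholds`,
#'   `scans`, `qtls`, `qtl_models`, `epistasis`, `scorecards` (named by
#'   QTL), `candidates` (high-priority table).
#' @export
run_pipeline <- function(dataset, config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in c("map", "genotypes", "phenotypes"))
    if (is.null(dataset[[nm]])) stage_stop("input", "dataset lacks ", nm)
  envs <- sort(unique(dataset$phenotypes$environment))
  scans <- list(); thr_rows <- list(); qtl_rows <- list()
  scorecards <- list(); epi_rows <- list(); model_rows <- list()
  annotations <- NULL
  if (!is.null(dataset$variants) && !is.null(dataset$gene_models)) {
    annotations <- tryCatch(
      classify_variants(dataset$variants, dataset$gene_models, dataset$ref),
      error = function(e) stage_stop("annotate", conditionMessage(e)))
  }
  si <- 0L
  for (spec in config$traits) {
    tr <- spec$name
    tr_scans <- list(); tr_thr <- numeric(0); tr_means <- list()
    for (env in envs) {
      si <- si + 1L
      y <- tryCatch(
        line_means(dataset$phenotypes, tr, env,
                   lines = rownames(dataset$genotypes)),
        error = function(e) stage_stop("line_means", conditionMessage(e)))
      sc <- tryCatch(
        marker_scan(dataset$genotypes, dataset$map, y,
                    log_transform = spec$log_scale, min_n = config$min_n,
                    trait = tr, environment = env),
        error = function(e) stage_stop("scan", conditionMessage(e)))
      th <- tryCatch(
        permutation_threshold(dataset$genotypes, dataset$map, y,
                              n_perm = config$n_perm, alpha = config$alpha,
                              seed = config$seed + si,
                              log_transform = spec$log_scale,
                              min_n = config$min_n),
        error = function(e) stage_stop("threshold", conditionMessage(e)))
      tr_scans[[env]] <- sc
      tr_thr[env] <- as.numeric(th)
      tr_means[[env]] <- y
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        trait = tr, environment = env, threshold = as.numeric(th),
        stringsAsFactors = FALSE)
      scans[[paste(tr, env, sep = ".")]] <- sc
    }
    qtls <- tryCatch(
      find_robust_qtls(tr_scans, tr_thr, config$colocalization_cM,
                       trait = tr, genotypes = dataset$genotypes,
                       phenotypes = tr_means),
      error = function(e) stage_stop("robust_qtls", conditionMessage(e)))
    if (nrow(qtls)) {
      qtl_rows[[tr]] <- qtls
      # joint model and pairwise epistasis on robust peaks (best env means)
      ybest <- tr_means[[qtls$env_best[which.max(qtls$peak_lod)]]]
      if (spec$log_scale) {
        off <- if (min(ybest, na.rm = TRUE) > 0) 0 else
          -min(ybest, na.rm = TRUE) + 1
        ybest <- log10(ybest + off)
      }
      fitm <- tryCatch(
        fit_qtl_model(dataset$genotypes[, qtls$peak_marker, drop = FALSE],
                      ybest),
        error = function(e) stage_stop("qtl_model", conditionMessage(e)))
      model_rows[[tr]] <- data.frame(trait = tr, pct_var = fitm$pct_var,
                                     n_qtls = nrow(qtls),
                                     stringsAsFactors = FALSE)
      if (nrow(qtls) >= 2L) {
        prs <- utils::combn(nrow(qtls), 2L)
        for (k in seq_len(ncol(prs))) {
          i <- prs[1L, k]; j <- prs[2L, k]
          ep <- test_epistasis(dataset$genotypes[, qtls$peak_marker[i]],
                               dataset$genotypes[, qtls$peak_marker[j]],
                               ybest)
          epi_rows[[length(epi_rows) + 1L]] <- data.frame(
            trait = tr, qtl_i = qtls$name[i], qtl_j = qtls$name[j],
            p_interaction = ep$p_interaction, stringsAsFactors = FALSE)
        }
      }
      # evidence layers per QTL interval
      if (!is.null(annotations) && !is.null(dataset$gene_models)) {
        assoc_p <- pipeline_assoc_p(dataset, tr)
        for (qi in seq_len(nrow(qtls))) {
          itv <- qtls[qi, ]
          genes <- genes_in_interval(itv, dataset$gene_models, dataset$map,
                                     tr_scans[[itv$env_best]])
          if (!nrow(genes)) next
          cards <- score_qtl_genes(itv, genes, annotations,
                                   dataset$descriptions,
                                   dataset$expression, assoc_p, spec,
                                   config$weights)
          scorecards[[itv$name]] <- cards
        }
      }
    }
  }
  qtls_all <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else NULL
  if (!is.null(qtls_all)) rownames(qtls_all) <- NULL
  candidates <- NULL
  if (length(scorecards)) {
    comb <- do.call(rbind, scorecards)
    rownames(comb) <- NULL
    candidates <- comb[comb$general_score >= config$general_cutoff, ,
                       drop = FALSE]
  }
  status <- if (is.null(qtls_all) || !nrow(qtls_all)) "no robust QTLs"
    else "ok"
  structure(list(
    status = status,
    thresholds = do.call(rbind, thr_rows),
    scans = scans, qtls = qtls_all,
    qtl_models = if (length(model_rows)) do.call(rbind, model_rows) else NULL,
    epistasis = if (length(epi_rows)) do.call(rbind, epi_rows) else NULL,
    scorecards = scorecards, candidates = candidates),
    class = "pipeline_result")
}

# best association p per gene for one trait from the validation panel
pipeline_assoc_p <- function(dataset, trait) {
  val <- dataset$validation
  if (is.null(val)) return(numeric(0))
  ph <- val$phenotypes
  ph <- ph[ph$trait == trait, , drop = FALSE]
  if (!nrow(ph)) return(numeric(0))
  y <- stats::setNames(ph$value, ph$line)[rownames(val$genotypes)]
  out <- numeric(0)
  for (i in seq_len(nrow(val$snp_pos))) {
    sid <- val$snp_pos$snp_id[i]
    if (!(sid %in% colnames(val$genotypes))) next
    gid <- gene_at_position(dataset$gene_models, val$snp_pos$chrom[i],
                            val$snp_pos$pos[i] - 1L)
    if (is.na(gid)) next
    res <- tryCatch(candidate_snp_association(val$genotypes[, sid], y),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (!(gid %in% names(out)) || res$p < out[[gid]]) out[gid] <- res$p
  }
  out
}

gene_at_position <- function(models, chrom, pos0) {
  for (m in models)
    if (m$chrom == chrom && pos0 >= m$start0 && pos0 < m$end0)
      return(m$gene_id)
  NA_character_
}

#' Write pipeline outputs as a report directory
#'
#' Emits per-trait LOD tracks, the QTL table, per-QTL score cards, the
#' high-priority candidate table and a run manifest.  Byte-identical for
#' identical inputs and seed.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param inputs Named input paths recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_candidate_report <- function(result, out_dir, seed = NA,
                                   inputs = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  writeLines(result$status, file.path(out_dir, "status.txt"))
  if (!is.null(result$thresholds)) wt(result$thresholds, "thresholds.tsv")
  for (nm in names(result$scans))
    wt(result$scans[[nm]][, c("chrom", "pos_cM", "lod")],
       paste0("lod_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv"))
  if (!is.null(result$qtls)) wt(result$qtls, "qtls.tsv")
  if (length(result$scorecards)) {
    comb <- do.call(rbind, result$scorecards)
    rownames(comb) <- NULL
    wt(comb, "scorecards.tsv")
  }
  if (!is.null(result$candidates)) wt(result$candidates, "candidates.tsv")
  write_run_manifest(file.path(out_dir, "run_manifest.yaml"), inputs, seed)
  invisible(out_dir)
}
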