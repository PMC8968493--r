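# Synthetic annotation bundle: gene models tiled on a physical axis
# colinear with the genetic map, sequence fragments backing their CDS,
# planted variants, expression profiles and description keywords.  Planted
# causal genes carry a premature-stop variant, a trait-concordant
# expression profile and a relevant description; decoys carry random
# low/moderate-impact variants, flat profiles and neutral descriptions.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                        paste0), c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))

NEUTRAL_DESCRIPTIONS <- c(
  "ribosomal protein L13", "histone H3.2", "photosystem II subunit",
  "tubulin alpha chain", "heat shock protein 70", "actin depolymerizing factor",
  "unknown protein", "hypothetical protein", "uncharacterized protein")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# build one two-exon gene model plus its backing sequence fragment.
# geometry (plus strand, from gene start): UTR5 50 | CDS 300 | intron 200 |
# CDS 300 | UTR3 50; minus-strand genes mirror this layout.
build_synth_gene <- function(gene_id, chrom, mid_bp, strand, description) {
  u5 <- 50L; c1 <- 300L; int <- 200L; c2 <- 300L; u3 <- 50L
  glen <- u5 + c1 + int + c2 + u3
  start0 <- as.integer(round(mid_bp)) - glen %/% 2L
  e <- function(a, b) cbind(start0 = a, end0 = b)
  if (strand == "+") {
    utr5 <- e(start0, start0 + u5)
    cds1 <- e(start0 + u5, start0 + u5 + c1)
    cds2 <- e(start0 + u5 + c1 + int, start0 + u5 + c1 + int + c2)
    utr3 <- e(start0 + glen - u3, start0 + glen)
    exons <- rbind(e(start0, start0 + u5 + c1),
                   e(start0 + u5 + c1 + int, start0 + glen))
    cds <- rbind(cbind(cds1, phase = 0L), cbind(cds2, phase = 0L))
  } else {
    # transcription runs right to left: UTR5 at the right end
    utr5 <- e(start0 + glen - u5, start0 + glen)
    cds1 <- e(start0 + glen - u5 - c1, start0 + glen - u5)
    cds2 <- e(start0 + u3, start0 + u3 + c2)
    utr3 <- e(start0, start0 + u3)
    exons <- rbind(e(start0 + glen - u5 - c1, start0 + glen),
                   e(start0, start0 + u3 + c2))
    cds <- rbind(cbind(cds1, phase = 0L), cbind(cds2, phase = 0L))
  }
  model <- list(gene_id = gene_id, chrom = chrom, strand = strand,
                start0 = start0, end0 = start0 + glen,
                exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                description = description, translatable = TRUE)
  # CDS: ATG + 198 sense codons + TAA
  codons <- c("ATG", sample(SENSE_CODONS, (c1 + c2) / 3 - 2, replace = TRUE),
              "TAA")
  model$cds_codons <- codons
  model
}

# write the designed CDS codons into a plus-strand fragment sequence
imprint_cds <- function(frag_seq, frag_start0, model) {
  v <- strsplit(frag_seq, "")[[1L]]
  bases <- strsplit(paste(model$cds_codons, collapse = ""), "")[[1L]]
  gpos <- vapply(seq_along(bases) - 1L,
                 function(p) cds_pos_to_genome(model, p), numeric(1))
  if (model$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  v[gpos - frag_start0 + 1L] <- bases
  paste(v, collapse = "")
}

#' Simulate a gene/variant/expression annotation bundle
#'
#' Tiles `round(total cM * n_genes_per_cM)` two-exon genes on a physical
#' axis colinear with the map.  For each planted QTL in `truth`, the gene
#' nearest the QTL peak is moved onto the peak, given a premature-stop
#' (`stop_gained`) variant, a trait-concordant expression peak with
#' parental differential expression, and a relevant description.  Decoy
#' genes receive random synonymous/missense/intron/upstream variants, flat
#' expression and neutral descriptions; a few intergenic decoy variants are
#' added between genes.
#'
#' @param map Genetic map with bp anchors.
#' @param truth Truth list from [simulate_ril_population()] (uses
#'   `truth$qtls`).
#' @param n_genes_per_cM Gene density per cM (default 1).
#' @param seed Integer seed.
#' @param bp_per_cM Physical scale matching the map (default 250000).
#' @param stages Expression stage vocabulary.
#' @param relevant_stage Stage at which causal genes peak and are
#'   differentially expressed between parents.
#' @param causal_description Description planted on causal genes.
#' @return List: `gene_models`, `variants`, `expression`, `descriptions`,
#'   `ref` (fragment table), `truth_genes` (causal gene bookkeeping:
#'   `gene_id`, `trait`, `chrom`, `pos_cM`, `snp_id`, `intended_term`).
#' @export
simulate_annotation_bundle <- function(map, truth, n_genes_per_cM = 1,
                                       seed, bp_per_cM = 250000,
                                       stages = c("rind_5DAA", "rind_15DAA",
                                                  "rind_ripe", "leaf", "root"),
                                       relevant_stage = "rind_ripe",
                                       causal_description =
                                         "WRKY family transcription factor, ethylene and ripening related") {
  with_seed(seed, {
    chroms <- unique(map$chrom)
    qtls <- truth$qtls
    models <- list(); frags <- list(); vrows <- list()
    descr <- list(); truth_rows <- list()
    gi <- 0L
    for (ch in chroms) {
      L <- max(map$pos_cM[map$chrom == ch])
      n_ch <- max(1L, round(L * n_genes_per_cM))
      mids_cM <- seq(L / (n_ch + 1), L - L / (n_ch + 1), length.out = n_ch)
      chq <- qtls[qtls$chrom == ch, , drop = FALSE]
      causal_idx <- integer(0)
      if (nrow(chq)) {
        for (p in unique(chq$pos_cM)) {
          k <- which.min(abs(mids_cM - p))
          mids_cM[k] <- p
          causal_idx <- c(causal_idx, k)
        }
      }
      for (k in seq_len(n_ch)) {
        gi <- gi + 1L
        gene_id <- sprintf("SYN%sG%04d", sub("chr", "", ch), gi)
        is_causal <- k %in% causal_idx
        desc <- if (is_causal) causal_description else
          sample(NEUTRAL_DESCRIPTIONS, 1L)
        m <- build_synth_gene(gene_id, ch, mids_cM[k] * bp_per_cM + 1,
                              sample(c("+", "-"), 1L), desc)
        frag_start0 <- m$start0 - 1000L
        frag <- random_dna(m$end0 - m$start0 + 2000L)
        frag <- imprint_cds(frag, frag_start0, m)
        frags[[gi]] <- data.frame(chrom = ch, start0 = frag_start0,
                                  seq = frag, stringsAsFactors = FALSE)
        descr[[gi]] <- data.frame(gene_id = gene_id, description = desc,
                                  stringsAsFactors = FALSE)
        if (is_causal) {
          # plant TGG at an interior codon; G>A at its third base gives TGA
          ci <- 50L
          m$cds_codons[ci] <- "TGG"
          frag <- imprint_cds(frag, frag_start0, m)
          frags[[gi]]$seq <- frag
          p0 <- cds_pos_to_genome(m, 3L * (ci - 1L) + 2L)
          refb <- if (m$strand == "+") "G" else "C"
          altb <- if (m$strand == "+") "A" else "T"
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = ch, pos = p0 + 1L, ref = refb, alt = altb,
            stringsAsFactors = FALSE)
          for (tr in unique(chq$trait[chq$pos_cM == mids_cM[k]])) {
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
              gene_id = gene_id, trait = tr, chrom = ch,
              pos_cM = mids_cM[k],
              snp_id = paste0("S", ch, "_", p0 + 1L),
              intended_term = "stop_gained", stringsAsFactors = FALSE)
          }
        } else if (stats::runif(1) < 0.8) {
          kind <- sample(c("synonymous", "missense", "intron", "upstream"),
                         1L)
          if (kind == "synonymous") {
            ci <- sample(2:150, 1L)
            m$cds_codons[ci] <- "CTG"          # Leu; CTG>CTC stays Leu
            frag <- imprint_cds(frag, frag_start0, m)
            frags[[gi]]$seq <- frag
            p0 <- cds_pos_to_genome(m, 3L * (ci - 1L) + 2L)
            refb <- if (m$strand == "+") "G" else "C"
            altb <- if (m$strand == "+") "C" else "G"
          } else if (kind == "missense") {
            ci <- sample(2:150, 1L)
            m$cds_codons[ci] <- "GCT"          # Ala; GCT>GTT is Val
            frag <- imprint_cds(frag, frag_start0, m)
            frags[[gi]]$seq <- frag
            p0 <- cds_pos_to_genome(m, 3L * (ci - 1L) + 1L)
            refb <- if (m$strand == "+") "C" else "G"
            altb <- if (m$strand == "+") "T" else "A"
          } else if (kind == "intron") {
            # intron midpoint, clear of splice regions
            intron <- intron_spans(m)[1L, ]
            p0 <- as.integer((intron[1L] + intron[2L]) %/% 2L)
            refb <- substr(frag, p0 - frag_start0 + 1L, p0 - frag_start0 + 1L)
            altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          } else {
            p0 <- m$start0 - 300L
            refb <- substr(frag, p0 - frag_start0 + 1L, p0 - frag_start0 + 1L)
            altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
          }
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = ch, pos = p0 + 1L, ref = refb, alt = altb,
            stringsAsFactors = FALSE)
        }
        m$cds_codons <- NULL
        models[[gene_id]] <- m
      }
      # a couple of intergenic decoy variants per chromosome
      if (n_ch >= 2L) {
        gaps_mid <- (mids_cM[-1L] + mids_cM[-n_ch]) / 2
        for (gm in utils::head(gaps_mid, 2L)) {
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = ch, pos = as.integer(round(gm * bp_per_cM)),
            ref = "A", alt = "C", stringsAsFactors = FALSE)
        }
      }
    }
    vdf <- do.call(rbind, vrows)
    variants <- make_variant_records(vdf$chrom, vdf$pos, vdf$ref, vdf$alt)
    gene_models <- structure(models, class = "gene_models")
    descriptions <- do.call(rbind, descr)
    truth_genes <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(gene_id = character(0), trait = character(0),
                 chrom = character(0), pos_cM = numeric(0),
                 snp_id = character(0), intended_term = character(0))
    expression <- simulate_expression(gene_models, truth_genes, stages,
                                      relevant_stage)
    ref <- do.call(rbind, frags)
    class(ref) <- c("ref_fragments", "data.frame")
    list(gene_models = gene_models, variants = variants,
         expression = expression, descriptions = descriptions,
         ref = ref, truth_genes = truth_genes)
  })
}

# replicated parental FPKM profiles; causal genes peak at the relevant
# stage with ~4x parental differential expression, decoys are flat
simulate_expression <- function(gene_models, truth_genes, stages,
                                relevant_stage, n_reps = 2L) {
  gids <- vapply(gene_models, `[[`, "", "gene_id")
  grid <- expand.grid(replicate = paste0("rep", seq_len(n_reps)),
                      genotype = c("P1", "P2"), stage = stages,
                      gene_id = gids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  causal <- grid$gene_id %in% truth_genes$gene_id
  at_rel <- grid$stage == relevant_stage
  base <- stats::rlnorm(nrow(grid), log(2), 0.3)
  # one baseline per gene x stage x genotype cell, shared across replicates
  cell <- paste(grid$gene_id, grid$stage, grid$genotype)
  base <- stats::ave(base, cell, FUN = function(x) x[1L])
  base[causal & at_rel & grid$genotype == "P1"] <- 40
  base[causal & at_rel & grid$genotype == "P2"] <- 9
  grid$fpkm <- pmax(0, base * (1 + stats::rnorm(nrow(grid), 0, 0.1)))
  grid[, c("gene_id", "stage", "genotype", "replicate", "fpkm")]
}
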