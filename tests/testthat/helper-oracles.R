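# Independent oracles.  These deliberately take different computational
# routes from the package implementation: the LOD oracle goes through
# lm(), and the consequence oracle mutates the genomic sequence, re-extracts
# the full CDS and diffs the translated proteins.

oracle_lod <- function(dosage, y) {
  cc <- !is.na(dosage) & !is.na(y)
  fit <- lm(y[cc] ~ dosage[cc])
  r2 <- summary(fit)$r.squared
  -(sum(cc) / 2) * log10(1 - r2)
}

# --- translation-diff consequence oracle --------------------------------

oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# apply a normalized variant to a fragment string; returns the mutant
# fragment and the coordinate shift delta
apply_edit <- function(frag_seq, frag_start0, variant) {
  i <- variant$pos0 - frag_start0 + 1L        # 1-based anchor in fragment
  stopifnot(substr(frag_seq, i, i + nchar(variant$ref) - 1L) == variant$ref)
  mutant <- paste0(substr(frag_seq, 1L, i - 1L), variant$alt,
                   substr(frag_seq, i + nchar(variant$ref), nchar(frag_seq)))
  list(seq = mutant, delta = nchar(variant$alt) - nchar(variant$ref))
}

# extract the CDS from a fragment given (possibly shifted) segment bounds
extract_cds <- function(frag_seq, frag_start0, cds, strand) {
  segs <- vapply(seq_len(nrow(cds)), function(k)
    substr(frag_seq, cds[k, "start0"] - frag_start0 + 1L,
           cds[k, "end0"] - frag_start0), character(1))
  if (strand == "-")
    segs <- vapply(segs, function(s)
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]),
                                   collapse = "")), character(1),
      USE.NAMES = FALSE)
  paste(segs, collapse = "")
}

oracle_classify_coding <- function(variant, model, ref) {
  fr <- ref[ref$chrom == model$chrom &
              ref$start0 <= model$start0 &
              ref$start0 + nchar(ref$seq) >= model$end0, ][1L, ]
  cds_ref <- extract_cds(fr$seq, fr$start0, model$cds, model$strand)
  ed <- apply_edit(fr$seq, fr$start0, variant)
  # shift CDS segment bounds right of the edit anchor
  cds_mut <- model$cds
  for (k in seq_len(nrow(cds_mut))) {
    if (cds_mut[k, "start0"] > variant$pos0)
      cds_mut[k, "start0"] <- cds_mut[k, "start0"] + ed$delta
    if (cds_mut[k, "end0"] > variant$pos0)
      cds_mut[k, "end0"] <- cds_mut[k, "end0"] + ed$delta
  }
  cds_alt <- extract_cds(ed$seq, fr$start0, cds_mut, model$strand)
  dlen <- nchar(cds_alt) - nchar(cds_ref)
  if (dlen %% 3L != 0L) return("frameshift")
  p_ref <- strsplit(oracle_translate(cds_ref), "")[[1L]]
  p_alt <- strsplit(oracle_translate(cds_alt), "")[[1L]]
  if (identical(p_ref, p_alt)) return("synonymous")
  if (p_alt[1L] != "M") return("start_lost")
  if (dlen == 0L) {
    d <- which(p_ref != p_alt)
    if (length(d) == 1L && d == length(p_ref) && p_ref[d] == "*")
      return("stop_lost")
    if (any(p_alt[d] == "*")) return("stop_gained")
    return("missense")
  }
  internal_stops <- which(p_alt == "*")
  internal_stops <- internal_stops[internal_stops < length(p_alt)]
  if (length(internal_stops)) return("stop_gained")
  if (dlen < 0L) "inframe_deletion" else "inframe_insertion"
}

# random coding variants inside CDS exon interiors, clear of exon
# junction splice regions; SNPs may hit the start/stop codons, indels
# may not
random_coding_variants <- function(models, ref, n, seed) {
  set.seed(seed)
  gids <- names(models)
  rows <- list()
  while (length(rows) < n) {
    m <- models[[sample(gids, 1L)]]
    fr <- ref[ref$chrom == m$chrom & ref$start0 <= m$start0 &
                ref$start0 + nchar(ref$seq) >= m$end0, ][1L, ]
    kind <- sample(c("snp", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
    # candidate genome positions: CDS interiors away from junctions
    ok_pos <- unlist(lapply(seq_len(nrow(m$cds)), function(k)
      seq(m$cds[k, "start0"] + 4L, m$cds[k, "end0"] - 5L)))
    g0 <- sample(ok_pos, 1L)
    if (kind == "snp") {
      # occasionally aim at the start or stop codon
      if (runif(1) < 0.05) {
        cpos <- sample(c(0:2, (sum(m$cds[, "end0"] - m$cds[, "start0"]) - 3):
                           (sum(m$cds[, "end0"] - m$cds[, "start0"]) - 1)), 1L)
        g0 <- qtlprior:::cds_pos_to_genome(m, cpos)
      }
      refb <- substr(fr$seq, g0 - fr$start0 + 1L, g0 - fr$start0 + 1L)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      v <- list(pos0 = g0, pos = g0 + 1L, ref = refb, alt = altb,
                type = "SNP")
    } else if (kind == "del") {
      k <- sample(1:5, 1L)
      # deleted bases must stay inside the same CDS segment interior and
      # clear of the terminal codons
      seg <- which(m$cds[, "start0"] <= g0 & g0 < m$cds[, "end0"])
      if (g0 + k > m$cds[seg, "end0"] - 5L) next
      cposs <- vapply(seq(g0 + 1L, g0 + k), function(g)
        qtlprior:::genome_pos_to_cds(m, g), integer(1))
      ncod <- sum(m$cds[, "end0"] - m$cds[, "start0"]) %/% 3L
      if (any(cposs %/% 3L %in% c(0L, ncod - 1L))) next
      refs <- substr(fr$seq, g0 - fr$start0 + 1L, g0 - fr$start0 + 1L + k)
      v <- list(pos0 = g0, pos = g0 + 1L, ref = refs,
                alt = substr(refs, 1L, 1L), type = "deletion")
    } else {
      seg <- which(m$cds[, "start0"] <= g0 & g0 < m$cds[, "end0"])
      if (g0 + 1L >= m$cds[seg, "end0"]) next
      cpos_anchor <- qtlprior:::genome_pos_to_cds(m, g0)
      ncod <- sum(m$cds[, "end0"] - m$cds[, "start0"]) %/% 3L
      if (cpos_anchor %/% 3L %in% c(0L, ncod - 1L)) next
      k <- sample(1:5, 1L)
      refb <- substr(fr$seq, g0 - fr$start0 + 1L, g0 - fr$start0 + 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
      v <- list(pos0 = g0, pos = g0 + 1L, ref = refb,
                alt = paste0(refb, ins), type = "insertion")
    }
    v$chrom <- m$chrom
    v$gene_id <- m$gene_id
    v$snp_id <- paste0("S", m$chrom, "_", v$pos, "_", length(rows))
    rows[[length(rows) + 1L]] <- v
  }
  rows
}

# small gene-model universe with sequence backing, for classifier tests
oracle_gene_universe <- function(n_genes = 30, seed = 99) {
  cfg <- sim_config(n_lines = 10, chr_lengths_cM = c(30, 30),
                    marker_spacing_cM = 10,
                    traits = list(), seed = seed)
  pop <- simulate_ril_population(cfg)
  bundle <- simulate_annotation_bundle(pop$map, pop$truth,
                                       n_genes_per_cM = n_genes / 60,
                                       seed = seed + 1L)
  bundle
}
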