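# Variant consequence classification against gene models.  Terms follow
# the usual annotator vocabulary; impact is a fixed pure function of the
# term.  Codons are reconstructed locally from the reference fragment
# table (reverse complement on minus-strand genes); overlaps are resolved
# by severity precedence.

#' Consequence term -> impact tier table
#'
#' @format Named character vector mapping consequence terms to one of
#'   `MODIFIER`, `LOW`, `MODERATE`, `HIGH`.
#' @export
IMPACT_TABLE <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_donor = "HIGH", splice_acceptor = "HIGH", frameshift = "HIGH",
  missense = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE",
  synonymous = "LOW", splice_region = "LOW",
  five_prime_utr = "MODIFIER", three_prime_utr = "MODIFIER",
  intron = "MODIFIER", upstream = "MODIFIER", downstream = "MODIFIER",
  intergenic = "MODIFIER", exonic_unclassified = "MODIFIER")

# severity precedence for picking the single reported term per (variant, gene)
TERM_SEVERITY <- c("stop_gained", "stop_lost", "start_lost",
                   "splice_acceptor", "splice_donor", "frameshift",
                   "missense", "inframe_insertion", "inframe_deletion",
                   "splice_region", "synonymous", "five_prime_utr",
                   "three_prime_utr", "intron", "upstream", "downstream",
                   "exonic_unclassified", "intergenic")

IMPACT_LEVELS <- c("none", "MODIFIER", "LOW", "MODERATE", "HIGH")

revcomp <- function(s)
  vapply(s, function(x)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1L]]), collapse = "")), character(1),
    USE.NAMES = FALSE)

# standard genetic code, cached at namespace load
GC_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- GC_TABLE[codon]
  ifelse(is.na(aa), "X", unname(aa))
}

# intron spans (0-based half-open, ascending genome order)
intron_spans <- function(model) {
  ex <- model$exons[order(model$exons[, "start0"]), , drop = FALSE]
  if (nrow(ex) < 2L) return(matrix(numeric(0), 0, 2))
  cbind(ex[-nrow(ex), "end0"], ex[-1L, "start0"])
}

# genome position (0-based) of a CDS coordinate (0-based, transcription order)
cds_pos_to_genome <- function(model, cds_pos0) {
  off <- cds_pos0
  for (i in seq_len(nrow(model$cds))) {
    len <- model$cds[i, "end0"] - model$cds[i, "start0"]
    if (off < len) {
      return(if (model$strand == "+") model$cds[i, "start0"] + off
             else model$cds[i, "end0"] - 1L - off)
    }
    off <- off - len
  }
  stop("CDS position ", cds_pos0, " outside gene ", model$gene_id)
}

# CDS coordinate of a genome position, or NA when outside the CDS
genome_pos_to_cds <- function(model, g0) {
  cum <- 0L
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds[i, "start0"]; e <- model$cds[i, "end0"]
    if (g0 >= s && g0 < e) {
      return(if (model$strand == "+") cum + (g0 - s)
             else cum + (e - 1L - g0))
    }
    cum <- cum + (e - s)
  }
  NA_integer_
}

# full CDS sequence in transcription orientation
gene_cds_seq <- function(model, ref) {
  segs <- vapply(seq_len(nrow(model$cds)), function(i)
    ref_seq(ref, model$chrom, model$cds[i, "start0"], model$cds[i, "end0"]),
    character(1))
  if (model$strand == "-") segs <- revcomp(segs)
  paste(segs, collapse = "")
}

in_span <- function(p, spans) {
  if (is.null(spans) || !nrow(spans)) return(FALSE)
  any(p >= spans[, 1L] & p < spans[, 2L])
}

# splice-site terms for an intronic position; NULL if not near a boundary
splice_term_intronic <- function(model, p) {
  for (i in seq_len(nrow(intron_spans(model)))) {
    sp <- intron_spans(model)[i, ]
    if (p < sp[1L] || p >= sp[2L]) next
    d_left <- p - sp[1L]            # bases from the left intron edge
    d_right <- sp[2L] - 1L - p      # bases from the right intron edge
    if (model$strand == "+") {
      d_donor <- d_left; d_acceptor <- d_right
    } else {
      d_donor <- d_right; d_acceptor <- d_left
    }
    if (d_donor < 2L) return("splice_donor")
    if (d_acceptor < 2L) return("splice_acceptor")
    if (d_donor < 8L || d_acceptor < 8L) return("splice_region")
    return("intron")
  }
  NULL
}

# TRUE when an exonic position is within 3 bases of an intron boundary
exonic_splice_region <- function(model, p) {
  intr <- intron_spans(model)
  if (!nrow(intr)) return(FALSE)
  any(p >= intr[, 1L] - 3L & p < intr[, 1L]) ||
    any(p >= intr[, 2L] & p < intr[, 2L] + 3L)
}

utr_side <- function(model, p) {
  if (in_span(p, model$utr5)) return("five_prime_utr")
  if (in_span(p, model$utr3)) return("three_prime_utr")
  # infer from CDS span when UTRs unannotated
  cds_min <- min(model$cds[, "start0"]); cds_max <- max(model$cds[, "end0"])
  if (model$strand == "+") {
    if (p < cds_min) "five_prime_utr" else "three_prime_utr"
  } else {
    if (p >= cds_max) "five_prime_utr" else "three_prime_utr"
  }
}

classify_snp_in_cds <- function(model, ref, g0, ref_allele, alt_allele) {
  cpos <- genome_pos_to_cds(model, g0)
  codon_idx <- cpos %/% 3L
  within <- cpos %% 3L
  codon_g <- vapply(0:2, function(k)
    cds_pos_to_genome(model, codon_idx * 3L + k), numeric(1))
  bases <- vapply(codon_g, function(gp) {
    b <- ref_seq(ref, model$chrom, gp, gp + 1L)
    if (model$strand == "-") chartr("ACGT", "TGCA", b) else b
  }, character(1))
  ref_codon <- paste(bases, collapse = "")
  alt_b <- if (model$strand == "-") chartr("ACGT", "TGCA", alt_allele)
    else alt_allele
  alt_bases <- bases
  alt_bases[within + 1L] <- alt_b
  alt_codon <- paste(alt_bases, collapse = "")
  n_codons <- cds_len_codons(model)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (codon_idx == 0L) {
    if (alt_codon == "ATG") "synonymous" else "start_lost"
  } else if (codon_idx == n_codons - 1L && ref_aa == "*") {
    if (alt_aa == "*") "synonymous" else "stop_lost"
  } else if (alt_aa == "*") {
    "stop_gained"
  } else if (alt_aa == ref_aa) {
    "synonymous"
  } else {
    "missense"
  }
}

cds_len_codons <- function(model)
  as.integer(sum(model$cds[, "end0"] - model$cds[, "start0"])) %/% 3L

classify_indel_in_cds <- function(model, ref, variant) {
  # after normalization the first base is a shared anchor; the edit spans
  # genome positions [pos0 + 1, pos0 + nchar(ref)) for deletions, or sits
  # in the (pos0, pos0 + 1) gap for insertions
  dlen <- nchar(variant$ref) - nchar(variant$alt)
  if (dlen > 0L) {
    del_g <- seq(variant$pos0 + 1L, variant$pos0 + nchar(variant$ref) - 1L)
    cposs <- vapply(del_g, function(g) genome_pos_to_cds(model, g),
                    integer(1))
    if (anyNA(cposs)) return(NULL)  # spans out of CDS; caller falls back
    cstart <- min(cposs)
    n_codons <- cds_len_codons(model)
    if (any(cposs %/% 3L == 0L)) return("start_lost")
    if (any(cposs %/% 3L == n_codons - 1L)) return("stop_lost")
    if (dlen %% 3L != 0L) return("frameshift")
    # inframe: does the junction create a premature stop?
    cds <- gene_cds_seq(model, ref)
    mutant <- paste0(substr(cds, 1L, cstart),
                     substr(cds, cstart + dlen + 1L, nchar(cds)))
    win_from <- (cstart %/% 3L) * 3L
    win_to <- min(nchar(mutant), win_from + 6L)
    win <- substr(mutant, win_from + 1L, win_to)
    cods <- substring(win, seq(1L, nchar(win) - 2L, 3L),
                      seq(3L, nchar(win), 3L))
    if (any(translate_codon(cods) == "*") &&
        win_from %/% 3L < cds_len_codons(model) - 1L)
      "stop_gained" else "inframe_deletion"
  } else {
    ilen <- -dlen
    c_anchor <- genome_pos_to_cds(model, variant$pos0)
    c_next <- genome_pos_to_cds(model, variant$pos0 + 1L)
    if (is.na(c_anchor) || is.na(c_next)) return(NULL)
    ins_at <- min(c_anchor, c_next) + 1L   # insert before this CDS index
    ins_seq <- substr(variant$alt, 2L, nchar(variant$alt))
    if (model$strand == "-") ins_seq <- revcomp(ins_seq)
    if (ilen %% 3L != 0L) return("frameshift")
    cds <- gene_cds_seq(model, ref)
    mutant <- paste0(substr(cds, 1L, ins_at),
                     ins_seq,
                     substr(cds, ins_at + 1L, nchar(cds)))
    win_from <- (ins_at %/% 3L) * 3L
    win_to <- min(nchar(mutant), ((ins_at + ilen) %/% 3L) * 3L + 3L)
    win <- substr(mutant, win_from + 1L, win_to)
    cods <- substring(win, seq(1L, nchar(win) - 2L, 3L),
                      seq(3L, nchar(win), 3L))
    if (any(translate_codon(cods) == "*")) "stop_gained"
    else "inframe_insertion"
  }
}

#' Classify one variant against one gene model
#'
#' Assigns the single highest-severity consequence term for the
#' (variant, gene) pair, with minus-strand codons read on the reverse
#' complement.  Variants in non-translatable models get the best-effort
#' term `exonic_unclassified` (MODIFIER) when exonic.
#'
#' @param variant One-row `variant_records` data frame (or list with
#'   `pos0`, `ref`, `alt`, `type`).
#' @param model A single gene model.
#' @param ref Reference fragment table.
#' @return Character consequence term.
#' @export
classify_variant_gene <- function(variant, model, ref) {
  p <- variant$pos0
  edit_span <- if (variant$type == "deletion")
    c(p + 1L, p + nchar(variant$ref)) else c(p, p + 1L)
  terms <- character(0)
  pos_in_gene <- edit_span[1L] >= model$start0 && edit_span[2L] <= model$end0
  if (!pos_in_gene && p >= model$start0 && p < model$end0) pos_in_gene <- TRUE
  if (!pos_in_gene) {
    before <- edit_span[2L] <= model$start0
    return(if ((model$strand == "+") == before) "upstream" else "downstream")
  }
  if (!isTRUE(model$translatable) || is.null(model$cds)) {
    return(if (in_span(p, model$exons)) "exonic_unclassified" else "intron")
  }
  positions <- seq(edit_span[1L], edit_span[2L] - 1L)
  in_cds <- vapply(positions, function(g)
    !is.na(genome_pos_to_cds(model, g)), TRUE)
  if (variant$type == "SNP") {
    if (in_cds[1L]) {
      terms <- c(terms, classify_snp_in_cds(model, ref, p, variant$ref,
                                            variant$alt))
      if (exonic_splice_region(model, p)) terms <- c(terms, "splice_region")
    } else if (in_span(p, model$exons)) {
      terms <- c(terms, utr_side(model, p))
      if (exonic_splice_region(model, p)) terms <- c(terms, "splice_region")
    } else {
      terms <- c(terms, splice_term_intronic(model, p) %||% "intron")
    }
  } else {
    # indel: try CDS logic; fall back on the per-base regions
    if (all(in_cds) &&
        (variant$type == "deletion" ||
         !is.na(genome_pos_to_cds(model, p)))) {
      t_cds <- classify_indel_in_cds(model, ref, variant)
      if (!is.null(t_cds)) terms <- c(terms, t_cds)
    }
    if (!length(terms)) {
      for (g in positions) {
        if (!is.na(genome_pos_to_cds(model, g))) {
          terms <- c(terms, "frameshift")  # partial CDS overlap
        } else if (in_span(g, model$exons)) {
          terms <- c(terms, utr_side(model, g))
        } else {
          terms <- c(terms, splice_term_intronic(model, g) %||% "intron")
        }
      }
    }
  }
  terms[which.min(match(terms, TERM_SEVERITY))]
}

#' Classify variants against all overlapping gene models
#'
#' One annotation per (variant, gene); a variant overlapping two genes
#' yields two annotations.  Variants overlapping no gene within
#' `updown_bp` are reported as `intergenic` with `gene_id = NA`.
#'
#' @param variants `variant_records` data frame.
#' @param models `gene_models` object.
#' @param ref Reference fragment table.
#' @param updown_bp Flank within which upstream/downstream terms are
#'   assigned (default 1000).
#' @return Data frame: `snp_id`, `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `term`, `impact`.
#' @export
classify_variants <- function(variants, models, ref, updown_bp = 1000) {
  gtab <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    start0 = vapply(models, `[[`, 1, "start0"),
    end0 = vapply(models, `[[`, 1, "end0"), stringsAsFactors = FALSE)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hit <- which(gtab$chrom == v$chrom &
                   v$pos0 < gtab$end0 + updown_bp &
                   v$pos0 >= gtab$start0 - updown_bp)
    if (!length(hit)) {
      out[[i]] <- data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                             ref = v$ref, alt = v$alt,
                             gene_id = NA_character_, term = "intergenic",
                             impact = "MODIFIER", stringsAsFactors = FALSE)
      next
    }
    ann <- lapply(hit, function(h) {
      term <- classify_variant_gene(v, models[[h]], ref)
      data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                 ref = v$ref, alt = v$alt, gene_id = gtab$gene_id[h],
                 term = term, impact = unname(IMPACT_TABLE[term]),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, ann)
  }
  do.call(rbind, out)
}

#' Filter a variant set to genic space
#'
#' Keeps variants within any gene span, within annotated UTRs, or (for
#' genes without UTR annotation) within `utr_flank_bp` of the gene span.
#'
#' @param variants `variant_records` data frame.
#' @param models `gene_models` object.
#' @param utr_flank_bp Flank used when a gene lacks UTR annotation
#'   (default 500).
#' @return List with `variants` (retained rows) and `report`
#'   (named counts: input, retained, removed).
#' @export
filter_to_genic <- function(variants, models, utr_flank_bp = 500) {
  windows <- lapply(models, function(m) {
    fl <- if (is.null(m$utr5) && is.null(m$utr3)) utr_flank_bp else 0L
    c(chrom = m$chrom, lo = m$start0 - fl, hi = m$end0 + fl)
  })
  wchrom <- vapply(windows, `[[`, "", "chrom")
  wlo <- as.numeric(vapply(windows, `[[`, "", "lo"))
  whi <- as.numeric(vapply(windows, `[[`, "", "hi"))
  keep <- vapply(seq_len(nrow(variants)), function(i)
    any(wchrom == variants$chrom[i] & variants$pos0[i] >= wlo &
          variants$pos0[i] < whi), TRUE)
  list(variants = variants[keep, , drop = FALSE],
       report = c(input = nrow(variants), retained = sum(keep),
                  removed = sum(!keep)))
}

#' Summarize the variants of one gene
#'
#' @param annotations Data frame of [classify_variants()] rows for one gene.
#' @return List with `max_impact` (`"none"` for empty input) and `tally`
#'   (table of consequence terms).
#' @export
summarize_gene_variants <- function(annotations) {
  if (is.null(annotations) || !nrow(annotations))
    return(list(max_impact = "none", tally = table(character(0))))
  lv <- factor(annotations$impact, levels = IMPACT_LEVELS, ordered = TRUE)
  list(max_impact = as.character(max(lv)),
       tally = table(annotations$term))
}
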