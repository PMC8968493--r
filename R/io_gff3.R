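# GFF3 gene-model input/output.  Parsing is delegated to
# rtracklayer::import(); the writer is a small serializer that restores
# 1-based inclusive GFF3 coordinates from the package's 0-based half-open
# internal convention.

#' Read gene models from a GFF3 file
#'
#' Expects `gene`/`mRNA`/`exon`/`CDS` features (UTR features optional), with
#' 1-based inclusive coordinates as per the GFF3 standard.  Internal
#' coordinates are converted to 0-based half-open.  Exons and CDS segments
#' are sorted 5'->3' in transcription order (reversed file order on the
#' minus strand).  Models whose CDS length (after phase handling) is not a
#' multiple of 3 are flagged non-translatable and retained with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gene_models`: a named list of gene model
#'   lists with elements `gene_id`, `chrom`, `strand`, `start0`, `end0`,
#'   `exons`, `cds` (two-column 0-based half-open matrices in transcription
#'   order; `cds` has a `phase` column), `utr5`, `utr3`, `description`,
#'   `translatable`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  if (!is.null(df$Parent))
    df$parent <- vapply(df$Parent, function(p)
      if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  else df$parent <- NA_character_
  genes <- df[df$type == "gene", , drop = FALSE]
  # map mRNA id -> gene id so exon/CDS Parent (usually the mRNA) resolves
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  feat_parent_gene <- function(parent) {
    ifelse(parent %in% mrna$ID,
           mrna$parent[match(parent, mrna$ID)], parent)
  }
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    kids <- df[!is.na(df$parent) & feat_parent_gene(df$parent) == gid, ,
               drop = FALSE]
    seg <- function(type) {
      s <- kids[kids$type %in% type, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      ord <- order(s$start)
      if (g$strand == "-") ord <- rev(ord)
      m <- cbind(start0 = s$start[ord] - 1L, end0 = s$end[ord])
      if ("CDS" %in% type) {
        ph <- suppressWarnings(as.integer(as.character(s$phase[ord])))
        ph[is.na(ph)] <- 0L
        m <- cbind(m, phase = ph)
      }
      m
    }
    cds <- seg("CDS")
    translatable <- TRUE
    if (!is.null(cds)) {
      clen <- sum(cds[, "end0"] - cds[, "start0"]) - cds[1L, "phase"]
      if (clen %% 3L != 0L) {
        translatable <- FALSE
        warning("gene ", gid, ": CDS length not divisible by 3; ",
                "model flagged non-translatable", call. = FALSE)
      }
    }
    desc <- if (!is.null(g$description)) g$description else NA_character_
    list(gene_id = gid, chrom = g$seqnames, strand = g$strand,
         start0 = g$start - 1L, end0 = g$end,
         exons = seg("exon"), cds = cds,
         utr5 = seg(c("five_prime_UTR", "5'UTR")),
         utr3 = seg(c("three_prime_UTR", "3'UTR")),
         description = desc, translatable = translatable)
  })
  names(models) <- genes$ID
  structure(models, class = "gene_models")
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS (and UTR) records, restoring 1-based inclusive
#' coordinates.  `write_gff3(read_gff3(f), f2)` reproduces an equivalent
#' file; writing, reading and writing again is a fixed point.
#'
#' @param models `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s0, e0, strand, phase, attrs)
    paste(chrom, "qtlprior", type, s0 + 1L, e0, ".", strand,
          phase, attrs, sep = "\t")
  for (m in models) {
    desc <- if (!is.na(m$description %||% NA))
      paste0(";description=", m$description) else ""
    writeLines(fmt(m$chrom, "gene", m$start0, m$end0, m$strand, ".",
                   paste0("ID=", m$gene_id, desc)), con)
    tid <- paste0(m$gene_id, ".t1")
    writeLines(fmt(m$chrom, "mRNA", m$start0, m$end0, m$strand, ".",
                   paste0("ID=", tid, ";Parent=", m$gene_id)), con)
    emit <- function(mat, type, with_phase = FALSE) {
      if (is.null(mat)) return()
      ord <- order(mat[, "start0"])  # file order is ascending
      for (r in ord) {
        ph <- if (with_phase) mat[r, "phase"] else "."
        writeLines(fmt(m$chrom, type, mat[r, "start0"], mat[r, "end0"],
                       m$strand, ph, paste0("Parent=", tid)), con)
      }
    }
    emit(m$exons, "exon")
    emit(m$cds, "CDS", with_phase = TRUE)
    emit(m$utr5, "five_prime_UTR")
    emit(m$utr3, "three_prime_UTR")
  }
  invisible(path)
}

#' Total CDS length of a gene model
#'
#' @param model A single gene model.
#' @return Integer CDS length in bp (0 when the model has no CDS).
#' @export
cds_length <- function(model) {
  if (is.null(model$cds)) return(0L)
  as.integer(sum(model$cds[, "end0"] - model$cds[, "start0"]))
}
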