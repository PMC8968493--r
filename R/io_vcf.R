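# VCF variant input/output.  Parsing is delegated to vcfR::read.vcfR();
# the writer emits a minimal VCF 4.2 so written files round-trip through
# the reader.

#' Read variants from a VCF file
#'
#' Multiallelic sites are split into one record per alternate allele.
#' Records with missing REF or ALT are skipped with a counted warning.
#' Alleles are normalized to their minimal representation (shared
#' suffix/prefix trimmed, anchor base kept) and, when a reference fragment
#' table is supplied, indels are left-shifted while the flanking reference
#' sequence permits.
#'
#' @param path Path to a VCF 4.x file.
#' @param ref Optional [read_ref_fragments()] table for indel left-alignment.
#' @return Data frame with class `variant_records`: columns `snp_id`,
#'   `chrom`, `pos` (1-based), `pos0` (0-based internal), `ref`, `alt`,
#'   `type` (`SNP`/`insertion`/`deletion`).
#' @export
read_vcf <- function(path, ref = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bad <- is.na(fix$REF) | is.na(fix$ALT) | fix$REF == "" | fix$ALT == "" |
    fix$REF == "." | fix$ALT == "."
  if (any(bad))
    warning(sum(bad), " record(s) with missing REF/ALT skipped")
  fix <- fix[!bad, , drop = FALSE]
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  norm <- normalize_alleles(df$pos, df$ref, df$alt, df$chrom, ref)
  df$pos <- norm$pos
  df$ref <- norm$ref
  df$alt <- norm$alt
  make_variant_records(df$chrom, df$pos, df$ref, df$alt)
}

make_variant_records <- function(chrom, pos, ref, alt, snp_id = NULL) {
  type <- ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNP",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  if (is.null(snp_id)) snp_id <- paste0("S", chrom, "_", pos)
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                   pos0 = as.integer(pos) - 1L, ref = toupper(ref),
                   alt = toupper(alt), type = type, stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("variant with ref == alt")
  class(df) <- c("variant_records", "data.frame")
  df
}

# minimal representation + optional left shift against reference fragments
normalize_alleles <- function(pos, ref_al, alt_al, chrom, ref_tab = NULL) {
  for (i in seq_along(pos)) {
    r <- ref_al[i]; a <- alt_al[i]
    # trim common suffix (keep >= 1 base each)
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix (keep anchor base for indels)
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    if (!is.null(ref_tab) && nchar(r) != nchar(a)) {
      # left-shift while the base entering on the left equals the base
      # leaving on the right of the longer allele
      repeat {
        prev <- tryCatch(
          ref_seq(ref_tab, chrom[i], pos[i] - 2L, pos[i] - 1L),
          error = function(e) NULL)
        if (is.null(prev) || !nzchar(prev)) break
        long <- if (nchar(r) > nchar(a)) r else a
        if (substr(long, nchar(long), nchar(long)) !=
            substr(long, 1L, 1L) || prev != substr(long, 1L, 1L)) break
        shift1 <- function(x) paste0(prev, substr(x, 1L, nchar(x) - 1L))
        r <- shift1(r); a <- shift1(a); pos[i] <- pos[i] - 1L
      }
    }
    ref_al[i] <- r; alt_al[i] <- a
  }
  list(pos = pos, ref = ref_al, alt = alt_al)
}

#' Write variants to a minimal VCF 4.2 file
#'
#' @param variants `variant_records` data frame.
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(paste(variants$chrom, variants$pos, variants$snp_id,
                   variants$ref, variants$alt, ".", "PASS", ".", sep = "\t"),
             con)
  invisible(path)
}
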