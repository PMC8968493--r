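# Delimited-text readers/writers for genotypes, phenotypes, genetic maps,
# expression tables and reference-sequence fragment tables.  TSV is the
# default dialect throughout.  All readers pair with a writer such that
# write -> read -> write is a fixed point on valid files.

#' Read a genotype matrix
#'
#' Reads a delimited text file with a header row of marker ids, one row per
#' line (first column = line id).  Cells may be letter-coded
#' (`A`/`H`/`B`/`NA`, parental-origin) or dosage-coded (`0`/`1`/`2`/`NA`).
#' Output is an integer dosage matrix with `A -> 0`, `H -> 1`, `B -> 2`,
#' missing -> `NA`.
#'
#' @param path Path to the genotype file.
#' @param parent_a_label,parent_b_label Labels of the two parents (stored as
#'   attributes; parent A carries dosage 0, parent B dosage 2).
#' @param map Optional genetic map; markers absent from the map are dropped
#'   with a warning and listed in the `excluded_markers` attribute.
#' @param sep Field separator (default tab).
#' @return Integer matrix (lines x markers) with `line_id` rownames, marker
#'   colnames, and attributes `parent_a`, `parent_b`, `excluded_markers`.
#' @export
read_genotypes <- function(path, parent_a_label = "A", parent_b_label = "B",
                           map = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE)
  line_ids <- raw[[1L]]
  if (anyDuplicated(line_ids)) {
    dup <- unique(line_ids[duplicated(line_ids)])
    stop("duplicated line id(s) in '", path, "': ", paste(dup, collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  dos <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = list(line_ids, colnames(cells)))
  dos[cells == "A" | cells == "0"] <- 0L
  dos[cells == "H" | cells == "1"] <- 1L
  dos[cells == "B" | cells == "2"] <- 2L
  bad <- !is.na(cells) & is.na(dos)
  if (any(bad))
    stop("unrecognized genotype cell value(s): ",
         paste(utils::head(unique(cells[bad]), 5), collapse = ", "))
  excluded <- character(0)
  if (!is.null(map)) {
    excluded <- setdiff(colnames(dos), map$marker)
    if (length(excluded)) {
      warning(length(excluded), " marker(s) absent from the genetic map were excluded")
      dos <- dos[, setdiff(colnames(dos), excluded), drop = FALSE]
    }
  }
  structure(dos, parent_a = parent_a_label, parent_b = parent_b_label,
            excluded_markers = excluded)
}

#' Write a genotype matrix
#'
#' Letter-codes dosages (`0 -> A`, `1 -> H`, `2 -> B`, `NA -> NA`) so that
#' [read_genotypes()] round-trips the matrix exactly.
#'
#' @param genotypes Integer dosage matrix as returned by [read_genotypes()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_genotypes <- function(genotypes, path, sep = "\t") {
  codes <- matrix(c("A", "H", "B")[genotypes + 1L], nrow(genotypes),
                  dimnames = dimnames(genotypes))
  df <- data.frame(line_id = rownames(genotypes), codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a genetic map
#'
#' Columns: `marker`, `chrom`, `pos_cM`, optional `pos_bp`.  Marker ids must
#' be unique genome-wide; rows are sorted by chromosome then cM.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame with class `genetic_map`.
#' @export
read_genetic_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos_cM") %in% names(df)))
    stop("genetic map must have columns marker, chrom, pos_cM")
  if (!("pos_bp" %in% names(df))) df$pos_bp <- NA_real_
  df$chrom <- as.character(df$chrom)
  validate_genetic_map(df)
}

validate_genetic_map <- function(df) {
  if (anyDuplicated(df$marker))
    stop("duplicated marker id(s) in genetic map: ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  if (any(df$pos_cM < 0)) stop("negative cM positions in genetic map")
  df <- df[order(df$chrom, df$pos_cM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @rdname read_genetic_map
#' @param map Genetic map data frame.
#' @export
write_genetic_map <- function(map, path, sep = "\t") {
  utils::write.table(map[, c("marker", "chrom", "pos_cM", "pos_bp")], path,
                     sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Long-format records `(line, trait, environment, replicate, value)`.
#' Keys must be unique; missing values are kept as `NA`, never dropped.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame with class `phenotype_table`.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA")
  validate_phenotypes(df)
}

validate_phenotypes <- function(df) {
  need <- c("line", "trait", "environment", "replicate", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "))
  key <- do.call(paste, c(df[c("line", "trait", "environment", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicated (line, trait, environment, replicate) key(s) in phenotypes")
  if (any(!is.na(df$value) & !is.finite(df$value)))
    stop("non-finite phenotype values must be coded NA")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype table.
#' @export
write_phenotypes <- function(phenotypes, path, sep = "\t") {
  utils::write.table(
    phenotypes[, c("line", "trait", "environment", "replicate", "value")],
    path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Line means of one trait in one environment
#'
#' Arithmetic mean over replicates within an environment (the least-squares
#' mean surrogate used as the scan phenotype).  Missing replicates are
#' dropped pairwise; lines with no observation get `NA`.
#'
#' @param phenotypes Phenotype table.
#' @param trait,environment Trait and environment to select.
#' @param lines Optional character vector fixing the output order.
#' @return Named numeric vector of line means.
#' @export
line_means <- function(phenotypes, trait, environment, lines = NULL) {
  sel <- phenotypes$trait == trait & phenotypes$environment == environment
  sub <- phenotypes[sel, , drop = FALSE]
  if (!nrow(sub)) stop("no records for trait '", trait, "' in environment '",
                       environment, "'")
  mns <- tapply(sub$value, sub$line, mean, na.rm = TRUE)
  mns[is.nan(mns)] <- NA_real_
  if (!is.null(lines)) mns <- mns[lines]
  out <- as.numeric(mns)
  names(out) <- if (is.null(lines)) names(mns) else lines
  out
}

#' Read / write an expression table
#'
#' Long format: `gene_id`, `stage`, `genotype`, `replicate`, `fpkm`
#' (non-negative).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame of expression records.
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "stage", "genotype", "replicate", "fpkm")
  if (!all(need %in% names(df)))
    stop("expression table must have columns ", paste(need, collapse = ", "))
  if (any(df$fpkm < 0, na.rm = TRUE)) stop("negative FPKM values")
  df
}

#' @rdname read_expression
#' @param expression Expression table.
#' @export
write_expression <- function(expression, path, sep = "\t") {
  utils::write.table(
    expression[, c("gene_id", "stage", "genotype", "replicate", "fpkm")],
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference-sequence fragment table
#'
#' Sparse reference representation: one row per contiguous fragment with
#' `chrom`, `start0` (0-based) and `seq` (uppercase ACGT).  Sequence lookups
#' outside any fragment are an error, which keeps accidental use of
#' unmodelled sequence loud.
#'
#' @param path File path.
#' @return Data frame with class `ref_fragments`.
#' @export
read_ref_fragments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "start0", "seq") %in% names(df)))
    stop("reference fragment table must have columns chrom, start0, seq")
  class(df) <- c("ref_fragments", "data.frame")
  df
}

#' @rdname read_ref_fragments
#' @param ref Fragment table.
#' @export
write_ref_fragments <- function(ref, path) {
  utils::write.table(as.data.frame(ref)[, c("chrom", "start0", "seq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract reference sequence from a fragment table
#'
#' @param ref Fragment table.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open span.
#' @return Character scalar of length `end0 - start0`.
#' @export
ref_seq <- function(ref, chrom, start0, end0) {
  hits <- ref$chrom == chrom & ref$start0 <= start0 &
    (ref$start0 + nchar(ref$seq)) >= end0
  if (!any(hits))
    stop("no reference fragment covers ", chrom, ":", start0, "-", end0)
  fr <- ref[which(hits)[1L], ]
  substr(fr$seq, start0 - fr$start0 + 1L, end0 - fr$start0)
}

#' Read / write a structured YAML configuration
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records input paths, the seed, and a hash of the parameter list so that
#' permutation-based results can be replayed exactly.
#'
#' @param path Output YAML path.
#' @param inputs Named list/character vector of input file paths.
#' @param seed Integer seed used for the run.
#' @param params Named list of parameters.
#' @export
write_run_manifest <- function(path, inputs, seed, params = list()) {
  manifest <- list(
    inputs = as.list(inputs),
    seed = seed,
    parameter_hash = param_hash(params),
    parameters = params
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}

param_hash <- function(params) {
  prm <- if (length(params)) params[order(names(params))] else params
  txt <- paste(deparse(prm), collapse = "")
  # small polynomial rolling hash; stable across sessions, no extra deps
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Chromosome-name alias resolution
#'
#' Chromosome matching is exact string match; an alias table maps between
#' dialects such as `"chr3"` and `"3"`.
#'
#' @param x Character vector of chromosome names.
#' @param aliases Named character vector, `names(aliases)` mapped to values.
#' @return Character vector with aliases applied.
#' @export
resolve_chrom_alias <- function(x, aliases = NULL) {
  if (is.null(aliases)) return(x)
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}
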