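# Small in-code fixtures shared across tests.

tiny_map <- function(markers, chrom = "chr1", pos_cM = NULL, bp_per_cM = 1e5) {
  if (is.null(pos_cM)) pos_cM <- seq(0, by = 10, length.out = length(markers))
  data.frame(marker = markers, chrom = chrom, pos_cM = pos_cM,
             pos_bp = pos_cM * bp_per_cM + 1, stringsAsFactors = FALSE)
}

tiny_geno <- function(mat, lines = NULL, markers = NULL) {
  m <- as.matrix(mat)
  rownames(m) <- lines %||% sprintf("L%02d", seq_len(nrow(m)))
  colnames(m) <- markers %||% sprintf("M%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one synthetic study dataset reused by several prioritization tests
cached_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_lines = 200, chr_lengths_cM = rep(100, 2),
                        marker_spacing_cM = 2,
                        traits = list(sim_trait("EtE", h2 = 0.6,
                          qtls = list(qtl_spec(1, 50, pvar = 0.2)))),
                        seed = 4242)
      cache <<- simulate_qtl_study(cfg, n_genes_per_cM = 0.5)
    }
    cache
  }
})
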