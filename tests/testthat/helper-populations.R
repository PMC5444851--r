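# Shared fixture builders. Populations are simulated once per test run and
# cached, since several files reuse the same preset populations.

.pop_cache <- new.env(parent = emptyenv())

simulate_called_pop <- function(type, n, seed, label = type, ...) {
  sc <- scenario_preset(type, n_progeny = n, seed = seed, ...)
  sim <- simulate_population(sc)
  gmap <- build_genetic_map(sim$genotypes)
  list(sim = sim,
       pop = call_crossovers(sim$genotypes, genetic_map = gmap,
                             label = label))
}

cached_pop <- function(key, type, n, seed, ...) {
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- simulate_called_pop(type, n, seed, ...)
  .pop_cache[[key]]
}

# a tiny hand-built genotype matrix: one row per marker, alleles given as
# strings like "AABB" (one character per progeny)
toy_genotypes <- function(rows, chrom = "A01",
                          pos_bp = NULL, pos_cM = NULL) {
  nm <- length(rows)
  if (is.null(pos_bp)) pos_bp <- seq(1e6, by = 1e6, length.out = nm)
  map_df <- data.frame(marker_id = sprintf("M%02d", seq_len(nm)),
                       chrom = chrom, pos_bp = pos_bp,
                       stringsAsFactors = FALSE)
  if (!is.null(pos_cM)) map_df$pos_cM <- pos_cM
  geno <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(geno) <- map_df$marker_id
  genotype_matrix(geno, marker_map(map_df))
}
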