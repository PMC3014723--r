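# Independent oracles and small fixture builders, kept deliberately separate
# from the implementation paths they check.

# A tiny edge-free tray: C complete cells covering the whole arena.
tiny_geometry <- function(C) {
  tray_geometry(inner_diameter = 2.5, cell_side = 1,
                n_complete_cells = C, equivalent_cells = C)
}

# Build a sample_realization by hand from a regions x taxa count matrix.
make_sample <- function(cell_counts, large_counts = NULL, geometry,
                        p_detect_cell = 1, p_detect_scan = 0.5) {
  ids <- colnames(cell_counts)
  if (is.null(large_counts))
    large_counts <- stats::setNames(integer(length(ids)), ids)
  taxa <- taxa_spec(ids, relative_abundance = 1,
                    p_detect_cell = p_detect_cell,
                    p_detect_scan = p_detect_scan)
  structure(list(cell_counts = cell_counts, large_counts = large_counts,
                 true_total = sum(cell_counts) + sum(large_counts),
                 true_phase2_total = sum(cell_counts),
                 true_taxa = ids[colSums(cell_counts) + large_counts > 0],
                 taxa = taxa, geometry = geometry, preset = "fixture"),
            class = "sample_realization")
}

# Exact probability that a taxon with m individuals, placed independently and
# uniformly into C equal cells (no edge), is seen at least once when k cells
# are drawn without replacement and each individual in a drawn cell is seen
# with probability p. Brute force: enumerate all C^m placements and all
# choose(C, k) selections.
oracle_detect_prob <- function(m, C, k, p = 1) {
  placements <- as.matrix(expand.grid(rep(list(seq_len(C)), m)))
  selections <- utils::combn(C, k)
  p_miss <- 0
  for (i in seq_len(nrow(placements))) {
    counts <- tabulate(placements[i, ], nbins = C)
    miss_given_sel <- apply(selections, 2,
                            function(sel) (1 - p)^sum(counts[sel]))
    p_miss <- p_miss + mean(miss_given_sel)
  }
  1 - p_miss / nrow(placements)
}

# Exact probability that the whole three-phase protocol misses a taxon of m
# uniformly placed individuals (no large pool): phase 2 must see none of
# them, then the scan of the 'remaining' m individuals must also fail.
oracle_miss_prob <- function(m, C, k, p, q) {
  (1 - oracle_detect_prob(m, C, k, p)) * (1 - q)^m
}

# Monte-Carlo standard deviation for an estimated proportion.
mc_sd <- function(p_hat, n) sqrt(p_hat * (1 - p_hat) / n)

preset_names <- c("pan_low", "pan_moderate", "pan_high",
                  "pitfall_low", "pitfall_moderate", "pitfall_high")

# Field mean taxa richness per preset: calibration targets of the generator.
richness_targets <- c(pan_low = 13.6, pan_moderate = 15.5, pan_high = 18.7,
                      pitfall_low = 15.4, pitfall_moderate = 18.6,
                      pitfall_high = 23.7)
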