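#' Phase 1: large-specimen separation
#'
#' Returns the sample's 4 mm-sieve pool per taxon. The phase is treated as
#' lossless: retained large specimens are counted and identified in full.
#'
#' @param sample A [simulate_sample()] realization.
#' @return Named integer vector of large-specimen counts per taxon.
#' @export
phase1_sieve <- function(sample) {
  stopifnot(inherits(sample, "sample_realization"))
  sample$large_counts
}

#' Phase 2: count k randomly selected complete cells
#'
#' Selects `k` distinct complete cells uniformly without replacement (the
#' pooled edge region is never selectable) and records what a technician
#' would see: each individual in a selected cell is observed independently
#' with its taxon's `p_detect_cell`. The selection order is kept so that
#' results for any smaller number of cells are the nested prefix.
#'
#' @param sample A [simulate_sample()] realization.
#' @param k Number of cells to count, between 1 and the number of complete
#'   cells.
#' @param p_detect_cell Optional per-taxon override of the detection
#'   probabilities in the sample's taxa table (recycled).
#' @return An object of class `"subsample_result"`: list with
#'   `selected_cells` (ordered indices), `observed_counts` (`k` x taxa
#'   integer matrix) and `k`.
#' @export
phase2_subsample <- function(sample, k, p_detect_cell = NULL) {
  stopifnot(inherits(sample, "sample_realization"))
  C <- sample$geometry$n_complete_cells
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > C)
    stop(sprintf("'k' must be an integer in [1, %d]", C), call. = FALSE)
  k <- as.integer(k)
  p <- if (is.null(p_detect_cell)) sample$taxa$p_detect_cell else
    rep_len(p_detect_cell, nrow(sample$taxa))
  cells <- sample.int(C, k)
  truth <- sample$cell_counts[cells, , drop = FALSE]
  obs <- matrix(stats::rbinom(length(truth), as.vector(truth),
                              rep(p, each = k)),
                nrow = k, dimnames = dimnames(truth))
  structure(list(selected_cells = cells,
                 observed_counts = obs,
                 k = k),
            class = "subsample_result")
}

#' Phase 3: quick scan of the remainder for missed taxa
#'
#' For each taxon not yet detected in phases 1 and 2, the scan succeeds with
#' probability `1 - (1 - p_detect_scan)^m`, where `m` is the number of that
#' taxon's individuals still on the plate: everything outside the counted
#' cells plus individuals that were present in a counted cell but missed
#' (a missed specimen is still physically in the tray). The scan records
#' presence only; it never contributes to abundance.
#'
#' @param sample A [simulate_sample()] realization.
#' @param detected_so_far Character vector of taxa already detected in
#'   phases 1-2.
#' @param subsample The phase-2 [phase2_subsample()] result.
#' @param p_detect_scan Optional per-taxon override (recycled).
#' @return Character vector of taxa newly detected by the scan (disjoint
#'   from `detected_so_far`).
#' @export
phase3_scan <- function(sample, detected_so_far, subsample,
                        p_detect_scan = NULL) {
  stopifnot(inherits(sample, "sample_realization"),
            inherits(subsample, "subsample_result"))
  q <- if (is.null(p_detect_scan)) sample$taxa$p_detect_scan else
    rep_len(p_detect_scan, nrow(sample$taxa))
  on_tray <- colSums(sample$cell_counts)
  remaining <- on_tray - colSums(subsample$observed_counts)
  ids <- sample$taxa$taxon_id
  candidate <- !(ids %in% detected_so_far) & remaining > 0
  p_hit <- 1 - (1 - q)^remaining
  hit <- candidate & stats::runif(length(ids)) < p_hit
  ids[hit]
}

#' Run the three-phase subsampling protocol on one sample
#'
#' Composes the 4 mm-sieve separation, the counting of `k` randomly selected
#' cells, and the quick scan, producing exactly what a technician's tally
#' sheet would hold. Setting `perfect_detection = TRUE` makes every
#' individual in a counted cell visible and the scan exhaustive (all
#' in-cell detection probabilities 1, scan probability 1), which is the
#' idealized-protocol reference.
#'
#' @param sample A [simulate_sample()] realization.
#' @param k Number of cells to count (default 16, the standard protocol).
#' @param p_detect_cell,p_detect_scan Optional per-taxon overrides.
#' @param perfect_detection If `TRUE`, overrides both detection stages to 1.
#' @return An object of class `"protocol_result"`: `large_counts`,
#'   `subsample` (a `subsample_result`), `scan_taxa`, `k_used`, plus the
#'   sample's `geometry`, taxa labels and — when simulated — the ground
#'   truth (`true_total`, `true_phase2_total`, `true_taxa`) for scoring.
#' @examples
#' set.seed(42)
#' s <- simulate_sample(community_preset("pitfall_moderate"))
#' run_protocol(s, k = 16)
#' @export
run_protocol <- function(sample, k = 16, p_detect_cell = NULL,
                         p_detect_scan = NULL, perfect_detection = FALSE) {
  stopifnot(inherits(sample, "sample_realization"))
  if (perfect_detection) {
    p_detect_cell <- 1
    p_detect_scan <- 1
  }
  large <- phase1_sieve(sample)
  sub <- phase2_subsample(sample, k, p_detect_cell)
  seen12 <- union(names(large)[large > 0],
                  colnames(sub$observed_counts)[colSums(sub$observed_counts) > 0])
  scan <- phase3_scan(sample, seen12, sub, p_detect_scan)
  protocol_result(large_counts = large, subsample = sub, scan_taxa = scan,
                  geometry = sample$geometry,
                  true_total = sample$true_total,
                  true_phase2_total = sample$true_phase2_total,
                  true_taxa = sample$true_taxa)
}

#' Assemble a protocol result
#'
#' Low-level constructor used both by [run_protocol()] and by the tally-sheet
#' reader (real-data mode, where no ground truth exists and the truth fields
#' stay `NA`).
#'
#' @param large_counts Named integer vector (phase 1).
#' @param subsample A `subsample_result` (phase 2).
#' @param scan_taxa Character vector of phase-3 detections; must be disjoint
#'   from taxa seen in phases 1-2.
#' @param geometry A [tray_geometry()].
#' @param true_total,true_phase2_total,true_taxa Ground truth when known.
#' @param sample_id Optional identifier carried from tally sheets.
#' @return An object of class `"protocol_result"`.
#' @export
protocol_result <- function(large_counts, subsample, scan_taxa = character(),
                            geometry = tray_geometry(), true_total = NA,
                            true_phase2_total = NA, true_taxa = NULL,
                            sample_id = NA_character_) {
  stopifnot(inherits(subsample, "subsample_result"),
            inherits(geometry, "tray_geometry"))
  if (anyDuplicated(subsample$selected_cells))
    stop("selected cells must be distinct", call. = FALSE)
  seen12 <- union(names(large_counts)[large_counts > 0],
                  colnames(subsample$observed_counts)[
                    colSums(subsample$observed_counts) > 0])
  if (length(intersect(scan_taxa, seen12)))
    stop("scan taxa must be disjoint from taxa detected in phases 1-2",
         call. = FALSE)
  structure(list(large_counts = large_counts, subsample = subsample,
                 scan_taxa = scan_taxa, k_used = subsample$k,
                 geometry = geometry, true_total = true_total,
                 true_phase2_total = true_phase2_total,
                 true_taxa = true_taxa, sample_id = sample_id),
            class = "protocol_result")
}

#' Taxa detected by a protocol result, by phase or overall
#'
#' @param result A [protocol_result()].
#' @param phase `"all"` (union over the three phases) or 1, 2, 3.
#' @return Character vector of taxon labels.
#' @export
detected_taxa <- function(result, phase = "all") {
  stopifnot(inherits(result, "protocol_result"))
  p1 <- names(result$large_counts)[result$large_counts > 0]
  obs <- result$subsample$observed_counts
  p2 <- colnames(obs)[colSums(obs) > 0]
  switch(as.character(phase),
         "1" = p1, "2" = p2, "3" = result$scan_taxa,
         all = union(union(p1, p2), result$scan_taxa),
         stop("'phase' must be 1, 2, 3 or \"all\"", call. = FALSE))
}

#' @export
print.protocol_result <- function(x, ...) {
  obs <- x$subsample$observed_counts
  cat(sprintf("Three-phase protocol result%s\n",
              if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]") else ""))
  cat(sprintf("  phase 1: %d large specimens (%d taxa)\n",
              sum(x$large_counts), sum(x$large_counts > 0)))
  cat(sprintf("  phase 2: %d cells counted, %d individuals (%d taxa)\n",
              x$k_used, sum(obs), sum(colSums(obs) > 0)))
  cat(sprintf("  phase 3: %d additional taxa in the quick scan\n",
              length(x$scan_taxa)))
  cat(sprintf("  taxa richness (all phases): %d\n", taxa_richness(x)))
  invisible(x)
}
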