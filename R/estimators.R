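#' Phase-2 extrapolation estimate
#'
#' The plug-in fixed-area estimator: the average number of individuals per
#' counted cell times the tray's cell-equivalent count (63.6 for the
#' standard apparatus).
#'
#' @param observed_counts Integer matrix (cells x taxa) or vector of
#'   per-cell totals from the counted cells.
#' @param k Number of cells counted (at least 1).
#' @param equivalent_cells The tray multiplier.
#' @return List with `mean_per_cell` and `phase2_estimate`.
#' @export
estimate_phase2 <- function(observed_counts, k, equivalent_cells = 63.6) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(observed_counts), all(observed_counts >= 0))
  mean_per_cell <- sum(observed_counts) / k
  list(mean_per_cell = mean_per_cell,
       phase2_estimate = mean_per_cell * equivalent_cells)
}

#' Abundance estimate from a protocol result
#'
#' Applies [estimate_phase2()] to the first `k` counted cells (the nested
#' prefix of the recorded selection order) and adds the phase-1 large count
#' to give the whole-sample estimate.
#'
#' @param result A [protocol_result()].
#' @param k Number of cells to use, up to `result$k_used`.
#' @return An object of class `"abundance_estimate"` with fields
#'   `mean_per_cell`, `phase2_estimate`, `large_count`, `total_estimate`,
#'   `k_used` and `equivalent_cells`.
#' @examples
#' set.seed(7)
#' s <- simulate_sample(community_preset("pan_high"))
#' estimate_abundance(run_protocol(s, k = 16))
#' @export
estimate_abundance <- function(result, k = result$k_used) {
  stopifnot(inherits(result, "protocol_result"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > result$k_used)
    stop(sprintf("'k' must be in [1, %d] (cells actually counted)",
                 result$k_used), call. = FALSE)
  obs <- result$subsample$observed_counts[seq_len(k), , drop = FALSE]
  ph2 <- estimate_phase2(obs, k, result$geometry$equivalent_cells)
  large <- sum(result$large_counts)
  structure(list(mean_per_cell = ph2$mean_per_cell,
                 phase2_estimate = ph2$phase2_estimate,
                 large_count = large,
                 total_estimate = ph2$phase2_estimate + large,
                 k_used = as.integer(k),
                 equivalent_cells = result$geometry$equivalent_cells,
                 sample_id = result$sample_id),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance estimate from %d cells:\n", x$k_used))
  cat(sprintf("  mean per cell   : %.2f\n", x$mean_per_cell))
  cat(sprintf("  phase-2 estimate: %.1f (x %.1f cell-equivalents)\n",
              x$phase2_estimate, x$equivalent_cells))
  cat(sprintf("  + large pool    : %d\n", x$large_count))
  cat(sprintf("  total estimate  : %.1f\n", x$total_estimate))
  invisible(x)
}

#' Percent accuracy of a phase-2 estimate
#'
#' 100 times the extrapolated phase-2 estimate divided by the true number of
#' individuals in the subsampled portion (the sample total minus the large
#' pool removed in phase 1). Values under 100 are underestimates, values
#' over 100 overestimates.
#'
#' @param phase2_estimate Non-negative estimate(s).
#' @param true_phase2_total Positive true total(s) of the tray portion.
#' @return Percent accuracy, same length as the inputs.
#' @export
percent_accuracy <- function(phase2_estimate, true_phase2_total) {
  stopifnot(is.numeric(phase2_estimate), is.numeric(true_phase2_total))
  if (any(true_phase2_total <= 0))
    stop("percent accuracy is undefined for empty subsampled portions; ",
         "filter samples with no phase-2 individuals", call. = FALSE)
  100 * phase2_estimate / true_phase2_total
}

#' Taxa richness across the three phases
#'
#' The number of distinct taxa detected in any phase: large-specimen
#' separation, the counted cells, and the quick scan.
#'
#' @param result A [protocol_result()].
#' @return Integer richness.
#' @export
taxa_richness <- function(result) {
  length(detected_taxa(result, "all"))
}

#' Percent of true taxa richness detected
#'
#' @param detected Number of taxa detected (0 to `true_richness`).
#' @param true_richness Positive true number of taxa in the sample.
#' @return `100 * detected / true_richness`.
#' @export
percent_richness <- function(detected, true_richness) {
  stopifnot(is.numeric(detected), is.numeric(true_richness))
  if (any(true_richness <= 0))
    stop("percent richness is undefined when the true richness is zero",
         call. = FALSE)
  if (any(detected < 0) || any(detected > true_richness))
    stop("'detected' must lie between 0 and 'true_richness'", call. = FALSE)
  100 * detected / true_richness
}

#' Classify a sample by overall abundance
#'
#' Low abundance: fewer than 250 individuals; moderate: 250 to 500
#' inclusive; high: more than 500.
#'
#' @param true_total Non-negative sample total(s).
#' @return Factor with levels `low`, `moderate`, `high`.
#' @examples
#' classify_abundance(c(249, 250, 500, 501))
#' @export
classify_abundance <- function(true_total) {
  stopifnot(is.numeric(true_total))
  if (any(true_total < 0))
    stop("'true_total' must be non-negative", call. = FALSE)
  factor(ifelse(true_total < 250, "low",
                ifelse(true_total <= 500, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

#' Full-count decision rule after 10 cells
#'
#' After counting 10 cells, if the average number of individuals per cell is
#' below 4 the sample is too sparse for reliable extrapolation and a
#' complete count is recommended; at 4 or more per cell, estimation
#' proceeds. The threshold corresponds to roughly 250 individuals on the
#' tray (4 x 63.6).
#'
#' @param mean_per_cell Average individuals per cell computed from exactly
#'   10 counted cells.
#' @return Logical: `TRUE` when a full count is recommended.
#' @examples
#' recommend_full_count(c(3.9, 4.0))
#' @export
recommend_full_count <- function(mean_per_cell) {
  stopifnot(is.numeric(mean_per_cell), all(mean_per_cell >= 0))
  mean_per_cell < 4
}
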