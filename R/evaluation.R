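# Evaluate one simulated sample: nested-prefix accuracy and richness curves.
.evaluate_one <- function(config, geometry, k_max, perfect_detection,
                          scan_at = k_max) {
  s <- simulate_sample(config, geometry)
  res <- run_protocol(s, k = k_max, perfect_detection = perfect_detection)
  obs <- res$subsample$observed_counts
  ks <- seq_len(k_max)

  acc <- rep(NA_real_, k_max)
  empty <- s$true_phase2_total == 0
  if (!empty) {
    cum <- cumsum(rowSums(obs))
    acc <- percent_accuracy((cum / ks) * geometry$equivalent_cells,
                            s$true_phase2_total)
  }

  true_rich <- length(s$true_taxa)
  p1 <- names(s$large_counts)[s$large_counts > 0]
  # first counted cell (in selection order) in which each taxon was seen
  first_seen <- apply(obs > 0, 2, function(v) if (any(v)) which(v)[1] else Inf)
  n_new <- tabulate(first_seen[is.finite(first_seen) &
                                 !(names(first_seen) %in% p1)],
                    nbins = k_max)
  detected_k <- length(p1) + cumsum(n_new)
  rich_pct <- 100 * detected_k / true_rich
  rich_final <- detected_k[k_max] + length(res$scan_taxa)

  present <- s$true_taxa
  missed <- setdiff(present, detected_taxa(res, "all"))

  list(category = as.character(classify_abundance(s$true_total)),
       empty = empty, acc = acc, rich_pct = rich_pct,
       rich_final_pct = 100 * rich_final / true_rich,
       scan_gain = length(res$scan_taxa),
       present = present, missed = missed)
}

.ci <- function(m, se) c(lo = m - 1.96 * se, hi = m + 1.96 * se)

#' Monte-Carlo evaluation of the subsampling design
#'
#' Simulates `n_reps` samples per preset, runs the three-phase protocol with
#' one ordered `k_max`-cell selection per sample, and evaluates the
#' abundance estimator on every nested prefix `k = 1..k_max`, giving percent
#' accuracy and cumulative percent taxa richness as functions of the number
#' of subsamples, with normal-approximation 95% confidence intervals
#' (mean +/- 1.96 SE) per preset, abundance category and `k`. The quick-scan
#' richness increment is evaluated at `k_max`, and per-taxon miss
#' frequencies (fraction of samples containing a taxon in which all three
#' phases failed to detect it) are tabulated.
#'
#' @param presets Character vector of [community_preset()] names.
#' @param n_reps Simulated samples per preset (at least 2).
#' @param k_max Cells counted per sample (curves run over `1..k_max`).
#' @param seed Optional integer seed for exact reproducibility.
#' @param geometry A [tray_geometry()].
#' @param perfect_detection If `TRUE`, the idealized protocol: every
#'   individual in a counted cell is seen and the scan misses nothing.
#' @param clustering_theta Optional override of each preset's spatial
#'   clustering (finite values clump individuals; default uniform).
#' @param keep_samples If `TRUE`, the per-sample accuracy and richness
#'   curves are returned in `samples` (one `n_reps` x `k_max` matrix pair
#'   per preset), enabling paired statistics such as marginal richness
#'   gains.
#' @return An object of class `"subsample_eval"`: list with `summary` (one
#'   row per preset x category x k: accuracy and richness means, SEs and CI
#'   bounds), `final` (richness including the scan at `k_max`), `miss`
#'   (per-taxon miss frequencies), `diagnostics` (samples excluded for an
#'   empty subsampled portion) and the call settings.
#' @examples
#' ev <- evaluate_design("pan_high", n_reps = 50, seed = 1)
#' head(summary(ev))
#' @export
evaluate_design <- function(presets = c("pan_low", "pan_moderate", "pan_high",
                                        "pitfall_low", "pitfall_moderate",
                                        "pitfall_high"),
                            n_reps = 1000, k_max = 16, seed = NULL,
                            geometry = tray_geometry(),
                            perfect_detection = FALSE,
                            clustering_theta = NULL, keep_samples = FALSE) {
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("'n_reps' must be at least 2", call. = FALSE)
  if (k_max < 1 || k_max > geometry$n_complete_cells)
    stop("'k_max' must be between 1 and the number of complete cells",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  summ <- list(); fin <- list(); miss <- list(); diag <- list()
  kept <- list()
  for (pr in presets) {
    config <- if (is.null(clustering_theta)) community_preset(pr) else
      community_preset(pr, clustering_theta = clustering_theta)
    S <- nrow(config$taxa)
    ids <- config$taxa$taxon_id
    acc <- matrix(NA_real_, n_reps, k_max)
    rich <- matrix(NA_real_, n_reps, k_max)
    cat_lab <- character(n_reps)
    rich_final <- numeric(n_reps); scan_gain <- numeric(n_reps)
    n_present <- n_missed <- stats::setNames(numeric(S), ids)
    n_empty <- 0L
    for (i in seq_len(n_reps)) {
      r <- .evaluate_one(config, geometry, k_max, perfect_detection)
      acc[i, ] <- r$acc
      rich[i, ] <- r$rich_pct
      cat_lab[i] <- r$category
      rich_final[i] <- r$rich_final_pct
      scan_gain[i] <- r$scan_gain
      n_present[r$present] <- n_present[r$present] + 1
      n_missed[r$missed] <- n_missed[r$missed] + 1
      if (r$empty) n_empty <- n_empty + 1L
    }
    for (ct in unique(cat_lab)) {
      sel <- cat_lab == ct
      for (k in seq_len(k_max)) {
        a <- acc[sel, k]; a <- a[!is.na(a)]
        rch <- rich[sel, k]
        am <- mean(a); ase <- stats::sd(a) / sqrt(length(a))
        rm_ <- mean(rch); rse <- stats::sd(rch) / sqrt(length(rch))
        summ[[length(summ) + 1L]] <- data.frame(
          preset = pr, category = ct, k = k, n = length(a),
          accuracy = am, accuracy_se = ase,
          accuracy_lo = am - 1.96 * ase, accuracy_hi = am + 1.96 * ase,
          richness_pct = rm_, richness_se = rse,
          richness_lo = rm_ - 1.96 * rse, richness_hi = rm_ + 1.96 * rse,
          stringsAsFactors = FALSE)
      }
      fm <- mean(rich_final[sel])
      fse <- stats::sd(rich_final[sel]) / sqrt(sum(sel))
      fin[[length(fin) + 1L]] <- data.frame(
        preset = pr, category = ct, k = k_max, n = sum(sel),
        richness_pct_with_scan = fm, se = fse,
        lo = fm - 1.96 * fse, hi = fm + 1.96 * fse,
        scan_gain_taxa = mean(scan_gain[sel]), stringsAsFactors = FALSE)
    }
    miss[[length(miss) + 1L]] <- data.frame(
      preset = pr, taxon_id = ids, n_present = as.integer(n_present),
      n_missed = as.integer(n_missed),
      miss_rate = ifelse(n_present > 0, n_missed / n_present, NA_real_),
      stringsAsFactors = FALSE)
    diag[[length(diag) + 1L]] <- data.frame(
      preset = pr, n_reps = n_reps, n_empty_phase2 = n_empty,
      stringsAsFactors = FALSE)
    if (keep_samples)
      kept[[pr]] <- list(accuracy = acc, richness_pct = rich,
                         category = cat_lab)
  }
  structure(list(summary = do.call(rbind, summ),
                 final = do.call(rbind, fin),
                 miss = do.call(rbind, miss),
                 diagnostics = do.call(rbind, diag),
                 samples = if (keep_samples) kept,
                 n_reps = n_reps, k_max = k_max, seed = seed,
                 perfect_detection = perfect_detection),
            class = "subsample_eval")
}

#' @export
summary.subsample_eval <- function(object, ...) object$summary

#' @export
print.subsample_eval <- function(x, ...) {
  cat(sprintf(
    "Subsampling design evaluation: %d reps/preset, k = 1..%d%s\n",
    x$n_reps, x$k_max,
    if (x$perfect_detection) " (perfect detection)" else ""))
  at_k <- x$summary[x$summary$k == x$k_max, ]
  cat(sprintf("At k = %d cells:\n", x$k_max))
  for (i in seq_len(nrow(at_k))) {
    r <- at_k[i, ]
    cat(sprintf(
      "  %-17s (%s): accuracy %5.1f%% [%5.1f, %5.1f], richness %5.1f%%\n",
      r$preset, r$category, r$accuracy, r$accuracy_lo, r$accuracy_hi,
      r$richness_pct))
  }
  ex <- sum(x$diagnostics$n_empty_phase2)
  if (ex > 0)
    cat(sprintf("  (%d samples excluded from accuracy: empty tray portion)\n",
                ex))
  invisible(x)
}

#' Plot accuracy or richness against the number of subsamples
#'
#' One panel per preset: the Monte-Carlo mean with 95% confidence bars over
#' `k = 1..k_max`; the accuracy panels carry the 100% reference line.
#'
#' @param x A [evaluate_design()] result.
#' @param which `"accuracy"` or `"richness"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.subsample_eval <- function(x, which = c("accuracy", "richness"), ...) {
  which <- match.arg(which)
  s <- x$summary
  presets <- unique(s$preset)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(presets)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pr in presets) {
    d <- s[s$preset == pr, ]
    if (which == "accuracy") {
      y <- d$accuracy; lo <- d$accuracy_lo; hi <- d$accuracy_hi
      ylab <- "Percent accuracy"
    } else {
      y <- d$richness_pct; lo <- d$richness_lo; hi <- d$richness_hi
      ylab <- "Percent taxa richness"
    }
    graphics::plot(d$k, y, type = "b", pch = 19, main = pr,
                   xlab = "Number of subsamples", ylab = ylab,
                   ylim = range(lo, hi, if (which == "accuracy") 100), ...)
    graphics::arrows(d$k, lo, d$k, hi, angle = 90, code = 3,
                     length = 0.03)
    if (which == "accuracy") graphics::abline(h = 100)
  }
  invisible(x)
}

#' Do two 95% confidence intervals fail to overlap?
#'
#' Non-overlapping intervals are read as a statistically significant
#' difference between the means they bracket. Intervals sharing an endpoint
#' are treated as overlapping.
#'
#' @param a,b Length-2 numeric vectors `c(lower, upper)`.
#' @return `TRUE` iff the intervals are disjoint.
#' @examples
#' ci_nonoverlap(c(1, 2), c(3, 4))  # TRUE
#' ci_nonoverlap(c(1, 2), c(2, 3))  # FALSE: shared endpoint
#' @export
ci_nonoverlap <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 2L, is.numeric(b), length(b) == 2L,
            a[1] <= a[2], b[1] <= b[2])
  a[2] < b[1] || b[2] < a[1]
}
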