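# Tabular text I/O: tally sheets (what a technician records), ground-truth
# sample sheets, estimate tables, and the run-configuration file. All files
# are comma-separated UTF-8 with a header row; writers prepend '#' comment
# lines carrying the package version, the seed in force and an MD5 of the
# written payload (provenance), which readers skip.

.provenance_header <- function(df, seed = NA) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  md5 <- unname(tools::md5sum(tmp))
  sprintf("# traysub %s; seed=%s; payload_md5=%s",
          as.character(utils::packageVersion("traysub")),
          as.character(seed), md5)
}

.write_csv_prov <- function(df, path, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(df, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write protocol results as a tally sheet
#'
#' One row per record: `sample_id, phase, cell_index, taxon_id, count`.
#' Phase-1 rows hold large-specimen counts (no cell index); phase-2 rows
#' hold per-cell, per-taxon counts for the selected cells (a cell counted
#' but found empty is written with a blank taxon and count 0, so the number
#' of counted cells survives the round trip); phase-3 rows record presence
#' only (no count).
#'
#' @param results A [protocol_result()] or list of them.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header, if any.
#' @return The path, invisibly.
#' @export
write_tally_sheet <- function(results, path, seed = NA) {
  if (inherits(results, "protocol_result")) results <- list(results)
  rows <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    stopifnot(inherits(r, "protocol_result"))
    sid <- if (!is.na(r$sample_id)) r$sample_id else sprintf("S%03d", i)
    lg <- r$large_counts[r$large_counts > 0]
    if (length(lg))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, phase = 1L, cell_index = NA_integer_,
        taxon_id = names(lg), count = as.integer(lg))
    obs <- r$subsample$observed_counts
    for (j in seq_len(nrow(obs))) {
      ci <- r$subsample$selected_cells[j]
      pos <- obs[j, ] > 0
      rows[[length(rows) + 1L]] <- if (any(pos)) data.frame(
        sample_id = sid, phase = 2L, cell_index = ci,
        taxon_id = colnames(obs)[pos], count = as.integer(obs[j, pos]))
      else data.frame(sample_id = sid, phase = 2L, cell_index = ci,
                      taxon_id = NA_character_, count = 0L)
    }
    if (length(r$scan_taxa))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, phase = 3L, cell_index = NA_integer_,
        taxon_id = r$scan_taxa, count = NA_integer_)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), phase = integer(),
               cell_index = integer(), taxon_id = character(),
               count = integer())
  .write_csv_prov(df, path, seed)
}

#' Read a tally sheet into protocol results
#'
#' Parses and validates the format written by [write_tally_sheet()] (or
#' recorded by hand in the laboratory). Malformed rows are reported with
#' their line numbers; duplicate phase-2 (sample, cell, taxon) records and
#' cell indices outside the tray are rejected. Ground truth is unknown for
#' real tallies, so the truth fields of the returned results are `NA`.
#'
#' @param path Tally-sheet file.
#' @param geometry A [tray_geometry()] used to validate cell indices.
#' @return Named list of [protocol_result()] objects, one per sample.
#' @export
read_tally_sheet <- function(path, geometry = tray_geometry()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        taxon_id = "character"))
  need <- c("sample_id", "phase", "cell_index", "taxon_id", "count")
  if (!all(need %in% names(raw)))
    stop("tally sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0) return(list())
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1 of the payload

  bad <- !(raw$phase %in% 1:3)
  bad2 <- raw$phase == 2 &
    (is.na(raw$cell_index) | raw$cell_index < 1 |
       raw$cell_index > geometry$n_complete_cells)
  bad3 <- raw$phase != 2 & !is.na(raw$cell_index)
  bad4 <- raw$phase %in% 1:2 & !is.na(raw$taxon_id) &
    (is.na(raw$count) | raw$count < 0)
  problems <- bad | bad2 | bad3 | bad4
  if (any(problems))
    stop("malformed tally rows at line(s): ",
         paste(line_no[problems], collapse = ", "), call. = FALSE)
  p2 <- raw[raw$phase == 2 & !is.na(raw$taxon_id), ]
  if (nrow(p2) && anyDuplicated(p2[c("sample_id", "cell_index", "taxon_id")]))
    stop("duplicate phase-2 (sample, cell, taxon) records", call. = FALSE)

  out <- list()
  for (sid in unique(raw$sample_id)) {
    d <- raw[raw$sample_id == sid, ]
    taxa <- sort(unique(stats::na.omit(d$taxon_id)))
    if (!length(taxa)) taxa <- "none"
    lg <- stats::setNames(integer(length(taxa)), taxa)
    d1 <- d[d$phase == 1, ]
    if (nrow(d1)) lg[d1$taxon_id] <- as.integer(d1$count)
    d2 <- d[d$phase == 2, ]
    cells <- unique(d2$cell_index)
    obs <- matrix(0L, nrow = length(cells), ncol = length(taxa),
                  dimnames = list(NULL, taxa))
    d2t <- d2[!is.na(d2$taxon_id), ]
    if (nrow(d2t))
      obs[cbind(match(d2t$cell_index, cells), match(d2t$taxon_id, taxa))] <-
        as.integer(d2t$count)
    sub <- structure(list(selected_cells = as.integer(cells),
                          observed_counts = obs, k = length(cells)),
                     class = "subsample_result")
    scan <- d$taxon_id[d$phase == 3]
    out[[sid]] <- protocol_result(large_counts = lg, subsample = sub,
                                  scan_taxa = scan, geometry = geometry,
                                  sample_id = sid)
  }
  out
}

#' Write / read ground-truth sample sheets
#'
#' A sample sheet stores a full simulated realization as text: one row per
#' `sample_id, region, taxon_id, count`, where `region` is `cell1` ..
#' `cellN`, `edge`, or `large`. Reading reconstructs
#' [simulate_sample()]-shaped objects; per-taxon detection parameters are
#' re-attached from `taxa` (taxa absent from the table get perfect
#' detection).
#'
#' @param samples A `sample_realization` or list of them.
#' @param path File path.
#' @param seed Seed recorded in the provenance header, if any.
#' @param geometry A [tray_geometry()].
#' @param taxa Optional [taxa_spec()] supplying detection parameters.
#' @return `write_sample_sheet`: the path, invisibly. `read_sample_sheet`:
#'   named list of `sample_realization` objects.
#' @export
write_sample_sheet <- function(samples, path, seed = NA) {
  if (inherits(samples, "sample_realization")) samples <- list(samples)
  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "sample_realization"))
    sid <- sprintf("S%03d", i)
    cc <- s$cell_counts
    idx <- which(cc > 0, arr.ind = TRUE)
    if (nrow(idx))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, region = rownames(cc)[idx[, 1]],
        taxon_id = colnames(cc)[idx[, 2]], count = cc[idx])
    lg <- s$large_counts[s$large_counts > 0]
    if (length(lg))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, region = "large", taxon_id = names(lg),
        count = as.integer(lg))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), region = character(),
               taxon_id = character(), count = integer())
  .write_csv_prov(df, path, seed)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path, geometry = tray_geometry(), taxa = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        taxon_id = "character",
                                        region = "character"))
  C <- geometry$n_complete_cells
  regions <- c(paste0("cell", seq_len(C)), "edge")
  out <- list()
  for (sid in unique(raw$sample_id)) {
    d <- raw[raw$sample_id == sid, ]
    if (!all(d$region %in% c(regions, "large")))
      stop("unknown region label(s) in sample ", sid, call. = FALSE)
    ids <- sort(unique(d$taxon_id))
    tx <- if (is.null(taxa)) taxa_spec(ids, relative_abundance = 1) else {
      m <- match(ids, taxa$taxon_id)
      taxa_spec(ids,
                relative_abundance = ifelse(is.na(m), 1,
                                            taxa$relative_abundance[m]),
                large_fraction = ifelse(is.na(m), 0, taxa$large_fraction[m]),
                p_detect_cell = ifelse(is.na(m), 1, taxa$p_detect_cell[m]),
                p_detect_scan = ifelse(is.na(m), 1, taxa$p_detect_scan[m]))
    }
    cc <- matrix(0L, nrow = C + 1L, ncol = length(ids),
                 dimnames = list(regions, ids))
    dc <- d[d$region != "large", ]
    if (nrow(dc))
      cc[cbind(match(dc$region, regions), match(dc$taxon_id, ids))] <-
        as.integer(dc$count)
    lg <- stats::setNames(integer(length(ids)), ids)
    dl <- d[d$region == "large", ]
    if (nrow(dl)) lg[dl$taxon_id] <- as.integer(dl$count)
    tot <- sum(cc) + sum(lg)
    out[[sid]] <- structure(
      list(cell_counts = cc, large_counts = lg, true_total = tot,
           true_phase2_total = sum(cc),
           true_taxa = ids[colSums(cc) + lg > 0],
           taxa = tx, geometry = geometry, preset = "file"),
      class = "sample_realization")
  }
  out
}

#' Write an estimate table
#'
#' One row per sample: the abundance estimate, its components, the
#' abundance category of the estimated total, the 10-cell full-count
#' recommendation (blank when fewer than 10 cells were counted) and the
#' detected taxa richness, plus the true values when available.
#'
#' @param results Named list of [protocol_result()] objects.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header, if any.
#' @return The estimate data frame, invisibly.
#' @export
write_estimates <- function(results, path, seed = NA) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    est <- estimate_abundance(r)
    mpc10 <- if (r$k_used >= 10)
      estimate_abundance(r, k = 10)$mean_per_cell else NA_real_
    data.frame(
      sample_id = if (!is.na(r$sample_id)) r$sample_id else
        if (!is.null(names(results))) names(results)[i] else sprintf("S%03d", i),
      k = est$k_used, mean_per_cell = est$mean_per_cell,
      phase2_estimate = est$phase2_estimate, large_count = est$large_count,
      total_estimate = est$total_estimate,
      category = as.character(classify_abundance(est$total_estimate)),
      recommend_full_count = if (is.na(mpc10)) NA else
        recommend_full_count(mpc10),
      richness_detected = taxa_richness(r),
      true_total = r$true_total,
      true_phase2_total = r$true_phase2_total,
      percent_accuracy = if (!is.na(r$true_phase2_total) &&
                             r$true_phase2_total > 0)
        percent_accuracy(est$phase2_estimate, r$true_phase2_total) else
          NA_real_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .write_csv_prov(df, path, seed)
  invisible(df)
}

#' Read a run-configuration file
#'
#' YAML with optional blocks `geometry` (`inner_diameter_cm`,
#' `cell_side_cm`, `n_complete_cells`, `equivalent_cells`), `community`
#' (`preset` or `taxa_file`, `clustering_theta`), `protocol` (`k`),
#' `evaluation` (`n_reps`, `k_max`, `seed`) and `output` (`dir`). Missing
#' entries take the package defaults (the published apparatus, k = 16,
#' 1000 replicates).
#'
#' @param path YAML file.
#' @return A list of class `"run_config"` with elements `geometry`
#'   (a [tray_geometry()]), `community`, `protocol`, `evaluation`, `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  g <- y$geometry
  geometry <- tray_geometry(
    inner_diameter = g$inner_diameter_cm %||% 22.9,
    cell_side = g$cell_side_cm %||% 2.54,
    n_complete_cells = g$n_complete_cells %||% 45L,
    equivalent_cells = g$equivalent_cells %||% 63.6)
  ev <- y$evaluation
  seed <- ev$seed %||% NA
  if (!is.na(seed) && (!is.numeric(seed) || seed < 0))
    stop("'seed' must be a non-negative integer", call. = FALSE)
  k <- y$protocol$k %||% 16L
  if (k > geometry$n_complete_cells)
    stop("'k' exceeds the number of complete cells", call. = FALSE)
  structure(list(
    geometry = geometry,
    community = list(preset = y$community$preset %||% "pan_moderate",
                     taxa_file = y$community$taxa_file,
                     clustering_theta = y$community$clustering_theta %||% Inf,
                     n_samples = y$community$n_samples %||% 10L),
    protocol = list(k = as.integer(k)),
    evaluation = list(n_reps = ev$n_reps %||% 1000L,
                      k_max = ev$k_max %||% 16L, seed = seed),
    output = list(dir = y$output$dir %||% ".")),
    class = "run_config")
}

#' Read a taxa preset file
#'
#' Delimited text, one row per taxon with columns `taxon_id`,
#' `relative_abundance`, `large_fraction`, `p_detect_cell`,
#' `p_detect_scan`.
#'
#' @param path CSV file.
#' @return A [taxa_spec()] table.
#' @export
read_taxa_file <- function(path) {
  d <- .read_csv_prov(path)
  need <- c("taxon_id", "relative_abundance", "large_fraction",
            "p_detect_cell", "p_detect_scan")
  if (!all(need %in% names(d)))
    stop("taxa file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  taxa_spec(d$taxon_id, d$relative_abundance, d$large_fraction,
            d$p_detect_cell, d$p_detect_scan)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
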