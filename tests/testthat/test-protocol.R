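test_that("phase 1 passes the large pool through losslessly", {
  g <- tiny_geometry(4)
  cc <- matrix(0L, 5, 1, dimnames = list(NULL, "Carabidae"))
  s0 <- make_sample(cc, c(Carabidae = 0L), g)
  expect_equal(phase1_sieve(s0), c(Carabidae = 0L))
  s3 <- make_sample(cc + 1L, c(Carabidae = 3L), g)
  expect_equal(phase1_sieve(s3), c(Carabidae = 3L))
  expect_equal(s3$true_phase2_total, s3$true_total - 3L)
})

test_that("counting all cells with perfect detection recovers the truth", {
  set.seed(10)
  s <- simulate_sample(community_preset("pan_moderate"))
  sub <- phase2_subsample(s, k = 45, p_detect_cell = 1)
  truth <- s$cell_counts[sub$selected_cells, , drop = FALSE]
  expect_equal(unname(sub$observed_counts), unname(truth))
  # edge-free tray: phase-2 observation equals the full tray truth
  g <- tiny_geometry(6)
  set.seed(11)
  cc <- allocate_to_tray(c(A = 40L, B = 9L), g, Inf)
  s2 <- make_sample(cc, geometry = g)
  r <- run_protocol(s2, k = 6, perfect_detection = TRUE)
  expect_equal(sum(r$subsample$observed_counts), s2$true_phase2_total)
})

test_that("detection can miss but never invent individuals", {
  set.seed(12)
  s <- simulate_sample(community_preset("pitfall_high"))
  sub <- phase2_subsample(s, k = 16, p_detect_cell = 0.5)
  truth <- s$cell_counts[sub$selected_cells, , drop = FALSE]
  expect_true(all(sub$observed_counts <= truth))
  zero <- phase2_subsample(s, k = 16, p_detect_cell = 0)
  expect_equal(sum(zero$observed_counts), 0)
  expect_error(phase2_subsample(s, k = 0), "must be an integer")
  expect_error(phase2_subsample(s, k = 46), "must be an integer")
})

test_that("cell selection is uniform without replacement", {
  set.seed(13)
  s <- simulate_sample(community_preset("pan_low"))
  n <- 20000
  counts <- integer(45)
  dup <- 0L
  for (i in seq_len(n)) {
    sel <- phase2_subsample(s, k = 16, p_detect_cell = 0)$selected_cells
    dup <- dup + (anyDuplicated(sel) > 0L)
    counts[sel] <- counts[sel] + 1L
  }
  expect_equal(dup, 0L)
  p <- 16 / 45
  s_incl <- sqrt(p * (1 - p) / n)
  # 4-SD band to allow for the 45 simultaneous comparisons
  expect_true(all(abs(counts / n - p) < 4 * s_incl))
})

test_that("quick-scan detection follows 1 - (1 - q)^m", {
  g <- tiny_geometry(4)
  cc <- matrix(c(3L, 0L, 0L, 0L, 0L), 5, 1, dimnames = list(NULL, "A"))
  s <- make_sample(cc, geometry = g)
  empty_sub <- structure(list(selected_cells = 2L,
                              observed_counts = matrix(0L, 1, 1,
                                dimnames = list(NULL, "A")),
                              k = 1L), class = "subsample_result")
  # m = 3, q = 0.5: closed form 1 - 0.5^3 = 0.875
  set.seed(14)
  hits <- replicate(20000,
    length(phase3_scan(s, character(), empty_sub, p_detect_scan = 0.5)))
  p_hat <- mean(hits)
  expect_lt(abs(p_hat - 0.875), 3 * mc_sd(0.875, 20000))
  # q = 1 with m >= 1 always detects; already-detected taxa are never re-added
  expect_equal(phase3_scan(s, character(), empty_sub, p_detect_scan = 1), "A")
  expect_equal(phase3_scan(s, "A", empty_sub, p_detect_scan = 1),
               character(0))
})

test_that("three-phase composition keeps the scan partition disjoint", {
  cfg <- community_preset("pitfall_low")
  for (seed in 1:100) {
    set.seed(seed)
    s <- simulate_sample(cfg)
    r <- run_protocol(s, k = 16)
    expect_length(intersect(r$scan_taxa,
                            union(detected_taxa(r, 1), detected_taxa(r, 2))),
                  0)
    expect_true(all(detected_taxa(r) %in% s$true_taxa))
  }
})

test_that("phase-2 taxon detection probability matches brute-force
           enumeration", {
  # single taxon, m = 2 individuals in C = 4 cells, k = 2, perfect
  # detection: enumeration over all 16 placements gives 0.75
  expect_equal(oracle_detect_prob(2, 4, 2, 1), 0.75)
  g <- tiny_geometry(4)
  n <- 20000
  set.seed(15)
  hits <- replicate(n, {
    cc <- allocate_to_tray(c(A = 2L), g, Inf)
    s <- make_sample(cc, geometry = g)
    sum(phase2_subsample(s, k = 2, p_detect_cell = 1)$observed_counts) > 0
  })
  expect_lt(abs(mean(hits) - 0.75), 3 * mc_sd(0.75, n))
})

test_that("protocol-result constructor enforces the scan partition", {
  g <- tiny_geometry(4)
  sub <- structure(list(selected_cells = c(1L, 2L),
                        observed_counts = matrix(c(2L, 0L, 0L, 0L), 2, 2,
                          dimnames = list(NULL, c("A", "B"))),
                        k = 2L), class = "subsample_result")
  expect_error(protocol_result(c(A = 0L, B = 0L), sub, scan_taxa = "A",
                               geometry = g), "disjoint")
  ok <- protocol_result(c(A = 0L, B = 0L), sub, scan_taxa = "B",
                        geometry = g)
  expect_equal(taxa_richness(ok), 2)
})
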