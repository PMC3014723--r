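test_that("evaluation is reproducible under a fixed seed", {
  a <- evaluate_design("pan_low", n_reps = 30, seed = 40)
  b <- evaluate_design("pan_low", n_reps = 30, seed = 40)
  expect_identical(a$summary, b$summary)
  expect_identical(a$miss, b$miss)
})

test_that("accuracy spread shrinks as more cells are counted", {
  ev <- evaluate_design("pitfall_high", n_reps = 300, seed = 41,
                        perfect_detection = TRUE)
  s <- ev$summary
  expect_lt(s$accuracy_se[s$k == 16], s$accuracy_se[s$k == 4])
  width <- function(k) {
    r <- s[s$k == k, ]
    r$accuracy_hi - r$accuracy_lo
  }
  expect_lte(width(16), width(10))
  expect_lte(width(10), width(4))
})

test_that("a taxon kept wholly in the large pool gives full richness at
           every k", {
  taxa <- taxa_spec("Carabidae", 1, large_fraction = 1)
  cfg <- community_config(taxa, total_range = c(50, 50), name = "one")
  set.seed(42)
  s <- simulate_sample(cfg)
  r <- run_protocol(s, k = 16)
  expect_equal(taxa_richness(r), 1)
  expect_equal(percent_richness(taxa_richness(r), length(s$true_taxa)), 100)
})

test_that("an exhaustive scan closes every richness gap", {
  ev <- evaluate_design(c("pan_low", "pitfall_high"), n_reps = 40, seed = 43,
                        perfect_detection = TRUE)
  expect_true(all(ev$final$richness_pct_with_scan == 100))
})

test_that("abundant taxa are essentially never missed at k = 16", {
  # coverage bound: (1 - 16/63.6)^50 is ~ 1e-8 before the scan even runs
  taxa <- taxa_spec(c("common", "filler"), c(1, 1))
  cfg <- community_config(taxa, total_range = c(200, 200), name = "two")
  set.seed(44)
  missed <- replicate(300, {
    s <- simulate_sample(cfg)
    r <- run_protocol(s, k = 16)
    !("common" %in% detected_taxa(r))
  })
  expect_lt(mean(missed), 0.01)
})

test_that("whole-protocol miss rate matches the closed-form product", {
  # rare pale taxon: m = 2 individuals in C = 4 cells, k = 2,
  # p_detect_cell = 0.5, scan q = 0.05
  p_oracle <- oracle_miss_prob(2, 4, 2, p = 0.5, q = 0.05)
  g <- tiny_geometry(4)
  n <- 20000
  set.seed(45)
  missed <- replicate(n, {
    cc <- allocate_to_tray(c(A = 2L), g, Inf)
    s <- make_sample(cc, geometry = g, p_detect_cell = 0.5,
                     p_detect_scan = 0.05)
    r <- run_protocol(s, k = 2)
    length(detected_taxa(r)) == 0
  })
  expect_lt(abs(mean(missed) - p_oracle), 3 * mc_sd(p_oracle, n))
})

test_that("clustering inflates the estimator's spread but not its mean", {
  ev_u <- evaluate_design("pan_high", n_reps = 400, seed = 46,
                          perfect_detection = TRUE)
  ev_c <- evaluate_design("pan_high", n_reps = 400, seed = 46,
                          perfect_detection = TRUE, clustering_theta = 0.5)
  su <- ev_u$summary[ev_u$summary$k == 16, ]
  sc <- ev_c$summary[ev_c$summary$k == 16, ]
  expect_gt(sc$accuracy_se, 2 * su$accuracy_se)
  expect_lt(abs(sc$accuracy - 100), 3 * sc$accuracy_se)
})

test_that("confidence-interval nonoverlap uses a closed boundary", {
  expect_true(ci_nonoverlap(c(1, 2), c(3, 4)))
  expect_false(ci_nonoverlap(c(1, 3), c(2, 4)))
  expect_false(ci_nonoverlap(c(1, 2), c(2, 3)))
  expect_true(ci_nonoverlap(c(3, 4), c(1, 2)))
  expect_error(ci_nonoverlap(c(2, 1), c(3, 4)))
})

test_that("per-taxon miss table distinguishes absent from never-missed", {
  ev <- evaluate_design("pan_low", n_reps = 30, seed = 47,
                        perfect_detection = TRUE)
  m <- ev$miss
  expect_true(all(m$miss_rate[m$n_present > 0] == 0))  # perfect protocol
  expect_true(all(is.na(m$miss_rate[m$n_present == 0])))
  expect_true(all(m$n_missed <= m$n_present))
})
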