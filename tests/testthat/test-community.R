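test_that("community draws allocate the sample total multinomially", {
  one <- community_config(taxa_spec("A", 1), total_range = c(100, 100))
  expect_equal(unname(draw_community(one)), 100)

  two <- community_config(taxa_spec(c("A", "B"), c(1, 1)),
                          total_range = c(10000, 10000))
  set.seed(1)
  x <- draw_community(two)
  expect_equal(sum(x), 10000)
  # binomial closed form: SD = sqrt(10000 * 0.25) = 50
  expect_lt(abs(x[["A"]] - 5000), 3 * 50)
  expect_error(community_config(taxa_spec(character(0), 1), c(1, 2)),
               "at least one taxon")
})

test_that("binomial sieve split conserves individuals", {
  ab <- c(A = 10L, B = 7L)
  expect_equal(split_large(ab, 0)$large, c(A = 0L, B = 0L))
  expect_equal(split_large(ab, 1)$small, c(A = 0L, B = 0L))
  set.seed(2)
  sp <- split_large(c(A = 10000L), 0.1)
  expect_equal(sp$large + sp$small, c(A = 10000L))
  # binomial closed form: SD = sqrt(10000 * 0.1 * 0.9) = 30
  expect_lt(abs(sp$large[["A"]] - 1000), 3 * 30)
})

test_that("tray allocation conserves counts for any clustering level", {
  g <- tray_geometry()
  for (seed in 1:100) {
    set.seed(seed)
    ab <- stats::setNames(rpois(5, 40), letters[1:5])
    theta <- sample(c(0.5, 5, Inf), 1)
    cc <- allocate_to_tray(ab, g, theta)
    expect_equal(colSums(cc), ab)
    expect_true(all(cc >= 0))
    expect_equal(dim(cc), c(46L, 5L))
  }
  expect_equal(sum(allocate_to_tray(c(A = 0L), g)), 0)
})

test_that("uniform placement is multinomial over area weights", {
  g <- tray_geometry()
  set.seed(3)
  cc <- allocate_to_tray(c(A = 63600L), g, Inf)
  # each complete cell expects 1000 with SD ~31.4; 4-SD band for 45 cells
  p <- 1 / 63.6
  s <- sqrt(63600 * p * (1 - p))
  cells <- cc[1:45, 1]
  expect_true(all(abs(cells - 1000) < 4 * s))
  # pooled edge region expects its area share, 18.6 / 63.6
  set.seed(4)
  edge <- replicate(50, allocate_to_tray(c(A = 2000L), g, Inf)[46, 1])
  expect_lt(abs(mean(edge) / 2000 - 18.6 / 63.6),
            3 * sqrt((18.6 / 63.6) * (45 / 63.6) / (50 * 2000)))
})

test_that("per-cell variance decreases toward the multinomial limit as
           clustering weakens", {
  g <- tiny_geometry(6)
  N <- 120
  vars <- sapply(c(0.5, 5, 50, Inf), function(theta) {
    set.seed(5)
    var(replicate(2000, allocate_to_tray(c(A = N), g, theta)[1, 1]))
  })
  expect_true(all(diff(vars) < 0))
  # theta -> Inf limit: multinomial variance N p (1-p), within 10%
  v_mult <- N * (1 / 6) * (5 / 6)
  expect_lt(abs(vars[4] - v_mult) / v_mult, 0.10)
})

test_that("presets stay inside the field envelopes for totals and richness", {
  for (pr in preset_names) {
    cfg <- community_preset(pr)
    set.seed(6)
    reps <- replicate(100, {
      s <- simulate_sample(cfg)
      c(total = s$true_total, rich = length(s$true_taxa))
    })
    expect_true(all(reps["total", ] >= cfg$total_range[1]))
    expect_true(all(reps["total", ] <= cfg$total_range[2]))
    # calibrated: mean realized richness close to the field mean
    expect_lt(abs(mean(reps["rich", ]) - richness_targets[[pr]]), 1.2)
    expect_true(all(reps["rich", ] <= nrow(cfg$taxa)))
  }
})

test_that("identical config and seed give bit-identical realizations", {
  cfg <- community_preset("pitfall_moderate", clustering_theta = 2)
  set.seed(7); s1 <- simulate_sample(cfg)
  set.seed(7); s2 <- simulate_sample(cfg)
  expect_identical(s1, s2)
})

test_that("taxa table validation rejects bad parameters", {
  expect_error(taxa_spec(c("A", "A"), 1), "unique")
  expect_error(taxa_spec("A", -1), "positive")
  expect_error(taxa_spec("A", 1, large_fraction = 1.2), "\\[0, 1\\]")
  expect_error(community_config(taxa_spec("A", 1), c(5, 2)), "increasing")
  expect_error(community_config(taxa_spec("A", 1), c(1, 2),
                                clustering_theta = 0), "positive")
  expect_error(allocate_to_tray(c(A = 5L), tray_geometry(),
                                clustering_theta = -1), "positive")
})
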