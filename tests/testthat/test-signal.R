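test_that("d_obs matches the hand-evaluated sister-difference sum", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  d <- tibble::tibble(taxon = c("A", "B", "C", "D"), s = c(1, 1, 0, 0))
  r <- d_statistic(d, tr, "s", n_permutations = 49, seed = 3)
  # node contrasts: |1-1| = 0, |0-0| = 0, |1-0| = 1
  expect_equal(r$d_obs, 1)

  # exhaustive recomputation over all 4-tip assignments with both states
  all_states <- expand.grid(rep(list(0:1), 4))
  for (i in seq_len(nrow(all_states))) {
    x <- as.numeric(all_states[i, ])
    if (length(unique(x)) < 2) next
    names(x) <- c("A", "B", "C", "D")
    v_ab <- mean(x[c("A", "B")]); v_cd <- mean(x[c("C", "D")])
    manual <- abs(x["A"] - x["B"]) + abs(x["C"] - x["D"]) + abs(v_ab - v_cd)
    got <- d_statistic(x, tr, n_permutations = 9, seed = 1)$d_obs
    expect_equal(got, unname(manual))
  }
})

test_that("d_obs is invariant to relabelling the two states", {
  withr::with_seed(19, {
    tr <- ape::rphylo(30, 1, 0)
    x <- rbinom(30, 1, 0.4)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    names(x) <- tr$tip.label
    r1 <- d_statistic(x, tr, n_permutations = 19, seed = 5)
    r2 <- d_statistic(setNames(1 - x, names(x)), tr,
                      n_permutations = 19, seed = 5)
    expect_equal(r1$d_obs, r2$d_obs)
  })
})

test_that("D results are seed-stable with floored p-values", {
  tr <- simulate_tree(40, "birth_death", seed = 2)
  x <- setNames(rep(c(0, 1), 20), tr$tip.label)
  r1 <- d_statistic(x, tr, n_permutations = 99, seed = 11)
  r2 <- d_statistic(x, tr, n_permutations = 99, seed = 11)
  expect_identical(r1, r2)
  expect_gte(r1$p_random, 1 / 100)
  expect_gte(r1$p_brownian, 1 / 100)
  expect_error(d_statistic(setNames(rep(1, 40), tr$tip.label), tr),
               "single-state")
  expect_error(d_statistic(setNames(rep(c(0.5, 1), 20), tr$tip.label), tr),
               "0/1")
})

test_that("polytomy resolution option runs on classification trees", {
  fx <- hunter_gatherer_fixture(seed = 5)
  r <- d_statistic(fx$traits, fx$tree, "specialists", n_permutations = 49,
                   seed = 2, polytomy = "resolve")
  expect_true(is.finite(r$D))
})

test_that("mantel raw z matches direct summation and r its oracle", {
  m1 <- matrix(c(0, 1, 2, 3,
                 1, 0, 4, 5,
                 2, 4, 0, 6,
                 3, 5, 6, 0), 4, 4)
  m2 <- matrix(c(0, 2, 1, 7,
                 2, 0, 3, 2,
                 1, 3, 0, 4,
                 7, 2, 4, 0), 4, 4)
  r <- mantel_test(m1, m2, n_permutations = 99, seed = 1)
  expect_equal(r$z, 1 * 2 + 2 * 1 + 3 * 7 + 4 * 3 + 5 * 2 + 6 * 4)
  expect_equal(r$r, cor(m1[upper.tri(m1)], m2[upper.tri(m2)]))

  # identical matrices: perfect correlation
  expect_equal(mantel_test(m1, m1, n_permutations = 49, seed = 1)$r, 1)

  # agreement with vegan's standardised statistic
  withr::with_seed(31, {
    a <- as.matrix(dist(matrix(rnorm(30), 10)))
    b <- as.matrix(dist(matrix(rnorm(30), 10)))
    ours <- mantel_test(a, b, n_permutations = 199, seed = 9)
    veg <- vegan::mantel(a, b, permutations = 199)
    expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  })
})

test_that("mantel permutation test is seed-stable and well calibrated", {
  withr::with_seed(47, {
    a <- as.matrix(dist(matrix(rnorm(16), 8)))
    b <- as.matrix(dist(matrix(rnorm(16), 8)))
    r1 <- mantel_test(a, b, n_permutations = 99, seed = 3)
    r2 <- mantel_test(a, b, n_permutations = 99, seed = 3)
    expect_identical(r1, r2)
    expect_gte(r1$p, 1 / 100)

    # type-I error near nominal under independent random matrices
    hits <- replicate(400, {
      x <- as.matrix(dist(rnorm(9)))
      y <- as.matrix(dist(rnorm(9)))
      mantel_test(x, y, n_permutations = 99,
                  seed = sample.int(1e6, 1))$p < 0.05
    })
    expect_gt(mean(hits), 0.02)
    expect_lt(mean(hits), 0.09)
  })
  expect_error(mantel_test(matrix(0, 3, 3), matrix(0, 4, 4)), "dimension")
})

test_that("trait distances are elementwise state mismatches", {
  x <- setNames(c(1, 0, 1), c("a", "b", "c"))
  m <- trait_distance(x)
  expect_equal(m, 1 * outer(x, x, "!="), ignore_attr = TRUE)
  expect_equal(unname(m["a", "b"]), 1)
  expect_equal(unname(m["a", "c"]), 0)
  expect_true(all(trait_distance(setNames(c(1, 1), c("a", "b"))) == 0))
})

test_that("geographic distances use the 6371 km haversine", {
  co <- tibble::tibble(taxon = c("p", "q"), lat = c(0, 0), lon = c(0, 180))
  m <- geographic_distances(co)
  expect_equal(unname(m["p", "q"]), pi * 6371, tolerance = 1e-6)
  expect_equal(m, t(m))

  co2 <- tibble::tibble(taxon = c("x", "y"), lat = c(10, 10), lon = c(20, 20))
  expect_equal(unname(geographic_distances(co2)["x", "y"]), 0)

  withr::with_seed(5, {
    co3 <- tibble::tibble(taxon = paste0("t", 1:6),
                          lat = runif(6, -80, 80), lon = runif(6, -170, 170))
    ours <- geographic_distances(co3)
    ref <- geosphere::distm(cbind(co3$lon, co3$lat),
                            fun = function(p1, p2) {
                              geosphere::distHaversine(p1, p2, r = 6371000)
                            }) / 1000
    expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
  })
  expect_error(geographic_distances(tibble::tibble(taxon = "a", lat = 91,
                                                   lon = 0)), "latitude")
})
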