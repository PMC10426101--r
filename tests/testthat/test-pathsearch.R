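test_that("Fisher's C matches direct evaluation and its analytic identities", {
  expect_equal(fisher_c(c(1, 1, 1))$C, 0)
  expect_equal(fisher_c(c(1, 1, 1))$p_value, 1)
  expect_equal(fisher_c(c(0.05, 0.5))$C, -2 * (log(0.05) + log(0.5)),
               tolerance = 1e-12)
  # chi-square with df 2 inverts the transform for a single claim
  expect_equal(fisher_c(0.05)$p_value, 0.05, tolerance = 1e-12)
  empty <- fisher_c(numeric())
  expect_equal(empty$C, 0)
  expect_equal(empty$p_value, 1)
  expect_error(fisher_c(c(0.5, 1.2)), "p-values")
})

test_that("CICc follows its closed form and asymptotics", {
  expect_equal(cicc(10, 5, 68), 10 + 2 * 5 * 68 / 62, tolerance = 1e-12)
  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(cicc(7, 3, 1e6), 7 + 6, tolerance = 1e-3)
  expect_error(cicc(5, 10, 11), "insufficient sample")
  # strictly increasing in C at fixed q, n
  expect_gt(cicc(11, 5, 68), cicc(10, 5, 68))
})

test_that("Akaike weighting of the retained set is exact", {
  scores <- tibble::tibble(
    model_id = 1:3, n_edges = c(1L, 2L, 3L), k = c(2L, 1L, 0L),
    q = c(4L, 5L, 6L), C = c(1, 2, 9), C_pvalue = c(0.9, 0.6, 0.06),
    CICc = c(10, 12, 15), n = 60L, unscored = NA_character_
  )
  class(scores) <- c("model_scores", class(scores))
  ret <- best_set(scores, threshold = 2)
  expect_equal(ret$delta, c(0, 2))
  expect_equal(ret$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  one <- best_set(scores[3, ], threshold = 2)
  expect_equal(one$weight, 1)
  tied <- scores
  tied$CICc <- c(10, 10, 10)
  expect_equal(best_set(tied)$weight, rep(1 / 3, 3))
})

test_that("conditional averaging reproduces hand-computed values", {
  avg <- phylodag:::average_paths
  # shared path, equal weights, zero SEs
  f1 <- tibble::tibble(from = "A", to = "B", coefficient = 0.4, se = 0)
  f2 <- tibble::tibble(from = "A", to = "B", coefficient = 0.6, se = 0)
  out <- avg(list(f1, f2), c(0.5, 0.5))
  expect_equal(out$coefficient, 0.5)

  # path in a single model keeps that model's coefficient
  f3 <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                       coefficient = c(0.3, 0.9), se = c(0.1, 0.2))
  out2 <- avg(list(f1, f3), c(0.7, 0.3))
  expect_equal(out2$coefficient[out2$from == "B"], 0.9)

  # three models, renormalised weighted mean
  w <- c(0.5, 0.3, 0.2)
  fits <- list(
    tibble::tibble(from = "X", to = "Y", coefficient = 0.2, se = 0.05),
    tibble::tibble(from = "X", to = "Y", coefficient = 0.4, se = 0.05),
    tibble::tibble(from = "Z", to = "Y", coefficient = 0.8, se = 0.05)
  )
  out3 <- avg(fits, w)
  wr <- w[1:2] / sum(w[1:2])
  est <- sum(wr * c(0.2, 0.4))
  expect_equal(out3$coefficient[out3$from == "X"], est, tolerance = 1e-12)
  se_exp <- sum(wr * sqrt(0.05^2 + (c(0.2, 0.4) - est)^2))
  expect_equal(out3$se[out3$from == "X"], se_exp, tolerance = 1e-12)
  expect_equal(out3$ci_low, out3$coefficient - 1.96 * out3$se)
})

test_that("claim cache on and off give identical CICc values", {
  withr::with_seed(61, {
    tr <- ape::rphylo(60, 1, 0)
    dag <- dag_model(c("A", "B", "C"), c("A -> B", "B -> C"))
    d <- simulate_traits(tr, dag, c("A -> B" = 0.7, "B -> C" = 0.7),
                         seed = 8)
    sp <- enumerate_dags(c("A", "B", "C"))
    clear_claim_cache()
    s_on <- score_models(sp, d, tr, cache = TRUE)
    s_off <- score_models(sp, d, tr, cache = FALSE)
    expect_equal(s_on$CICc[order(s_on$model_id)],
                 s_off$CICc[order(s_off$model_id)], tolerance = 1e-12)
    # repeat run hits the cache instead of refitting
    s_again <- score_models(sp, d, tr, cache = TRUE)
    expect_equal(attr(s_again, "cache_stats")$fits, 0)
    expect_identical(s_on$CICc, s_again$CICc)
  })
})

test_that("scored spaces honour the saturated-model and monotonicity laws", {
  withr::with_seed(71, {
    tr <- ape::rphylo(50, 1, 0)
    xy <- simulate_bm(tr, 3)
    d <- tibble::tibble(taxon = tr$tip.label, A = xy[, 1], B = xy[, 2],
                        C = xy[, 3])
    sp <- enumerate_dags(c("A", "B", "C"))
    sc <- score_models(sp, d, tr)
    expect_true(all(sc$C >= 0))
    # complete DAGs have an empty basis: C = 0 and CICc = 2qn/(n-1-q)
    sat <- sc[sc$k == 0, ]
    expect_true(nrow(sat) > 0)
    expect_true(all(sat$C == 0))
    expect_equal(sat$CICc, 2 * sat$q * sat$n / (sat$n - 1 - sat$q))
    # basis size = claims count identity on every model
    expect_equal(sc$k, 3 - sc$n_edges)
  })
})

test_that("sparser models never have smaller basis sets", {
  withr::with_seed(15, {
    for (i in 1:50) {
      m <- random_dag(sample(3:6, 1), 0.6)
      if (!nrow(m$edges)) next
      drop_i <- sample(nrow(m$edges), 1)
      m2 <- dag_model(m$nodes, m$edges[-drop_i, ])
      expect_gte(nrow(basis_set(m2)), nrow(basis_set(m)))
    }
  })
})

test_that("the generating chain is retained and its skeleton recovered", {
  # One extra edge costs ~2 CICc while a true claim contributes C ~ 2 on
  # average, so truth-vs-saturated rankings sit near the break-even point
  # by construction; the meaningful checks are Delta <= 2 retention of the
  # generating model and recovery of its skeleton in the averaged model.
  withr::with_seed(505, {
    out <- replicate(10, {
      seed <- sample.int(1e6, 1)
      tr <- simulate_tree(200, "birth_death", seed = seed)
      dag <- dag_model(c("A", "B", "C"), c("A -> B", "B -> C"))
      d <- simulate_traits(tr, dag, c("A -> B" = 0.8, "B -> C" = 0.8),
                           seed = seed + 1)
      res <- phylo_path_explore(d, tr)
      sp <- attr(res$scores, "space")
      truth_id <- which(vapply(seq_len(n_models(sp)), function(i) {
        mm <- space_model(sp, i)
        nrow(mm$edges) == 2 &&
          setequal(paste(mm$edges$from, mm$edges$to), c("A B", "B C"))
      }, logical(1)))
      p <- res$averaged$paths
      sig <- p[!p$excluded, ]
      pair_sig <- function(a, b) {
        any((sig$from == a & sig$to == b) | (sig$from == b & sig$to == a))
      }
      c(retained = truth_id %in% res$retained$model_id,
        skeleton = pair_sig("A", "B") && pair_sig("B", "C") &&
          !pair_sig("A", "C"))
    })
    expect_gte(mean(out["retained", ]), 0.7)
    expect_gte(mean(out["skeleton", ]), 0.8)
  })
})

test_that("explore covers the full space, validates early, and is deterministic", {
  withr::with_seed(81, {
    tr <- simulate_tree(80, "birth_death", seed = 14)
    dag <- dag_model(c("A", "B", "C"), c("A -> B", "B -> C"))
    d <- simulate_traits(tr, dag, c("A -> B" = 0.8, "B -> C" = 0.8),
                         seed = 15)
    res <- phylo_path_explore(d, tr, seed = 42)
    expect_equal(res$n_models, 25)
    expect_s3_class(res$averaged, "averaged_model")
    expect_true(all(res$averaged$paths$ci_low <= res$averaged$paths$coefficient))
    expect_true(all(res$averaged$paths$coefficient <= res$averaged$paths$ci_high))
    expect_equal(sum(res$retained$weight), 1)

    res2 <- phylo_path_explore(d, tr, seed = 42)
    expect_identical(as.character(report_json(res)),
                     as.character(report_json(res2)))

    d_bad <- d
    d_bad$taxon[1] <- "not_a_tip"
    expect_error(phylo_path_explore(d_bad, tr), "absent from tree")
  })
})
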