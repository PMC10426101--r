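test_that("PGLS recovers exact fits in analytic cases", {
  # perfect linear relation on a star tree
  star <- star_tree(3, c("A", "B", "C"))
  d <- tibble::tibble(taxon = c("A", "B", "C"), y = c(0, 1, 2), x = c(0, 1, 2))
  f <- pgls_fit(d, star, "y", "x")
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"], 1,
               tolerance = 1e-10)
  expect_lt(f$sigma2, 1e-20)

  # fixed lambda = 1 equals the closed-form GLS solution
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1,E:2);")
  y <- c(1, 2, 0.5, 1.5, 3)
  x <- c(0.2, 1, -0.5, 0.8, 2)
  d5 <- tibble::tibble(taxon = tr$tip.label, y = y, x = x)
  f1 <- pgls_fit(d5, tr, "y", "x", fixed_parameter = 1)
  S <- ape::vcv.phylo(tr)[tr$tip.label, tr$tip.label]
  X <- cbind(1, x)
  beta <- solve(t(X) %*% solve(S) %*% X, t(X) %*% solve(S) %*% y)
  expect_equal(f1$coefficients$estimate, drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("lambda = 0 reduces PGLS to ordinary least squares", {
  withr::with_seed(101, {
    tr <- ape::rphylo(40, 1, 0)
    d <- tibble::tibble(taxon = tr$tip.label, y = rnorm(40), x = rnorm(40),
                        z = rnorm(40))
    f <- pgls_fit(d, tr, "y", c("x", "z"), fixed_parameter = 0)
    ols <- lm(y ~ x + z, d)
    expect_equal(f$coefficients$estimate, unname(coef(ols)),
                 tolerance = 1e-8)
    expect_equal(f$coefficients$std.error,
                 unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  })
})

test_that("PGLS agrees with nlme::gls under a fixed Pagel lambda", {
  withr::with_seed(55, {
    tr <- ape::rphylo(30, 1, 0)
    x <- drop(simulate_bm(tr))
    y <- 0.5 * x + drop(simulate_bm(tr))
    d <- tibble::tibble(taxon = tr$tip.label, x = x, y = y)
    for (lam in c(0.3, 1)) {
      f <- pgls_fit(d, tr, "y", "x", fixed_parameter = lam)
      g <- nlme::gls(
        y ~ x, data = as.data.frame(d),
        correlation = ape::corPagel(lam, tr, form = ~taxon, fixed = TRUE)
      )
      expect_equal(f$coefficients$estimate, unname(coef(g)),
                   tolerance = 1e-6)
      expect_equal(f$coefficients$std.error,
                   unname(sqrt(diag(g$varBeta))), tolerance = 1e-6)
    }
  })
})

test_that("profile likelihood at the fitted parameter beats a bound-spanning grid", {
  withr::with_seed(9, {
    tr <- ape::rphylo(50, 1, 0)
    y <- drop(simulate_bm(tr))
    x <- 0.4 * y + rnorm(50)
    d <- tibble::tibble(taxon = tr$tip.label, y = y, x = x)
    for (tf in c("lambda", "ou")) {
      f <- pgls_fit(d, tr, "y", "x", transform = tf)
      bounds <- if (tf == "lambda") c(0, 1) else {
        c(1e-6, 50 / max(patristic_distances(tr)))
      }
      grid <- seq(bounds[1], bounds[2], length.out = 20)
      ll_grid <- vapply(grid, f$profile, numeric(1))
      expect_gte(f$profile(f$correlation_parameter), max(ll_grid) - 1e-6)
    }
  })
})

test_that("fits are invariant to taxon order and predictor rescaling", {
  withr::with_seed(23, {
    tr <- ape::rphylo(35, 1, 0)
    x <- drop(simulate_bm(tr))
    y <- 0.6 * x + drop(simulate_bm(tr))
    d <- tibble::tibble(taxon = tr$tip.label, y = y, x = x)
    f1 <- pgls_fit(d, tr, "y", "x", standardise = TRUE)
    f2 <- pgls_fit(d[sample(nrow(d)), ], tr, "y", "x", standardise = TRUE)
    expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
                 tolerance = 1e-9)
    d3 <- d
    d3$x <- 3 * d3$x + 5
    f3 <- pgls_fit(d3, tr, "y", "x", standardise = TRUE)
    expect_equal(f1$coefficients$estimate[2], f3$coefficients$estimate[2],
                 tolerance = 1e-9)
  })
})

test_that("null p-values are approximately uniform", {
  withr::with_seed(77, {
    tr <- ape::rphylo(40, 1, 0)
    ps <- replicate(500, {
      xy <- simulate_bm(tr, 2)
      d <- tibble::tibble(taxon = tr$tip.label, x = xy[, 1], y = xy[, 2])
      f <- pgls_fit(d, tr, "y", "x")
      f$coefficients$p.value[2]
    })
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
  })
})

test_that("PGLS validates its inputs", {
  tr <- star_tree(4, LETTERS[1:4])
  d <- tibble::tibble(taxon = LETTERS[1:4], y = c(1, 1, 1, 1), x = 1:4)
  expect_error(pgls_fit(d, tr, "y", "x"), "zero variance")
  d2 <- tibble::tibble(taxon = LETTERS[1:4], y = rnorm(4), x = 1:4,
                       x2 = 2 * (1:4))
  expect_error(pgls_fit(d2, tr, "y", c("x", "x2")), "collinear")
  d3 <- tibble::tibble(taxon = c("A", "B", "C", "Z"), y = rnorm(4), x = rnorm(4))
  expect_error(pgls_fit(d3, tr, "y", "x"), "Z")
  expect_error(pgls_fit(d2[1:2, ], tr, "y", "x"), "too few")
  expect_error(pgls_fit(d2, tr, "y", "y"), "response")
})

test_that("bivariate screen ranks a known strong effect first", {
  withr::with_seed(300, {
    tr <- ape::rphylo(200, 1, 0)
    dag <- dag_model(c("x1", "x2", "x3", "y"), c("x1 -> y"))
    d <- simulate_traits(tr, dag, c("x1 -> y" = 0.8), seed = 4)
    scr <- bivariate_screen(d, tr, "y", c("x1", "x2", "x3"))
    expect_equal(scr$variable[1], "x1")
    expect_equal(scr$signif[1], "**")
    expect_true(all(is.na(scr$error)))
  })
  # empty candidate list -> empty table
  tr2 <- star_tree(4, LETTERS[1:4])
  d2 <- tibble::tibble(taxon = LETTERS[1:4], y = rnorm(4))
  expect_equal(nrow(bivariate_screen(d2, tr2, "y", character())), 0)
  d2$y <- 1
  expect_error(bivariate_screen(d2, tr2, "y", character()), "zero variance")
})

test_that("logistic variant matches glm at lambda 0 and flags separation", {
  withr::with_seed(88, {
    tr <- ape::rphylo(120, 1, 0)
    x <- rnorm(120)
    y <- rbinom(120, 1, plogis(0.8 * x))
    d <- tibble::tibble(taxon = tr$tip.label, y = y, x = x)
    f <- phylo_logistic_fit(d, tr, "y", "x", parameter = 0)
    g <- glm(y ~ x, binomial(), d)
    expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-4)
    expect_equal(f$coefficients$std.error,
                 unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)

    d$xs <- d$y  # predictor identical to response: separation
    expect_warning(phylo_logistic_fit(d, tr, "y", "xs", parameter = 0),
                   "separation")
  })
})

test_that("logistic null fits on a star tree are well calibrated", {
  withr::with_seed(132, {
    star <- star_tree(200)
    ps <- replicate(40, {
      d <- tibble::tibble(taxon = star$tip.label,
                          y = sample(rep(c(0, 1), 100)),
                          x = rnorm(200))
      f <- phylo_logistic_fit(d, star, "y", "x", parameter = 0)
      c(abs(f$coefficients$estimate[2]), f$coefficients$p.value[2])
    })
    expect_lt(mean(ps[1, ]), 0.25)          # coefficients near zero
    expect_gt(mean(ps[2, ] < 0.05), 0)      # occupies the whole p range
    expect_lt(mean(ps[2, ] < 0.05), 0.2)
    expect_gt(mean(ps[2, ]), 0.3)
  })
})
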