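#' Phylogenetic generalised least squares with a profiled correlation
#' parameter
#'
#' Fits `response ~ predictors + conditioning` by GLS with error covariance
#' taken from the phylogeny, `Sigma(theta)`, where `theta` is either Pagel's
#' lambda (off-diagonal multiplier, `lambda %in% [0, 1]`) or an
#' Ornstein-Uhlenbeck-style decay rate alpha (`corr_ij = exp(-alpha d_ij)`).
#' The correlation parameter is estimated by profile maximum likelihood
#' (coarse grid then golden-section refinement) unless `fixed_parameter` is
#' supplied. Coefficients are the closed-form GLS estimate
#' `(X' S^-1 X)^-1 X' S^-1 y` at the fitted parameter; Wald t-tests use
#' `n_used - p` degrees of freedom with `p` the number of columns of `X`
#' (intercept included).
#'
#' Binary (0/1) responses are fitted on the linear scale by default, the
#' convention of regression-based path analysis on binary data; set
#' `binary_method = "logistic"` for the approximate latent-scale logistic
#' variant ([phylo_logistic_fit()]).
#'
#' @param data Trait table: data frame with a taxon column (tip labels) and
#'   numeric trait columns.
#' @param tree [ape::phylo] phylogeny covering the taxa.
#' @param response Response variable name.
#' @param predictors Character vector of predictor names (the terms of
#'   interest).
#' @param conditioning Additional variable names appended to the design
#'   (used by d-separation tests).
#' @param transform `"lambda"` (default) or `"ou"`.
#' @param binary_method `"linear"` (default) or `"logistic"`, applied when
#'   the response is strictly 0/1.
#' @param fixed_parameter If non-`NULL`, the correlation parameter is fixed
#'   at this value instead of estimated.
#' @param alpha_max Upper search bound for alpha; default `50 / max
#'   patristic distance`.
#' @param standardise Centre/scale all continuous variables (binary kept
#'   0/1 but standardised too when `TRUE`, so coefficients are comparable
#'   path coefficients).
#' @return An object of class `pgls_fit` with a `coefficients` tibble
#'   (`term, estimate, std.error, statistic, df, p.value`), the fitted
#'   `correlation_parameter`, `transform`, `log_likelihood`, `sigma2`,
#'   `n_used`, and a `profile` function mapping a parameter value to its
#'   profile log-likelihood.
#' @export
pgls_fit <- function(data, tree, response, predictors,
                     conditioning = character(),
                     transform = c("lambda", "ou"),
                     binary_method = c("linear", "logistic"),
                     fixed_parameter = NULL, alpha_max = NULL,
                     standardise = FALSE) {
  transform <- match.arg(transform)
  binary_method <- match.arg(binary_method)
  predictors <- as.character(predictors)
  conditioning <- as.character(conditioning)
  if (response %in% c(predictors, conditioning)) {
    abort("response cannot appear among the predictors")
  }
  vars <- c(response, predictors, conditioning)
  aligned <- align_to_tree(data, tree, vars)
  keep <- complete.cases(aligned[vars])
  aligned <- aligned[keep, , drop = FALSE]
  n <- nrow(aligned)
  p <- length(predictors) + length(conditioning) + 1L
  if (n < p + 1L) {
    abort(paste0("too few taxa with complete data (", n, ") for ",
                 p - 1L, " predictor(s)"))
  }
  y <- aligned[[response]]
  if (sd(y) == 0) abort("zero variance response")

  if (is_binary01(y) && binary_method == "logistic") {
    return(phylo_logistic_fit(data, tree, response, predictors, conditioning,
                              transform = transform,
                              parameter = fixed_parameter))
  }

  xvars <- c(predictors, conditioning)
  if (standardise) {
    y <- standardise(y)
    for (v in xvars) aligned[[v]] <- standardise(aligned[[v]])
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(aligned[, xvars, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }

  sub <- prune_tree(tree, aligned$taxon)
  pieces <- cov_pieces(sub, aligned$taxon)
  sigma_fun <- switch(transform,
    lambda = function(par) transform_lambda(pieces$v_bm, par),
    ou = function(par) transform_ou(pieces$v_bm, pieces$d_pat, par)
  )
  bounds <- if (transform == "lambda") c(0, 1) else {
    c(1e-6, alpha_max %||% (50 / max(pieces$d_pat)))
  }

  profile_ll <- function(par) gls_core(sigma_fun(par), X, y)$log_lik
  if (is.null(fixed_parameter)) {
    par_hat <- maximise_profile(profile_ll, bounds)
  } else {
    if (fixed_parameter < bounds[1] - 1e-12 && transform == "lambda") {
      abort("lambda must lie in [0, 1]")
    }
    if (transform == "lambda" && (fixed_parameter < 0 || fixed_parameter > 1)) {
      abort("lambda must lie in [0, 1]")
    }
    if (transform == "ou" && fixed_parameter < 0) abort("alpha must be >= 0")
    par_hat <- fixed_parameter
  }
  fit <- gls_core(sigma_fun(par_hat), X, y)
  df <- n - p
  tval <- fit$coef / fit$se
  pval <- 2 * pt(-abs(tval), df = df)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(fit$coef),
    std.error = unname(fit$se),
    statistic = unname(tval),
    df = df,
    p.value = unname(pval)
  )
  structure(
    list(coefficients = coefs,
         response = response,
         predictors = predictors,
         conditioning = conditioning,
         transform = transform,
         correlation_parameter = par_hat,
         parameter_fixed = !is.null(fixed_parameter),
         log_likelihood = fit$log_lik,
         sigma2 = fit$sigma2,
         n_used = n,
         method = "linear",
         profile = profile_ll),
    class = "pgls_fit"
  )
}

prune_tree <- function(tree, taxa) {
  if (length(setdiff(tree$tip.label, taxa))) {
    ape::keep.tip(tree, taxa)
  } else {
    tree
  }
}

cov_pieces <- function(tree, taxa) {
  v_bm <- ape::vcv.phylo(tree)[taxa, taxa]
  d_pat <- stats::cophenetic(tree)[taxa, taxa]
  list(v_bm = v_bm, d_pat = d_pat)
}

# Whitened least squares given a covariance matrix: ML log-likelihood with
# profiled-out residual variance, GLS coefficients and their standard errors
# (unbiased variance estimate RSS / (n - p)).
gls_core <- function(sigma, X, y) {
  n <- length(y)
  L <- chol(sigma)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  qr_s <- qr(Xs)
  coef <- qr.coef(qr_s, ys)
  res <- ys - Xs %*% coef
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  log_det <- 2 * sum(log(diag(L)))
  log_lik <- -0.5 * (n * log(2 * pi) + n * log(max(sigma2_ml, 1e-300)) +
                       n + log_det)
  xtxi <- chol2inv(qr.R(qr_s))
  p <- ncol(X)
  s2 <- if (n > p) rss / (n - p) else 0
  se <- sqrt(pmax(diag(xtxi), 0) * s2)
  list(coef = coef, se = se, rss = rss, sigma2 = sigma2_ml,
       log_lik = log_lik, xtxi = xtxi)
}

# Coarse grid then optimize() inside the bracketing interval; returns the
# argmax. Guards against the local optima a single optimize() call can miss.
maximise_profile <- function(f, bounds, n_grid = 11) {
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.35)
  cands <- c(opt$maximum, grid[i], bounds)
  cand_vals <- vapply(cands, f, numeric(1))
  cands[which.max(cand_vals)]
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (", x$method, "), transform = ", x$transform,
      ", ", if (x$transform == "lambda") "lambda" else "alpha", " = ",
      signif(x$correlation_parameter, 4),
      ", n = ", x$n_used, "\n\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    transform = x$transform,
    correlation_parameter = x$correlation_parameter,
    logLik = x$log_likelihood,
    sigma2 = x$sigma2 %||% NA_real_,
    nobs = x$n_used,
    df.residual = x$n_used - nrow(x$coefficients)
  )
}

#' Bivariate phylogenetic screen
#'
#' One single-predictor PGLS per candidate variable against a common
#' response, with per-fit listwise deletion; the output mirrors a
#' bivariate-association table with significance flags at 0.05 (`*`) and
#' 0.01 (`**`). Per-candidate failures are reported in the table rather than
#' aborting the screen.
#'
#' @inheritParams pgls_fit
#' @param candidates Character vector of candidate predictor names.
#' @return A tibble sorted by p-value with columns `variable, estimate,
#'   std.error, statistic, p.value, parameter, transform, n, signif,
#'   error`.
#' @export
bivariate_screen <- function(data, tree, response, candidates,
                             transform = c("lambda", "ou"),
                             binary_method = c("linear", "logistic"),
                             standardise = FALSE) {
  transform <- match.arg(transform)
  binary_method <- match.arg(binary_method)
  y_all <- data[[response]]
  if (is.null(y_all)) abort(paste0("response '", response, "' not found"))
  if (sd(y_all, na.rm = TRUE) == 0) abort("zero variance response")
  empty <- tibble::tibble(
    variable = character(), estimate = numeric(), std.error = numeric(),
    statistic = numeric(), p.value = numeric(), parameter = numeric(),
    transform = character(), n = integer(), signif = character(),
    error = character()
  )
  if (!length(candidates)) return(empty)
  rows <- purrr::map(candidates, function(v) {
    res <- tryCatch(
      {
        fit <- pgls_fit(data, tree, response, v, transform = transform,
                        binary_method = binary_method,
                        standardise = standardise)
        co <- fit$coefficients[fit$coefficients$term == v, ]
        tibble::tibble(
          variable = v, estimate = co$estimate, std.error = co$std.error,
          statistic = co$statistic, p.value = co$p.value,
          parameter = fit$correlation_parameter, transform = fit$transform,
          n = fit$n_used,
          signif = if (co$p.value < 0.01) "**" else if (co$p.value < 0.05) "*" else "",
          error = NA_character_
        )
      },
      error = function(e) tibble::tibble(
        variable = v, estimate = NA_real_, std.error = NA_real_,
        statistic = NA_real_, p.value = NA_real_, parameter = NA_real_,
        transform = transform, n = NA_integer_, signif = "",
        error = conditionMessage(e)
      )
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(is.na(p.value) == FALSE), p.value)
}

#' Approximate phylogenetic logistic regression
#'
#' Latent-scale logistic fit for a strictly 0/1 response: iteratively
#' reweighted least squares in which the working covariance blends the
#' binomial variance with the phylogenetic correlation matrix,
#' `V = (1 - lambda) diag(1/w) + lambda sqrt(1/w w') * C`. At `lambda = 0`
#' this is exactly ordinary logistic IRLS. The method is deliberately
#' simple and documented as approximate; complete separation triggers a
#' warning and a Firth-style bias-reduction penalty.
#'
#' @inheritParams pgls_fit
#' @param parameter Correlation parameter lambda in `[0, 1]`; if `NULL` it
#'   is borrowed from the maximum-likelihood lambda of the linear 0/1 GLS
#'   fit of the same specification.
#' @return A `pgls_fit` object with `method = "logistic"` (Wald z-tests,
#'   `df = Inf`).
#' @export
phylo_logistic_fit <- function(data, tree, response, predictors,
                               conditioning = character(),
                               transform = "lambda", parameter = NULL) {
  vars <- c(response, predictors, conditioning)
  aligned <- align_to_tree(data, tree, vars)
  aligned <- aligned[complete.cases(aligned[vars]), , drop = FALSE]
  y <- aligned[[response]]
  if (!is_binary01(y)) abort("response must be strictly 0/1")
  if (sd(y) == 0) abort("zero variance response")
  n <- nrow(aligned)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(aligned[, c(predictors, conditioning), drop = FALSE]))
  if (is.null(parameter)) {
    lin <- pgls_fit(data, tree, response, predictors, conditioning,
                    transform = "lambda", binary_method = "linear")
    parameter <- lin$correlation_parameter
  }
  if (parameter < 0 || parameter > 1) abort("lambda must lie in [0, 1]")

  sub <- prune_tree(tree, aligned$taxon)
  C <- stats::cov2cor(ape::vcv.phylo(sub)[aligned$taxon, aligned$taxon])

  run_irls <- function(firth) {
    beta <- rep(0, ncol(X))
    for (iter in seq_len(200)) {
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      sw <- sqrt(1 / w)
      V <- (1 - parameter) * diag(1 / w, n) + parameter * outer(sw, sw) * C
      L <- chol(V)
      Xs <- backsolve(L, X, transpose = TRUE)
      ystar <- y
      if (firth) {
        qr_s <- qr(Xs)
        Q <- qr.Q(qr_s)
        h <- rowSums(Q^2)
        ystar <- y + h * (0.5 - mu)
      }
      z <- eta + (ystar - mu) / w
      zs <- backsolve(L, z, transpose = TRUE)
      beta_new <- qr.coef(qr(Xs), zs)
      if (anyNA(beta_new)) abort("rank-deficient design in logistic fit")
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      if (delta < 1e-10) break
    }
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    sw <- sqrt(1 / w)
    V <- (1 - parameter) * diag(1 / w, n) + parameter * outer(sw, sw) * C
    L <- chol(V)
    Xs <- backsolve(L, X, transpose = TRUE)
    xtxi <- chol2inv(qr.R(qr(Xs)))
    list(beta = beta, se = sqrt(pmax(diag(xtxi), 0)), mu = mu,
         converged = delta < 1e-6, delta = delta)
  }

  fit <- run_irls(firth = FALSE)
  separated <- all(fit$mu[y == 1] > 1 - 1e-6) && all(fit$mu[y == 0] < 1e-6)
  if (separated || !fit$converged || max(abs(fit$beta)) > 25) {
    warn("complete or quasi-complete separation detected; applying Firth-style penalty")
    fit <- run_irls(firth = TRUE)
  }
  zval <- fit$beta / fit$se
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(fit$beta),
    std.error = unname(fit$se),
    statistic = unname(zval),
    df = Inf,
    p.value = unname(2 * stats::pnorm(-abs(zval)))
  )
  structure(
    list(coefficients = coefs, response = response, predictors = predictors,
         conditioning = conditioning, transform = "lambda",
         correlation_parameter = parameter, parameter_fixed = TRUE,
         log_likelihood = sum(y * log(pmax(fit$mu, 1e-12)) +
                                (1 - y) * log(pmax(1 - fit$mu, 1e-12))),
         sigma2 = NA_real_, n_used = n, method = "logistic",
         profile = NULL),
    class = "pgls_fit"
  )
}
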