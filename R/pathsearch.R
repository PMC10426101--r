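#' Fisher's C statistic
#'
#' Combines the p-values of a model's d-separation tests:
#' `C = -2 sum(ln p_k)`, chi-square distributed with `2k` degrees of
#' freedom when the model's independence claims all hold (Shipley's test).
#' p-values are floored at `1e-16` before the log so C stays finite.
#'
#' @param p_values Numeric vector of claim p-values in `(0, 1]`; an empty
#'   vector denotes a saturated model (`C = 0`, model p-value 1).
#' @return List with `C`, `df` (`2k`) and `p_value` (upper chi-square
#'   tail; the probability of a C at least this large under the model).
#' @export
fisher_c <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (!length(p_values)) {
    return(list(C = 0, df = 0L, p_value = 1))
  }
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  C <- -2 * sum(log(pmax(p_values, 1e-16)))
  k <- length(p_values)
  list(C = C, df = 2L * k, p_value = pchisq(C, df = 2 * k, lower.tail = FALSE))
}

#' C-statistic information criterion, small-sample corrected
#'
#' `CICc = C + 2 q n / (n - 1 - q)`, the small-sample information
#' criterion used to compare path models, with `q` the number of estimated
#' parameters and `n` the number of taxa scored.
#'
#' @param C Fisher's C (non-negative).
#' @param q Parameter count.
#' @param n Sample size; must exceed `q + 1`.
#' @return Numeric CICc.
#' @export
cicc <- function(C, q, n) {
  if (any(n <= q + 1)) abort("insufficient sample for correction (need n > q + 1)")
  C + 2 * q * n / (n - 1 - q)
}

# Package-wide claim cache (canonical claim + data fingerprint -> log p).
the_claim_cache <- new.env(parent = emptyenv())

#' Clear the process-wide d-separation claim cache
#' @export
clear_claim_cache <- function() {
  rm(list = ls(the_claim_cache), envir = the_claim_cache)
  invisible(NULL)
}

#' Score every model in a DAG space by phylogenetic d-separation
#'
#' For each model: derive its d-separation basis set, test each
#' independence claim with a phylogenetic regression (the p-value of the
#' claimed-independent predictor given the conditioning set), combine into
#' Fisher's C, and compute CICc with `q = |edges| + |nodes|` (the path
#' coefficients plus one residual variance per node) or `q = |edges|`.
#' Each canonically keyed claim is fitted at most once process-wide; the
#' per-model pass is vectorised across the whole space.
#'
#' All models are scored on the same globally listwise-deleted sample so
#' CICc values are comparable.
#'
#' @param space A [enumerate_dags()] result (`dag_space`).
#' @param data Trait table (taxon column + model variables).
#' @param tree [ape::phylo] phylogeny.
#' @inheritParams pgls_fit
#' @param q_def `"edges_plus_nodes"` (default) or `"edges"`.
#' @param cache Use the process-wide claim cache (turn off to force
#'   claim-by-claim refits; results are identical).
#' @return A `model_scores` tibble sorted by CICc (ties: smaller C, fewer
#'   edges, lexicographic edge list) with columns `model_id, n_edges, k, q,
#'   C, C_pvalue, CICc, n, unscored`; the `dag_space` and cache statistics
#'   travel as attributes.
#' @export
score_models <- function(space, data, tree,
                         transform = c("lambda", "ou"),
                         binary_method = c("linear", "logistic"),
                         q_def = c("edges_plus_nodes", "edges"),
                         cache = TRUE, fixed_parameter = NULL,
                         alpha_max = NULL) {
  stopifnot(inherits(space, "dag_space"))
  transform <- match.arg(transform)
  binary_method <- match.arg(binary_method)
  q_def <- match.arg(q_def)
  nodes <- space$nodes
  n_nodes <- length(nodes)

  aligned <- align_to_tree(data, tree, nodes)
  aligned <- aligned[complete.cases(aligned[nodes]), , drop = FALSE]
  n <- nrow(aligned)
  if (n < n_nodes + 2) abort("too few taxa with complete data across model variables")
  sub <- prune_tree(tree, aligned$taxon)

  M <- space$membership
  N <- nrow(M)
  fi <- match(space$edges$from, nodes)
  ti <- match(space$edges$to, nodes)
  m <- length(fi)

  fingerprint <- hash(list(aligned, ape::write.tree(sub), transform,
                           binary_method, fixed_parameter, alpha_max))
  stats_env <- new.env(parent = emptyenv())
  stats_env$hits <- 0L
  stats_env$fits <- 0L

  fit_claim <- function(resp, pred, cond) {
    key <- paste0(fingerprint, "::", claim_key(resp, pred, cond))
    if (cache && !is.null(the_claim_cache[[key]])) {
      stats_env$hits <- stats_env$hits + 1L
      return(the_claim_cache[[key]])
    }
    stats_env$fits <- stats_env$fits + 1L
    val <- tryCatch({
      fit <- pgls_fit(aligned, sub, resp, pred, cond,
                      transform = transform, binary_method = binary_method,
                      fixed_parameter = fixed_parameter,
                      alpha_max = alpha_max)
      p <- fit$coefficients$p.value[fit$coefficients$term == pred]
      list(log_p = log(pmax(p, 1e-16)), error = NA_character_)
    }, error = function(e) list(log_p = NA_real_,
                                error = conditionMessage(e)))
    if (cache) the_claim_cache[[key]] <- val
    val
  }

  # ---- vectorised per-model structure ----------------------------------
  edge_col <- function(a, b) {
    j <- which(fi == a & ti == b)
    if (length(j)) M[, j] else rep(FALSE, N)
  }
  # parent bitmasks per node (bit = parent's node index)
  parmask <- matrix(0L, N, n_nodes)
  for (v in seq_len(n_nodes)) {
    into <- which(ti == v)
    if (length(into)) {
      parmask[, v] <- as.integer(M[, into, drop = FALSE] %*%
                                   2L^(fi[into] - 1L))
    }
  }
  # transitive closure per model (Floyd-Warshall over vectorised booleans)
  reach <- vector("list", n_nodes)
  for (a in seq_len(n_nodes)) {
    reach[[a]] <- vector("list", n_nodes)
    for (b in seq_len(n_nodes)) {
      reach[[a]][[b]] <- if (a == b) rep(FALSE, N) else edge_col(a, b)
    }
  }
  for (k in seq_len(n_nodes)) {
    for (a in seq_len(n_nodes)) {
      if (a == k) next
      rak <- reach[[a]][[k]]
      if (!any(rak)) next
      for (b in seq_len(n_nodes)) {
        if (b == a || b == k) next
        reach[[a]][[b]] <- reach[[a]][[b]] | (rak & reach[[k]][[b]])
      }
    }
  }

  n_edges <- as.integer(rowSums(M))
  k_claims <- as.integer(n_nodes * (n_nodes - 1) / 2 - n_edges)
  C <- numeric(N)
  bad <- rep(NA_character_, N)

  pairs <- if (n_nodes >= 2) combn(n_nodes, 2) else matrix(0L, 2, 0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    nonadj <- !(edge_col(a, b) | edge_col(b, a))
    if (!any(nonadj)) next
    cm <- bitwOr(parmask[, a], parmask[, b])
    # strip the pair's own bits (can appear via the other member's parents
    # only when adjacent, but keep the guard explicit)
    cm <- bitwAnd(cm, bitwNot(bitwOr(2L^(a - 1L), 2L^(b - 1L))))
    resp_is_a <- reach[[b]][[a]]   # b reaches a => a is downstream
    code <- cm * 2L + as.integer(resp_is_a)
    codes_here <- unique(code[nonadj])
    for (cd in codes_here) {
      sel <- nonadj & code == cd
      mask <- cd %/% 2L
      cond <- nodes[which(bitwAnd(mask, 2L^(seq_len(n_nodes) - 1L)) > 0L)]
      if (cd %% 2L == 1L) {
        resp <- nodes[a]; pred <- nodes[b]
      } else {
        resp <- nodes[b]; pred <- nodes[a]
      }
      res <- fit_claim(resp, pred, cond)
      if (is.na(res$log_p)) {
        bad[sel] <- ifelse(is.na(bad[sel]), res$error, bad[sel])
      } else {
        C[sel] <- C[sel] - 2 * res$log_p
      }
    }
  }

  q <- if (q_def == "edges_plus_nodes") n_edges + n_nodes else n_edges
  CICc_val <- ifelse(n > q + 1, C + 2 * q * n / (n - 1 - q), NA_real_)
  bad[is.na(bad) & n <= q + 1] <- "insufficient sample for CICc correction"
  CICc_val[!is.na(bad)] <- NA_real_
  C_pvalue <- ifelse(k_claims > 0,
                     pchisq(C, df = 2 * k_claims, lower.tail = FALSE), 1)

  # lexicographic edge-list tie-break: earlier canonical edge = most
  # significant bit, larger code first within equal edge counts
  lex_code <- if (m) drop(M %*% 2^((m - 1):0)) else numeric(N)
  out <- tibble::tibble(
    model_id = seq_len(N),
    n_edges = n_edges,
    k = k_claims,
    q = as.integer(q),
    C = C,
    C_pvalue = C_pvalue,
    CICc = CICc_val,
    n = n,
    unscored = bad
  )
  ord <- order(is.na(out$CICc), out$CICc, out$C, out$n_edges, -lex_code)
  out <- out[ord, ]
  attr(out, "space") <- space
  attr(out, "aligned") <- aligned
  attr(out, "tree") <- sub
  attr(out, "config") <- list(transform = transform,
                              binary_method = binary_method, q_def = q_def,
                              fixed_parameter = fixed_parameter,
                              alpha_max = alpha_max)
  attr(out, "cache_stats") <- list(hits = stats_env$hits,
                                   fits = stats_env$fits,
                                   enabled = cache)
  class(out) <- c("model_scores", class(out))
  out
}

#' Retain the best-supported models and weight them
#'
#' Keeps models with `CICc - min(CICc) <= threshold` and assigns Akaike
#' weights `w_i = exp(-delta_i / 2) / sum(exp(-delta_j / 2))` over the
#' retained set.
#'
#' @param scores A `model_scores` tibble.
#' @param threshold CICc window (default 2).
#' @return The retained rows with `delta` and `weight` columns; attributes
#'   carried over.
#' @export
best_set <- function(scores, threshold = 2) {
  ok <- scores[is.na(scores$unscored), , drop = FALSE]
  if (!nrow(ok)) abort("no scored models")
  best <- min(ok$CICc)
  ok$delta <- ok$CICc - best
  ret <- ok[ok$delta <= threshold, , drop = FALSE]
  rel <- exp(-ret$delta / 2)
  ret$weight <- rel / sum(rel)
  for (a in c("space", "aligned", "tree", "config")) {
    attr(ret, a) <- attr(scores, a)
  }
  class(ret) <- unique(c("model_scores", class(ret)))
  ret
}

# Pure averaging arithmetic over per-model path-coefficient tables.
# `per_model` is a list of tibbles (from, to, coefficient, se), one per
# retained model, parallel to `weights` (summing to 1 over the retained
# set). Conditional mode renormalises weights within the models containing
# each path; full mode counts absent models as coefficient 0 with zero SE.
average_paths <- function(per_model, weights, mode = "conditional",
                          ci_multiplier = 1.96) {
  stopifnot(length(per_model) == length(weights))
  all_fits <- dplyr::bind_rows(lapply(seq_along(per_model), function(i) {
    d <- per_model[[i]][c("from", "to", "coefficient", "se")]
    d$weight <- rep(weights[i], nrow(d))
    d
  }))
  if (!nrow(all_fits)) {
    return(tibble::tibble(from = character(), to = character(),
                          coefficient = numeric(), se = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          n_models = integer(), total_weight = numeric(),
                          excluded = logical()))
  }
  paths <- all_fits |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::group_modify(function(d, key) {
      w <- d$weight
      tw <- sum(w)
      if (mode == "conditional") {
        wr <- w / tw
        est <- sum(wr * d$coefficient)
        se <- sum(wr * sqrt(d$se^2 + (d$coefficient - est)^2))
      } else {
        est <- sum(w * d$coefficient)   # absent models contribute 0
        se <- sum(w * sqrt(d$se^2 + (d$coefficient - est)^2)) +
          (1 - tw) * abs(0 - est)
      }
      tibble::tibble(coefficient = est, se = se,
                     ci_low = est - ci_multiplier * se,
                     ci_high = est + ci_multiplier * se,
                     n_models = nrow(d), total_weight = tw)
    }) |>
    dplyr::ungroup()
  paths$excluded <- paths$ci_low <= 0 & paths$ci_high >= 0
  paths[order(paths$from, paths$to), ]
}

# Standardised path coefficients of one model: each child regressed on its
# parents (PGLS on standardised variables). Cached per (child, parent-set)
# within one averaging pass.
model_path_fits <- function(model, aligned, tree, config, fit_cache) {
  ed <- model$edges
  if (!nrow(ed)) {
    return(tibble::tibble(from = character(), to = character(),
                          coefficient = numeric(), se = numeric()))
  }
  children <- unique(ed$to)
  rows <- lapply(children, function(v) {
    pars <- sort(ed$from[ed$to == v])
    key <- paste0(v, "~", paste(pars, collapse = "+"))
    if (is.null(fit_cache[[key]])) {
      fit <- pgls_fit(aligned, tree, v, pars,
                      transform = config$transform,
                      binary_method = config$binary_method,
                      fixed_parameter = config$fixed_parameter,
                      alpha_max = config$alpha_max,
                      standardise = TRUE)
      co <- fit$coefficients[fit$coefficients$term %in% pars, ]
      fit_cache[[key]] <- tibble::tibble(from = co$term, to = v,
                                         coefficient = co$estimate,
                                         se = co$std.error)
    }
    fit_cache[[key]]
  })
  dplyr::bind_rows(rows)
}

#' Conditionally averaged path model
#'
#' Averages standardised path coefficients across the retained best-fitting
#' models. Under conditional averaging (default) a path's coefficient is
#' the weighted mean over only the models that contain that path, with the
#' weights renormalised within that subset; under full averaging absent
#' models contribute a coefficient of zero at their full weight. The
#' averaged standard error includes the between-model spread,
#' `se = sum w_i sqrt(se_i^2 + (b_i - b_avg)^2)`, and the confidence
#' interval is `b_avg +/- ci_multiplier * se`. Paths whose CI spans zero
#' are flagged `excluded`; unordered pairs present in both orientations
#' across the retained set are flagged bidirectional.
#'
#' @param retained A [best_set()] result.
#' @param mode `"conditional"` (default) or `"full"`.
#' @param ci_multiplier CI half-width in SE units (default 1.96).
#' @return An object of class `averaged_model`: `paths` tibble `(from, to,
#'   coefficient, se, ci_low, ci_high, n_models, total_weight, excluded)`,
#'   `bidirectional_pairs`, `excluded_paths`, `mode`, `ci_multiplier`.
#' @export
average_models <- function(retained, mode = c("conditional", "full"),
                           ci_multiplier = 1.96) {
  mode <- match.arg(mode)
  stopifnot(inherits(retained, "model_scores"), !is.null(retained$weight))
  space <- attr(retained, "space")
  aligned <- attr(retained, "aligned")
  tree <- attr(retained, "tree")
  config <- attr(retained, "config")
  fit_cache <- new.env(parent = emptyenv())

  per_model <- lapply(seq_len(nrow(retained)), function(i) {
    model <- space_model(space, retained$model_id[i])
    fits <- model_path_fits(model, aligned, tree, config, fit_cache)
    if (nrow(fits)) fits$weight <- retained$weight[i]
    fits$model_id <- rep(retained$model_id[i], nrow(fits))
    fits
  })
  paths <- average_paths(per_model, retained$weight, mode = mode,
                         ci_multiplier = ci_multiplier)
  bidir <- if (nrow(paths)) {
    pair_key <- paste(pmin(paths$from, paths$to),
                      pmax(paths$from, paths$to), sep = " <-> ")
    unique(pair_key[duplicated(pair_key)])
  } else {
    character(0)
  }
  structure(
    list(paths = paths,
         bidirectional_pairs = bidir,
         excluded_paths = paths[paths$excluded, c("from", "to")],
         mode = mode, ci_multiplier = ci_multiplier),
    class = "averaged_model"
  )
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Averaged path model (", x$mode, " averaging, ",
      nrow(x$paths), " paths, ", length(x$bidirectional_pairs),
      " bidirectional pair(s))\n", sep = "")
  print(as.data.frame(x$paths), digits = 3)
  invisible(x)
}

#' @export
tidy.averaged_model <- function(x, ...) x$paths

#' Exploratory phylogenetic path analysis
#'
#' The full pipeline: enumerate every DAG permitted by the constraints,
#' score each by phylogenetic d-separation (Fisher's C, CICc), retain the
#' models within `delta_threshold` CICc of the best, and average their
#' standardised path coefficients into a single summary causal model.
#'
#' @param data Trait table (taxon column plus the model variables).
#' @param tree [ape::phylo] phylogeny.
#' @param constraints A [constraint_spec()] or `NULL`.
#' @param variables Variables to model (default: every non-taxon column).
#' @param delta_threshold CICc retention window (default 2).
#' @param averaging `"conditional"` or `"full"`.
#' @param ci_multiplier CI half-width in SE units.
#' @param seed Recorded in the report (the pipeline itself is
#'   deterministic).
#' @inheritParams score_models
#' @inheritParams enumerate_dags
#' @return An object of class `phylo_path`: the scored space, retained
#'   set, averaged model, DOT render of the averaged model (excluded paths
#'   omitted), counts and configuration.
#' @export
phylo_path_explore <- function(data, tree, constraints = NULL,
                               variables = NULL, delta_threshold = 2,
                               transform = c("lambda", "ou"),
                               binary_method = c("linear", "logistic"),
                               q_def = c("edges_plus_nodes", "edges"),
                               averaging = c("conditional", "full"),
                               ci_multiplier = 1.96, max_nodes = 7,
                               max_models = 2e6, cache = TRUE, seed = 1L) {
  transform <- match.arg(transform)
  binary_method <- match.arg(binary_method)
  q_def <- match.arg(q_def)
  averaging <- match.arg(averaging)
  taxon_col <- guess_taxon_col(data)
  variables <- variables %||% setdiff(names(data), taxon_col)
  # validate before any fitting
  aligned <- align_to_tree(data, tree, variables)
  space <- enumerate_dags(variables, constraints, max_nodes = max_nodes,
                          max_models = max_models)
  scores <- score_models(space, data, tree, transform = transform,
                         binary_method = binary_method, q_def = q_def,
                         cache = cache)
  retained <- best_set(scores, threshold = delta_threshold)
  averaged <- average_models(retained, mode = averaging,
                             ci_multiplier = ci_multiplier)
  shown <- averaged$paths[!averaged$paths$excluded, , drop = FALSE]
  dot <- graph_dot(variables, shown[c("from", "to")],
                   coefficients = shown, name = "averaged")
  structure(
    list(n_models = n_models(space),
         n = scores$n[1],
         variables = variables,
         scores = scores,
         retained = retained,
         averaged = averaged,
         best_cicc = min(retained$CICc),
         dot = dot,
         seed = as.integer(seed),
         cache_stats = attr(scores, "cache_stats"),
         config = list(delta_threshold = delta_threshold,
                       transform = transform,
                       binary_method = binary_method, q_def = q_def,
                       averaging = averaging,
                       ci_multiplier = ci_multiplier)),
    class = "phylo_path"
  )
}

#' @export
print.phylo_path <- function(x, ...) {
  cat("Exploratory phylogenetic path analysis\n",
      "  models evaluated : ", format(x$n_models, big.mark = ","), "\n",
      "  taxa scored      : ", x$n, "\n",
      "  best CICc        : ", signif(x$best_cicc, 6), "\n",
      "  retained (delta <= ", x$config$delta_threshold, ") : ",
      nrow(x$retained), "\n\n", sep = "")
  print(x$averaged)
  invisible(x)
}

#' @export
glance.phylo_path <- function(x, ...) {
  tibble::tibble(
    n_models = x$n_models,
    n = x$n,
    best_cicc = x$best_cicc,
    n_retained = nrow(x$retained),
    n_paths = nrow(x$averaged$paths),
    n_excluded = sum(x$averaged$paths$excluded),
    n_bidirectional = length(x$averaged$bidirectional_pairs)
  )
}

#' @export
tidy.phylo_path <- function(x, ...) x$averaged$paths

#' Serialise an exploration report as canonical JSON
#'
#' Deterministic given identical inputs/configuration; numbers are written
#' at full precision.
#'
#' @param x A `phylo_path` object.
#' @param file Optional output path.
#' @return The JSON string (invisibly when written to file).
#' @export
report_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "phylo_path"))
  top <- utils::head(as.data.frame(x$retained[
    c("model_id", "n_edges", "k", "q", "C", "C_pvalue", "CICc", "delta",
      "weight")]), 100)
  payload <- list(
    n_models = x$n_models,
    n_taxa = x$n,
    variables = x$variables,
    best_cicc = x$best_cicc,
    n_retained = nrow(x$retained),
    retained = top,
    averaged_paths = as.data.frame(x$averaged$paths),
    bidirectional_pairs = x$averaged$bidirectional_pairs,
    dot = x$dot,
    seed = x$seed,
    claims_evaluated = x$cache_stats$hits + x$cache_stats$fits,
    config = x$config
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}
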