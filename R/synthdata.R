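#' Simulate a phylogeny
#'
#' Two generators: `"birth_death"` (standard birth-death tips via
#' [ape::rphylo()]) and `"classification_like"`, which mimics a tree built
#' from a nested classification — families of random sizes joined at the
#' root, unit branch length per classification level, ultrametric. The
#' classification-like root has exactly `n_families` children.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param model `"birth_death"` or `"classification_like"`.
#' @param n_families Number of families for the classification-like model.
#' @param birth,death Birth-death rates.
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return An [ape::phylo] object with tips `t1 ... tN`.
#' @export
simulate_tree <- function(n_taxa, model = c("birth_death", "classification_like"),
                          n_families = NULL, birth = 1, death = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_taxa >= 2)
  if (model == "birth_death") {
    tree <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = death))
    tree$tip.label <- paste0("t", seq_len(n_taxa))
    return(validate_phylo(tree))
  }
  n_families <- n_families %||% max(2L, round(n_taxa / 2))
  if (n_families > n_taxa) abort("more families than taxa")
  if (n_families < 2) abort("need at least 2 families")
  with_seed(seed, {
    sizes <- tabulate(sample.int(n_families, n_taxa - n_families,
                                 replace = TRUE), n_families) + 1L
    taxa <- paste0("t", seq_len(n_taxa))
    fam <- rep(paste0("F", sprintf("%02d", seq_len(n_families))), sizes)
    paths <- vector("list", n_taxa)
    idx <- 1L
    for (f in seq_len(n_families)) {
      members <- which(fam == paste0("F", sprintf("%02d", f)))
      if (sizes[f] >= 3) {
        # random second classification level within larger families
        n_sub <- sample.int(max(1L, sizes[f] - 1L), 1)
        sub <- sample.int(n_sub, sizes[f], replace = TRUE)
        for (j in seq_along(members)) {
          paths[[members[j]]] <- c(fam[members[j]],
                                   if (n_sub > 1) paste0(fam[members[j]], "g", sub[j]))
        }
      } else {
        for (j in members) paths[[j]] <- fam[j]
      }
    }
    names(paths) <- taxa
    tree_from_classification(paths)
  })
}

#' Simulate traits with a known generating causal structure
#'
#' Exogenous variables (no parents in `dag`) are drawn as Brownian traits
#' on the tree (multivariate normal with the tree's correlation
#' structure). Each endogenous variable is the coefficient-weighted sum of
#' its (standardised, observed) parents plus a residual whose correlation
#' structure blends the tree with independence:
#' `Var(resid) ~ noise_signal * C_tree + (1 - noise_signal) * I`, scaled so
#' each variable has unit marginal variance before standardisation.
#' Variables listed in `binary_vars` are liability-thresholded at the
#' empirical quantile that yields exactly the requested prevalence (count
#' of present states = `round(prevalence * n)`), which keeps fixture
#' marginals exact.
#'
#' @param tree [ape::phylo] phylogeny.
#' @param dag A [dag_model()] naming the variables.
#' @param coefficients Per-edge path coefficients: named numeric vector
#'   (`c("A -> B" = 0.8)`) or tibble `(from, to, coefficient)`; default 0.5
#'   for every edge.
#' @param binary_vars Named numeric vector of target prevalences in
#'   `(0, 1)` for the variables to binarise.
#' @param noise_signal Phylogenetic weight of endogenous residuals in
#'   `[0, 1]` (1 = fully Brownian residuals).
#' @param seed Integer seed.
#' @return Tibble with `taxon` plus one column per DAG node; continuous
#'   variables standardised, binary variables 0/1.
#' @export
simulate_traits <- function(tree, dag, coefficients = NULL,
                            binary_vars = numeric(), noise_signal = 1,
                            seed = 1L) {
  stopifnot(inherits(dag, "dag_model"))
  if (noise_signal < 0 || noise_signal > 1) abort("noise_signal must be in [0, 1]")
  if (length(binary_vars)) {
    if (is.null(names(binary_vars)) ||
        !all(names(binary_vars) %in% dag$nodes)) {
      abort("binary_vars must be named after DAG nodes")
    }
    if (any(binary_vars <= 0 | binary_vars >= 1)) {
      abort("prevalences must lie in (0, 1)")
    }
  }
  coefs <- edge_coefficients(dag, coefficients)
  tree <- validate_phylo(tree)
  n <- ape::Ntip(tree)
  taxa <- tree$tip.label
  C_tree <- stats::cov2cor(ape::vcv.phylo(tree)[taxa, taxa])
  L_bm <- chol(C_tree)
  C_mix <- noise_signal * C_tree + (1 - noise_signal) * diag(n)
  L_mix <- chol(C_mix)
  topo <- topological_order(dag$edges, dag$nodes)

  with_seed(seed, {
    observed <- list()
    std_obs <- list()
    for (v in topo) {
      pars <- dag$edges$from[dag$edges$to == v]
      z <- rnorm(n)
      if (!length(pars)) {
        raw <- drop(crossprod(L_bm, z))
      } else {
        beta <- coefs$coefficient[match(paste(pars, v),
                                        paste(coefs$from, coefs$to))]
        systematic <- rowSums(mapply(function(p, b) b * std_obs[[p]], pars,
                                     beta))
        s_res <- sqrt(max(0.05, 1 - sum(beta^2)))
        raw <- systematic + s_res * drop(crossprod(L_mix, z))
      }
      if (sd(raw) == 0) abort(paste0("constant liability for ", v))
      if (v %in% names(binary_vars)) {
        k <- round(binary_vars[[v]] * n)
        if (k < 1 || k > n - 1) abort(paste0("unreachable prevalence for ", v))
        obs <- threshold_top_k(raw, k)
      } else {
        obs <- standardise(raw)
      }
      observed[[v]] <- obs
      std_obs[[v]] <- standardise(obs)
    }
    tibble::tibble(taxon = taxa, !!!observed[dag$nodes])
  })
}

edge_coefficients <- function(dag, coefficients) {
  ed <- dag$edges
  if (is.null(coefficients)) {
    return(tibble::tibble(from = ed$from, to = ed$to,
                          coefficient = rep(0.5, nrow(ed))))
  }
  if (is.numeric(coefficients) && !is.null(names(coefficients))) {
    parsed <- parse_edges(names(coefficients))
    coefficients <- tibble::tibble(from = parsed$from, to = parsed$to,
                                   coefficient = unname(coefficients))
  }
  stopifnot(all(c("from", "to", "coefficient") %in% names(coefficients)))
  key <- paste(ed$from, ed$to)
  got <- paste(coefficients$from, coefficients$to)
  if (!all(key %in% got)) {
    abort(paste0("missing coefficients for edges: ",
                 paste(setdiff(key, got), collapse = ", ")))
  }
  if (any(!is.finite(coefficients$coefficient))) abort("coefficients must be finite")
  tibble::tibble(from = ed$from, to = ed$to,
                 coefficient = coefficients$coefficient[match(key, got)])
}

#' Study-shaped synthetic fixture
#'
#' A complete synthetic dataset shaped like a cross-cultural
#' hunter-gatherer comparative study: 68 taxa in 35 families on a
#' classification-like tree; six variables — three binary socio-cultural
#' traits (`specialists` at 48/68 present, `food_storage` at 34/68,
#' `social_leadership` at 34/68), a continuous `pathogen_load` and two
#' continuous environmental variables (`env_predictability`,
#' `env_richness`); an exogeneity constraint specification (the two
#' environmental variables may only be predicted by each other;
#' `pathogen_load` may not be predicted by the three socio-cultural
#' variables); and a generating DAG in which environment drives pathogen
#' load and social leadership, these drive food storage, and food storage
#' drives professional specialists. This is a synthetic stand-in with a
#' known generator, not a reconstruction of any real database.
#'
#' @param seed Integer seed.
#' @param n_taxa,n_families Sample shape.
#' @param coefficients Optional per-edge coefficients overriding the
#'   defaults.
#' @param noise_signal Residual phylogenetic weight (see
#'   [simulate_traits()]).
#' @return List with `tree`, `traits`, `coords`, `constraints`, `dag`,
#'   `coefficients`, `binary_vars`, `seed`.
#' @export
hunter_gatherer_fixture <- function(seed = 1L, n_taxa = 68, n_families = 35,
                              coefficients = NULL, noise_signal = 1) {
  vars <- c("specialists", "food_storage", "social_leadership",
            "pathogen_load", "env_predictability", "env_richness")
  default_coefs <- c(
    "env_predictability -> pathogen_load" = -0.4,
    "env_richness -> pathogen_load" = 0.5,
    "env_predictability -> social_leadership" = 0.4,
    "env_richness -> social_leadership" = -0.4,
    "pathogen_load -> food_storage" = -0.5,
    "social_leadership -> food_storage" = 0.5,
    "food_storage -> specialists" = 0.8
  )
  dag <- dag_model(vars, names(default_coefs))
  coefs <- edge_coefficients(dag, coefficients %||% default_coefs)
  constraints <- constraint_spec(
    mutual_exogenous = list(c("env_predictability", "env_richness")),
    forbidden_parents = list(
      pathogen_load = c("specialists", "food_storage", "social_leadership")
    )
  )
  binary_vars <- c(specialists = 48 / 68, food_storage = 34 / 68,
                   social_leadership = 34 / 68)
  tree <- simulate_tree(n_taxa, "classification_like",
                        n_families = n_families, seed = seed)
  traits <- simulate_traits(tree, dag, coefs, binary_vars = binary_vars,
                            noise_signal = noise_signal, seed = seed + 1000L)
  coords <- with_seed(seed + 2000L, {
    fam_of <- family_of_tips(tree)
    fams <- unique(fam_of)
    cen_lat <- runif(length(fams), -55, 70)
    cen_lon <- runif(length(fams), -175, 175)
    i <- match(fam_of, fams)
    tibble::tibble(
      taxon = tree$tip.label,
      lat = pmin(pmax(cen_lat[i] + runif(length(fam_of), -5, 5), -90), 90),
      lon = pmin(pmax(cen_lon[i] + runif(length(fam_of), -5, 5), -180), 180)
    )
  })
  list(tree = tree, traits = traits, coords = coords,
       constraints = constraints, dag = dag, coefficients = coefs,
       binary_vars = binary_vars, seed = as.integer(seed))
}

# Tip-to-family map: the root's child clade each tip belongs to.
family_of_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(n_tip), function(tip) {
    v <- tip
    while (parent[v] != root && parent[v] != 0L) v <- parent[v]
    v
  }, integer(1))
}

#' Write a fixture to a directory
#'
#' Emits `tree.nwk`, `traits.csv`, `coords.csv`, `constraints.json`,
#' `dag.json` and a `metadata.json` sidecar carrying the seed.
#'
#' @param fixture A [hunter_gatherer_fixture()]-style list.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(fixture$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(fixture$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  if (!is.null(fixture$coords)) {
    utils::write.csv(fixture$coords, file.path(dir, "coords.csv"),
                     row.names = FALSE)
  }
  cons <- fixture$constraints
  jsonlite::write_json(
    list(mutual_exogenous = cons$mutual_exogenous,
         forbidden_parents = cons$forbidden_parents,
         forbidden_edges = if (nrow(cons$forbidden_edges)) {
           paste(cons$forbidden_edges$from, "->", cons$forbidden_edges$to)
         } else {
           character(0)
         }),
    file.path(dir, "constraints.json")
  )
  jsonlite::write_json(
    list(nodes = fixture$dag$nodes,
         edges = as.data.frame(fixture$coefficients)),
    file.path(dir, "dag.json"), digits = NA
  )
  jsonlite::write_json(
    list(seed = fixture$seed, n_taxa = ape::Ntip(fixture$tree),
         binary_vars = as.list(fixture$binary_vars %||% list())),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a fixture directory back
#'
#' Inverse of [write_fixture()].
#'
#' @param dir Fixture directory.
#' @return List with `tree`, `traits`, `coords` (if present),
#'   `constraints`, `dag`, `coefficients`, `seed`.
#' @export
read_fixture <- function(dir) {
  tree <- read_newick(file = file.path(dir, "tree.nwk"))
  traits <- tibble::as_tibble(utils::read.csv(file.path(dir, "traits.csv")))
  coords_path <- file.path(dir, "coords.csv")
  coords <- if (file.exists(coords_path)) {
    tibble::as_tibble(utils::read.csv(coords_path))
  }
  cj <- jsonlite::read_json(file.path(dir, "constraints.json"))
  constraints <- constraint_spec(
    mutual_exogenous = lapply(cj$mutual_exogenous, function(g)
      as.character(unlist(g))),
    forbidden_parents = lapply(cj$forbidden_parents, function(g)
      as.character(unlist(g))),
    forbidden_edges = as.character(unlist(cj$forbidden_edges))
  )
  dj <- jsonlite::read_json(file.path(dir, "dag.json"), simplifyVector = TRUE)
  edges <- as.data.frame(dj$edges)
  dag <- dag_model(unlist(dj$nodes), edges[c("from", "to")])
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  list(tree = tree, traits = traits, coords = coords,
       constraints = constraints, dag = dag,
       coefficients = tibble::as_tibble(edges), seed = meta$seed)
}
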