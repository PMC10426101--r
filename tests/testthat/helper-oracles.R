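# Shared fixtures and independent brute-force oracles.

tree_abc <- function() read_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- labels
  tr
}

# Independent patristic oracle: walk tip-to-tip paths through the parent
# map and sum edge lengths (no cophenetic, no matrix algebra).
brute_patristic <- function(tree) {
  n_tip <- ape::Ntip(tree)
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  out <- matrix(0, n_tip, n_tip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip - 1)) {
    pi <- path_to_root(i)
    for (j in (i + 1):n_tip) {
      pj <- path_to_root(j)
      mrca <- intersect(pi, pj)[1]
      di <- sum(elen[pi[seq_len(which(pi == mrca) - 1)]])
      dj <- sum(elen[pj[seq_len(which(pj == mrca) - 1)]])
      out[i, j] <- out[j, i] <- di + dj
    }
  }
  out
}

# Independent DAG-space oracle: iterate ALL subsets of the allowed edges
# and keep the acyclic ones (igraph::is_dag, an external cycle checker).
brute_force_dag_count <- function(nodes, constraints = NULL) {
  ae <- allowed_edges(nodes, constraints)
  m <- nrow(ae)
  stopifnot(m <= 16)
  count <- 0L
  for (code in 0:(2^m - 1)) {
    sel <- bitwAnd(code, 2^(seq_len(m) - 1)) > 0
    g <- igraph::graph_from_data_frame(ae[sel, , drop = FALSE],
                                       directed = TRUE,
                                       vertices = nodes)
    if (igraph::is_dag(g)) count <- count + 1L
  }
  count
}

# Uniform-ish random DAG: random permutation defines the causal order,
# edges kept forward with probability p.
random_dag <- function(n_nodes, p = 0.4) {
  nodes <- paste0("V", seq_len(n_nodes))
  ord <- sample(nodes)
  pairs <- t(combn(seq_len(n_nodes), 2))
  keep <- runif(nrow(pairs)) < p
  ed <- tibble::tibble(from = ord[pairs[keep, 1]], to = ord[pairs[keep, 2]])
  dag_model(nodes, ed)
}

random_constraints <- function(nodes) {
  cs <- list(mutual_exogenous = list(), forbidden_parents = list(),
             forbidden_edges = character())
  if (runif(1) < 0.6) {
    grp <- sample(nodes, sample(1:2, 1))
    cs$mutual_exogenous <- list(grp)
  }
  if (runif(1) < 0.6) {
    v <- sample(nodes, 1)
    others <- setdiff(nodes, v)
    cs$forbidden_parents <- setNames(
      list(sample(others, sample(seq_along(others), 1))), v
    )
  }
  if (runif(1) < 0.5) {
    a <- sample(nodes, 2)
    cs$forbidden_edges <- paste(a[1], "->", a[2])
  }
  constraint_spec(cs$mutual_exogenous, cs$forbidden_parents,
                  cs$forbidden_edges)
}

# Brownian tip simulation used by generator-backed tests.
simulate_bm <- function(tree, n_draws = 1) {
  C <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  L <- chol(stats::cov2cor(C))
  m <- crossprod(L, matrix(rnorm(nrow(C) * n_draws), nrow(C), n_draws))
  rownames(m) <- tree$tip.label
  m
}
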