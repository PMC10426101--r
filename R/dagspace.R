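#' Causal path model (labelled DAG)
#'
#' @param nodes Ordered character vector of variable names.
#' @param edges Directed edges: character vector of `"A -> B"` strings, a
#'   two-column data frame/matrix `(from, to)`, or empty.
#' @return An object of class `dag_model`: `nodes` and an `edges` tibble.
#' @export
dag_model <- function(nodes, edges = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  ed <- parse_edges(edges)
  unknown <- setdiff(c(ed$from, ed$to), nodes)
  if (length(unknown)) {
    abort(paste0("edges reference undeclared nodes: ",
                 paste(unique(unknown), collapse = ", ")))
  }
  if (any(ed$from == ed$to)) abort("self-edges are not allowed")
  if (anyDuplicated(paste(ed$from, ed$to))) abort("duplicate edges")
  if (!is_acyclic(ed, nodes)) abort("edges contain a directed cycle")
  structure(list(nodes = nodes, edges = ed), class = "dag_model")
}

parse_edges <- function(edges) {
  if (is.null(edges) || (is.atomic(edges) && length(edges) == 0)) {
    return(tibble::tibble(from = character(), to = character()))
  }
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad)) {
      abort(paste0("cannot parse edge string(s): ",
                   paste(edges[bad], collapse = "; ")))
    }
    return(tibble::tibble(from = trimws(vapply(parts, `[`, "", 1)),
                          to = trimws(vapply(parts, `[`, "", 2))))
  }
  ed <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(ed) < 2) abort("edges need columns (from, to)")
  tibble::tibble(from = as.character(ed[[1]]), to = as.character(ed[[2]]))
}

#' @export
print.dag_model <- function(x, ...) {
  cat("<dag_model> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Test whether a directed edge set is acyclic
#'
#' Kahn's algorithm: true iff a topological order exists.
#'
#' @param edges Edge specification as in [dag_model()].
#' @param nodes Node names; inferred from the edges when omitted.
#' @return Logical scalar.
#' @export
is_acyclic <- function(edges, nodes = NULL) {
  ed <- parse_edges(edges)
  nodes <- nodes %||% unique(c(ed$from, ed$to))
  !is.null(topological_order(ed, nodes))
}

# Kahn topological sort with deterministic tie-break (declared node order);
# NULL when cyclic.
topological_order <- function(edges, nodes) {
  n <- length(nodes)
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  indeg <- tabulate(ti, nbins = n)
  alive <- rep(TRUE, n)
  order <- integer(0)
  repeat {
    avail <- which(alive & indeg == 0)
    if (!length(avail)) break
    v <- avail[1]
    order <- c(order, v)
    alive[v] <- FALSE
    out <- which(fi == v & alive[ti])
    if (length(out)) indeg[ti[out]] <- indeg[ti[out]] - 1L
  }
  if (any(alive)) NULL else nodes[order]
}

#' Constraint declaration for the searchable model space
#'
#' @param mutual_exogenous List of character vectors; the members of each
#'   group may be predicted only by members of the same group (they are
#'   otherwise exogenous).
#' @param forbidden_parents Named list: for variable `v`, a character
#'   vector of variables that may never be parents of `v`.
#' @param forbidden_edges Character vector of `"A -> B"` strings removed
#'   from the space.
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(mutual_exogenous = list(),
                            forbidden_parents = list(),
                            forbidden_edges = character()) {
  structure(list(mutual_exogenous = lapply(mutual_exogenous, as.character),
                 forbidden_parents = lapply(forbidden_parents, as.character),
                 forbidden_edges = parse_edges(forbidden_edges)),
            class = "constraint_spec")
}

#' Edges permitted under a constraint declaration
#'
#' @param nodes Node names.
#' @param constraints A [constraint_spec()] or `NULL` (no constraints).
#' @return Tibble `(from, to)` of all permitted directed edges, in
#'   canonical order.
#' @export
allowed_edges <- function(nodes, constraints = NULL) {
  stopifnot(length(nodes) >= 1)
  grid <- expand.grid(to = nodes, from = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, c("from", "to")]
  ok <- rep(TRUE, nrow(grid))
  if (!is.null(constraints)) {
    unknown <- setdiff(
      unique(c(unlist(constraints$mutual_exogenous),
               names(constraints$forbidden_parents),
               unlist(constraints$forbidden_parents),
               constraints$forbidden_edges$from,
               constraints$forbidden_edges$to)),
      nodes
    )
    if (length(unknown)) {
      abort(paste0("constraints reference unknown variables: ",
                   paste(unknown, collapse = ", ")))
    }
    for (grp in constraints$mutual_exogenous) {
      ok <- ok & !(grid$to %in% grp & !(grid$from %in% grp))
    }
    for (v in names(constraints$forbidden_parents)) {
      ok <- ok & !(grid$to == v &
                     grid$from %in% constraints$forbidden_parents[[v]])
    }
    if (nrow(constraints$forbidden_edges)) {
      key <- paste(grid$from, grid$to)
      fkey <- paste(constraints$forbidden_edges$from,
                    constraints$forbidden_edges$to)
      ok <- ok & !(key %in% fkey)
    }
  }
  grid <- grid[ok, , drop = FALSE]
  grid <- grid[order(match(grid$from, nodes), match(grid$to, nodes)), ]
  tibble::as_tibble(grid)
}

#' Enumerate every DAG in the constrained model space
#'
#' Yields the complete set of labelled directed acyclic graphs over `nodes`
#' whose every edge is permitted by `constraints`. The space is generated
#' deterministically by decomposing the permitted-edge digraph into
#' strongly connected components: a directed cycle can only use edges
#' internal to one component, so the space is the Cartesian product of the
#' acyclic edge subsets of each component with free inclusion of all
#' between-component edges.
#'
#' @inheritParams allowed_edges
#' @param max_nodes Guard on node count (default 7); raise deliberately via
#'   this argument for larger problems.
#' @param max_models Guard on the size of the materialised space.
#' @param connected_only Keep only weakly connected models (off by
#'   default: "all possible models" includes disconnected ones).
#' @return An object of class `dag_space`: `nodes`, `edges` (the permitted
#'   edge list) and `membership`, a logical model-by-edge matrix with one
#'   row per DAG. Use [n_models()] and [space_model()] to access models.
#' @export
enumerate_dags <- function(nodes, constraints = NULL, max_nodes = 7,
                           max_models = 2e6, connected_only = FALSE) {
  nodes <- as.character(nodes)
  if (length(nodes) > max_nodes) {
    abort(paste0("node limit exceeded (", length(nodes), " > ", max_nodes,
                 "); raise `max_nodes` to override"))
  }
  ae <- allowed_edges(nodes, constraints)
  parts <- space_blocks(nodes, ae, max_models = max_models)
  n_free <- length(parts$free)
  total <- prod(vapply(parts$block_sets, nrow, numeric(1)), 2^n_free)
  if (total > max_models) {
    abort(paste0("model space has ", format(total, big.mark = ","),
                 " DAGs > max_models = ", format(max_models, big.mark = ","),
                 "; raise `max_models` to override"))
  }
  m <- nrow(ae)
  N <- as.integer(total)
  membership <- matrix(FALSE, N, m)
  sizes <- c(vapply(parts$block_sets, nrow, integer(1)),
             if (n_free) 2L^n_free else integer(0))
  cols <- c(parts$blocks, if (n_free) list(parts$free) else NULL)
  mats <- c(parts$block_sets, if (n_free) list(bit_patterns(n_free)) else NULL)
  before <- 1L
  for (j in seq_along(sizes)) {
    idx <- rep(rep(seq_len(sizes[j]), each = before),
               length.out = N)
    membership[, cols[[j]]] <- mats[[j]][idx, , drop = FALSE]
    before <- before * sizes[j]
  }
  space <- structure(list(nodes = nodes, edges = ae, membership = membership,
                          constraints = constraints),
                     class = "dag_space")
  if (connected_only) {
    keep <- vapply(seq_len(N), function(i) {
      is_weakly_connected(nodes, ae[membership[i, ], , drop = FALSE])
    }, logical(1))
    space$membership <- membership[keep, , drop = FALSE]
  }
  space
}

# Partition permitted edges into intra-SCC blocks (which need a joint
# acyclicity enumeration) and free edges (never on a cycle).
space_blocks <- function(nodes, ae, max_models = Inf) {
  fi <- match(ae$from, nodes)
  ti <- match(ae$to, nodes)
  comp <- scc_components(length(nodes), fi, ti)
  intra <- which(comp[fi] == comp[ti])
  blocks <- if (length(intra)) {
    unname(split(intra, comp[fi[intra]]))
  } else {
    list()
  }
  block_sets <- lapply(blocks, function(eidx) {
    acyclic_subsets(fi[eidx], ti[eidx], length(nodes),
                    max_n = max_models)
  })
  list(blocks = blocks, block_sets = block_sets,
       free = setdiff(seq_len(nrow(ae)), intra))
}

# Kosaraju strongly connected components over node indices 1..n.
scc_components <- function(n, from_i, to_i) {
  adj <- split(to_i, factor(from_i, levels = seq_len(n)))
  radj <- split(from_i, factor(to_i, levels = seq_len(n)))
  visited <- rep(FALSE, n)
  order <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- s; path <- integer(0)
    visited[s] <- TRUE
    # iterative DFS recording finish order
    it <- list(list(v = s, i = 1L))
    while (length(it)) {
      fr <- it[[length(it)]]
      nbrs <- adj[[fr$v]]
      if (fr$i <= length(nbrs)) {
        it[[length(it)]]$i <- fr$i + 1L
        w <- nbrs[fr$i]
        if (!visited[w]) {
          visited[w] <- TRUE
          it[[length(it) + 1]] <- list(v = w, i = 1L)
        }
      } else {
        order <- c(order, fr$v)
        it[[length(it)]] <- NULL
      }
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (v in rev(order)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    stack <- v
    comp[v] <- cur
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in radj[[u]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

# All acyclic subsets of the given edges, as a logical matrix (subsets x
# edges). Depth-first over edges with an incrementally maintained
# transitive closure; including u->v is legal iff v does not already reach
# u.
acyclic_subsets <- function(from_i, to_i, n, max_n = Inf) {
  m <- length(from_i)
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 64)
  acc$k <- 0L
  push <- function(sel) {
    acc$k <- acc$k + 1L
    if (acc$k > max_n) {
      abort(paste0("model space exceeds max_models = ",
                   format(max_n, big.mark = ","),
                   "; raise `max_models` to override"))
    }
    if (acc$k > length(acc$rows)) {
      acc$rows <- c(acc$rows, vector("list", length(acc$rows)))
    }
    acc$rows[[acc$k]] <- sel
  }
  rec <- function(i, sel, reach) {
    if (i > m) {
      push(sel)
      return(invisible())
    }
    rec(i + 1L, sel, reach)
    u <- from_i[i]; v <- to_i[i]
    if (!reach[v, u]) {
      r2 <- reach
      anc <- c(which(r2[, u]), u)
      des <- c(which(r2[v, ]), v)
      r2[anc, des] <- TRUE
      sel[i] <- TRUE
      rec(i + 1L, sel, r2)
    }
  }
  rec(1L, logical(m), matrix(FALSE, n, n))
  do.call(rbind, acc$rows[seq_len(acc$k)])
}

bit_patterns <- function(f) {
  out <- matrix(FALSE, 2L^f, f)
  for (j in seq_len(f)) {
    out[, j] <- rep(rep(c(FALSE, TRUE), each = 2L^(j - 1L)),
                    length.out = 2L^f)
  }
  out
}

is_weakly_connected <- function(nodes, edges) {
  n <- length(nodes)
  if (n <= 1) return(TRUE)
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(c(ti[fi %in% frontier], fi[ti %in% frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Number of models in a DAG space
#' @param space A `dag_space`.
#' @return Integer count.
#' @export
n_models <- function(space) nrow(space$membership)

#' Count the constrained model space without materialising it
#'
#' @inheritParams enumerate_dags
#' @return Numeric count of DAGs.
#' @export
count_dags <- function(nodes, constraints = NULL) {
  ae <- allowed_edges(as.character(nodes), constraints)
  parts <- space_blocks(as.character(nodes), ae)
  prod(vapply(parts$block_sets, nrow, numeric(1)), 2^length(parts$free))
}

#' Materialise one model from a DAG space
#' @param space A `dag_space`.
#' @param i Model index (enumeration order is deterministic).
#' @return A [dag_model()].
#' @export
space_model <- function(space, i) {
  stopifnot(i >= 1, i <= n_models(space))
  dag_model(space$nodes, space$edges[space$membership[i, ], , drop = FALSE])
}

#' @export
print.dag_space <- function(x, ...) {
  cat("<dag_space> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " permitted edges, ",
      format(n_models(x), big.mark = ","), " DAGs\n", sep = "")
  invisible(x)
}

#' d-separation basis set of a DAG
#'
#' One independence claim per non-adjacent unordered pair `{x, y}`:
#' `x` independent of `y` given the union of the parents of `x` and the
#' parents of `y`. The regression response is whichever of the pair comes
#' later in the model's topological order (deterministic tie-break by
#' declared node order). Claims are returned in canonical sorted order.
#'
#' @param model A [dag_model()].
#' @return Tibble with columns `x, y, conditioning` (list column of sorted
#'   names), `response`, `predictor`, `claim_key`.
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "dag_model"))
  nodes <- model$nodes
  ed <- model$edges
  reach <- reachability(ed, nodes)
  adj <- paste(ed$from, ed$to)
  parents <- lapply(nodes, function(v) ed$from[ed$to == v])
  names(parents) <- nodes
  if (length(nodes) < 2) {
    return(tibble::tibble(x = character(), y = character(),
                          conditioning = list(), response = character(),
                          predictor = character(), claim_key = character()))
  }
  pairs <- combn(nodes, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    cond <- sort(setdiff(union(parents[[a]], parents[[b]]), c(a, b)))
    # response is downstream of the pair when comparable, else the later
    # node in declared order (a fixed, model-consistent topological rule)
    resp <- if (reach[match(b, nodes), match(a, nodes)]) a else b
    pred <- setdiff(c(a, b), resp)
    rows[[length(rows) + 1]] <- tibble::tibble(
      x = a, y = b, conditioning = list(cond), response = resp,
      predictor = pred,
      claim_key = claim_key(resp, pred, cond)
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(x = character(), y = character(),
                          conditioning = list(), response = character(),
                          predictor = character(), claim_key = character()))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$x, out$y), ]
}

# Boolean transitive closure (does i reach j by a directed path).
reachability <- function(edges, nodes) {
  n <- length(nodes)
  r <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    r[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- TRUE
  }
  for (k in seq_len(n)) {
    r <- r | (r[, k] %o% r[k, ])
  }
  r
}

claim_key <- function(response, predictor, conditioning) {
  paste0(response, "~", predictor, "|",
         paste(sort(conditioning), collapse = ","))
}

#' Render a path model as DOT
#'
#' Deterministic Graphviz DOT text. When coefficient annotations are given,
#' edge pen widths are proportional to the absolute coefficient and
#' negative coefficients are drawn red (positive black).
#'
#' @param model A [dag_model()].
#' @param coefficients Optional tibble `(from, to, coefficient)`.
#' @param name Graph name.
#' @return A single DOT string.
#' @export
to_dot <- function(model, coefficients = NULL, name = "model") {
  stopifnot(inherits(model, "dag_model"))
  graph_dot(model$nodes, model$edges, coefficients, name)
}

# DOT rendering without the acyclicity requirement (averaged models may
# carry both orientations of a pair).
graph_dot <- function(nodes, edges, coefficients = NULL, name = "model") {
  lines <- c(paste0("digraph ", name, " {"),
             "  rankdir=LR;",
             paste0("  \"", nodes, "\";"))
  ed <- edges
  if (nrow(ed)) {
    ed <- ed[order(match(ed$from, nodes), match(ed$to, nodes)), ]
    attrs <- rep("", nrow(ed))
    if (!is.null(coefficients)) {
      key <- paste(ed$from, ed$to)
      ck <- paste(coefficients$from, coefficients$to)
      co <- coefficients$coefficient[match(key, ck)]
      max_c <- max(abs(co), na.rm = TRUE)
      if (!is.finite(max_c) || max_c == 0) max_c <- 1
      w <- 0.5 + 3.5 * abs(co) / max_c
      col <- ifelse(co < 0, "red", "black")
      attrs <- ifelse(
        is.na(co), "",
        sprintf(" [penwidth=%.3f, color=%s, label=\"%.2f\"]", w, col, co)
      )
    }
    lines <- c(lines,
               paste0("  \"", ed$from, "\" -> \"", ed$to, "\"", attrs, ";"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Parse DOT produced by [to_dot()] back into a model
#'
#' Supports only the subset this package emits (round-trip helper).
#'
#' @param text DOT string.
#' @return A [dag_model()].
#' @export
from_dot <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  edge_lines <- grep("->", lines, value = TRUE)
  node_lines <- grep("^\\s*\"[^\"]+\"\\s*;\\s*$", lines, value = TRUE)
  nodes <- gsub("^\\s*\"|\"\\s*;\\s*$", "", node_lines)
  froms <- sub("^\\s*\"([^\"]+)\"\\s*->.*$", "\\1", edge_lines)
  tos <- sub("^.*->\\s*\"([^\"]+)\".*$", "\\1", edge_lines)
  dag_model(nodes, tibble::tibble(from = froms, to = tos))
}
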