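test_that("unconstrained enumeration matches brute force over edge subsets", {
  expect_equal(n_models(enumerate_dags(c("A", "B"))), 3)
  expect_equal(n_models(enumerate_dags(c("A", "B", "C"))), 25)
  expect_equal(n_models(enumerate_dags(c("A", "B", "C", "D"))), 543)
  expect_equal(brute_force_dag_count(c("A", "B", "C")), 25)
})

test_that("constrained enumeration matches the brute-force oracle", {
  withr::with_seed(64, {
    nodes <- c("A", "B", "C", "D")
    for (i in 1:6) {
      cs <- random_constraints(nodes)
      expect_equal(n_models(enumerate_dags(nodes, cs)),
                   brute_force_dag_count(nodes, cs),
                   info = paste("constraint draw", i))
    }
  })
})

test_that("every enumerated model is acyclic and constraint-compliant", {
  cs <- constraint_spec(
    mutual_exogenous = list(c("C", "D")),
    forbidden_parents = list(B = "A")
  )
  sp <- enumerate_dags(c("A", "B", "C", "D"), cs)
  ae_key <- paste(sp$edges$from, sp$edges$to)
  expect_false("A B" %in% ae_key)
  expect_false(any(grepl("^(A|B) (C|D)$", ae_key)))
  for (i in seq_len(n_models(sp))) {
    m <- space_model(sp, i)
    expect_true(is_acyclic(m$edges, m$nodes))
  }
  # no duplicates
  codes <- apply(sp$membership, 1, paste, collapse = "")
  expect_false(anyDuplicated(codes) > 0)
})

test_that("enumeration is deterministic/restartable and guarded", {
  s1 <- enumerate_dags(c("X", "Y", "Z"))
  s2 <- enumerate_dags(c("X", "Y", "Z"))
  expect_identical(s1$membership, s2$membership)
  expect_identical(s1$edges, s2$edges)
  expect_error(enumerate_dags(paste0("v", 1:8)), "node limit")
  expect_error(enumerate_dags(paste0("v", 1:6), max_models = 100),
               "max_models")
})

test_that("study-pattern constraints on six variables yield the SCC-product count", {
  vars <- c("S", "F", "L", "P", "E1", "E2")
  cs <- constraint_spec(
    mutual_exogenous = list(c("E1", "E2")),
    forbidden_parents = list(P = c("S", "F", "L"))
  )
  # independent factorisation: {E1,E2} cycle-capable pair (3 acyclic
  # subsets), {S,F,L} complete 3-tournament (25), 11 free edges
  expect_equal(count_dags(vars, cs), 3 * 25 * 2^11)
  ae <- allowed_edges(vars, cs)
  expect_equal(nrow(ae), 19)
})

test_that("is_acyclic agrees with igraph on random graphs", {
  withr::with_seed(12, {
    nodes <- paste0("n", 1:6)
    for (i in 1:50) {
      grid <- expand.grid(from = nodes, to = nodes,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, ]
      ed <- grid[runif(nrow(grid)) < 0.25, ]
      g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                         vertices = nodes)
      expect_equal(is_acyclic(ed, nodes), igraph::is_dag(g))
    }
  })
  expect_true(is_acyclic(character(), c("A", "B")))
  expect_false(is_acyclic(c("A -> B", "B -> A")))
})

test_that("basis sets obey the counting identity and claim structure", {
  chain <- dag_model(c("A", "B", "C"), c("A -> B", "B -> C"))
  b <- basis_set(chain)
  expect_equal(nrow(b), 1)
  expect_equal(b$response, "C")
  expect_equal(b$conditioning[[1]], "B")

  complete3 <- dag_model(c("A", "B", "C"),
                         c("A -> B", "A -> C", "B -> C"))
  expect_equal(nrow(basis_set(complete3)), 0)

  withr::with_seed(99, {
    for (i in 1:1000) {
      m <- random_dag(sample(2:7, 1), runif(1, 0.1, 0.9))
      v <- length(m$nodes)
      expect_equal(nrow(basis_set(m)), v * (v - 1) / 2 - nrow(m$edges))
    }
  })
})

test_that("dag_model validates its invariants", {
  expect_error(dag_model(c("A", "A"), character()), "duplicate node")
  expect_error(dag_model(c("A", "B"), "A -> A"), "self-edge")
  expect_error(dag_model(c("A", "B"), c("A -> B", "B -> A")), "cycle")
  expect_error(dag_model("A", "A -> B"), "undeclared")
})

test_that("DOT output is deterministic, styled, and round-trips", {
  m <- dag_model(c("A", "B", "C"), c("A -> B", "B -> C"))
  co <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                       coefficient = c(0.5, -0.25))
  dot <- to_dot(m, co)
  expect_identical(dot, to_dot(m, co))
  expect_match(dot, "color=red")
  expect_match(dot, "penwidth=4")
  back <- from_dot(dot)
  expect_equal(back$edges, m$edges)
  expect_setequal(back$nodes, m$nodes)

  empty <- dag_model(c("A", "B"), character())
  expect_equal(nrow(from_dot(to_dot(empty))$edges), 0)
})
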