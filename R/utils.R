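# Internal helpers shared across modules.

# Extract a named numeric trait vector (keyed by taxon) from a data frame.
# `data` must carry a taxon identifier column (default: "taxon", else the
# first character column).
trait_vector <- function(data, var, taxon_col = NULL) {
  stopifnot(is.data.frame(data))
  taxon_col <- taxon_col %||% guess_taxon_col(data)
  if (!var %in% names(data)) {
    abort(paste0("variable '", var, "' not found in trait table"))
  }
  setNames(data[[var]], as.character(data[[taxon_col]]))
}

guess_taxon_col <- function(data) {
  if ("taxon" %in% names(data)) return("taxon")
  is_chr <- vapply(data, function(x) is.character(x) || is.factor(x), logical(1))
  if (!any(is_chr)) {
    abort("trait table needs a 'taxon' column (or a character column of tip labels)")
  }
  names(data)[which(is_chr)[1]]
}

# Align a trait table to tree tips; errors list the offending labels.
align_to_tree <- function(data, tree, vars, taxon_col = NULL) {
  taxon_col <- taxon_col %||% guess_taxon_col(data)
  taxa <- as.character(data[[taxon_col]])
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicated taxa in trait table: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  missing_in_tree <- setdiff(taxa, tree$tip.label)
  if (length(missing_in_tree)) {
    abort(paste0("taxa absent from tree tips: ",
                 paste(missing_in_tree, collapse = ", ")))
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort(paste0("variables absent from trait table: ",
                 paste(missing_vars, collapse = ", ")))
  }
  out <- data[match(intersect(tree$tip.label, taxa), taxa),
              c(taxon_col, vars), drop = FALSE]
  names(out)[1] <- "taxon"
  tibble::as_tibble(out)
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0 && all(x %in% c(0, 1))
}

standardise <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardise a zero-variance variable")
  (x - mean(x)) / s
}

check_symmetric_distance <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0(name, " must be a square matrix"))
  }
  if (max(abs(m - t(m))) > 1e-8) abort(paste0(name, " must be symmetric"))
  if (max(abs(diag(m))) > 1e-8) abort(paste0(name, " must have a zero diagonal"))
  invisible(m)
}

upper_tri_vals <- function(m) m[upper.tri(m)]

# Deterministic RNG scoping: run `expr` under `seed` and restore the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

validation_error <- function(msg) {
  abort(msg, class = "phylodag_validation_error")
}
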