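#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: unique tip labels, at least two tips, and
#' branch lengths present everywhere. Edges without a stated length are set
#' to `default_length` with a warning, so classification-style trees written
#' without lengths can still feed covariance computations.
#'
#' @param text A Newick string, or `NULL` if `file` is given.
#' @param file Path to a Newick file.
#' @param default_length Branch length substituted for missing lengths.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(text = NULL, file = NULL, default_length = 1) {
  if (is.null(text) && is.null(file)) abort("supply `text` or `file`")
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))),
    warning = function(w) abort(paste0("Newick parse error: ", conditionMessage(w)))
  )
  if (is.null(tree)) {
    abort("Newick parse error: input could not be read as a tree")
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_phylo(tree, default_length = default_length)
}

validate_phylo <- function(tree, default_length = 1) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' tree")
  if (ape::Ntip(tree) < 2) abort("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dups, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    warn(paste0("tree has no branch lengths; defaulting all to ", default_length))
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warn(paste0("missing branch lengths defaulted to ", default_length))
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  tree
}

#' Write a tree as a Newick string
#'
#' @param tree An [ape::phylo] object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(file)
  }
}

#' Build a tree from a nested classification
#'
#' Converts a table of nested group memberships (for example a
#' Glottolog-style language classification: family, subgroup, ...) into a
#' rooted tree. Taxa sharing a prefix of groups share an internal node. Each
#' classification level contributes one unit of branch length and tip edges
#' are padded so all root-to-tip depths equal `max levels + 1` (the tree is
#' ultrametric). Single-member chains are collapsed, so a taxon that is the
#' sole member of its family attaches directly at the root.
#'
#' @param classification A data frame with a taxon column plus either (a)
#'   one `classification` column of semicolon-delimited group names, or (b)
#'   ordered columns `level1 ... levelK` (`NA`/`""` for unused deeper
#'   levels); alternatively a named list of character vectors.
#' @param taxon_col Name of the taxon column (default `"taxon"` or first
#'   character column).
#' @param scaling `"unit"` (one unit per level, default) or `"grafen"`
#'   (node heights proportional to clade tip counts, via
#'   [ape::compute.brlen()]).
#' @return An [ape::phylo] object whose tips are the taxa.
#' @export
tree_from_classification <- function(classification, taxon_col = NULL,
                                     scaling = c("unit", "grafen")) {
  scaling <- match.arg(scaling)
  paths <- classification_paths(classification, taxon_col)
  if (length(paths) < 2) abort("need at least 2 taxa to build a tree")
  if (anyDuplicated(names(paths))) abort("duplicated taxa in classification")
  if (any(vapply(paths, length, integer(1)) < 1)) {
    abort("every taxon needs at least one classification level")
  }
  max_depth <- max(vapply(paths, length, integer(1)))

  # Build the Newick text recursively; children are ordered by group name so
  # the construction is invariant to input row order.
  build <- function(members, depth) {
    # members: named list taxon -> remaining levels
    first <- vapply(members, function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
    tips_here <- names(members)[is.na(first)]
    # a tip reached here has consumed depth-1 levels; pad so every
    # root-to-tip distance equals max_depth + 1
    tip_parts <- if (length(tips_here)) {
      paste0(quote_label(sort(tips_here)), ":", max_depth - depth + 2)
    } else character(0)
    groups <- sort(unique(first[!is.na(first)]))
    grp_parts <- vapply(groups, function(g) {
      sub <- lapply(members[!is.na(first) & first == g], function(p) p[-1])
      paste0(build(sub, depth + 1), ":1")
    }, character(1))
    inner <- c(grp_parts, tip_parts)
    if (length(inner) == 1) {
      # unary chain: collapse by folding the edge length into the child
      collapse_single(inner)
    } else {
      paste0("(", paste(inner, collapse = ","), ")")
    }
  }
  txt <- paste0(build(paths, 1), ";")
  tree <- ape::read.tree(text = txt)
  tree <- ape::collapse.singles(tree)
  if (scaling == "grafen") tree <- ape::compute.brlen(tree, method = "Grafen")
  validate_phylo(tree)
}

# "(...):x" handled by caller appending ":1"; here we merge "label:a" into a
# subtree string so that wrapping it adds lengths rather than a unary node.
collapse_single <- function(part) {
  m <- regmatches(part, regexpr(":[0-9.]+$", part))
  len <- as.numeric(sub(":", "", m))
  base <- sub(":[0-9.]+$", "", part)
  # caller appends ":1"; pre-add the child's length by re-emitting with a
  # marker the caller's ":1" cannot see -- instead fold here: return base and
  # remember length via attribute is awkward in string land, so emit a
  # one-child clade and let ape::collapse.singles() merge the lengths.
  paste0("(", base, ":", len, ")")
}

quote_label <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.-]", x)
  x[bad] <- paste0("'", gsub("'", "_", x[bad]), "'")
  x
}

classification_paths <- function(classification, taxon_col = NULL) {
  if (is.list(classification) && !is.data.frame(classification)) {
    return(lapply(classification, as.character))
  }
  stopifnot(is.data.frame(classification))
  taxon_col <- taxon_col %||% guess_taxon_col(classification)
  taxa <- as.character(classification[[taxon_col]])
  other <- setdiff(names(classification), taxon_col)
  if (length(other) == 1 && any(grepl(";", classification[[other]]))) {
    paths <- strsplit(as.character(classification[[other]]), ";")
    paths <- lapply(paths, function(p) trimws(p[nzchar(trimws(p))]))
  } else {
    lev <- as.matrix(classification[other])
    paths <- lapply(seq_along(taxa), function(i) {
      p <- as.character(lev[i, ])
      p[!is.na(p) & nzchar(p)]
    })
  }
  names(paths) <- taxa
  paths
}

#' Read a classification table from file
#'
#' Accepts TSV/CSV with columns `taxon, level1..levelK`, or two columns
#' `taxon, classification` with semicolon-delimited groups.
#'
#' @param file Path.
#' @param sep Field separator; guessed from the extension by default.
#' @return A tibble.
#' @export
read_classification <- function(file, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  tibble::as_tibble(utils::read.table(file, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE, quote = "\"",
                                      check.names = FALSE))
}

#' Patristic distances between tips
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An [ape::phylo] object.
#' @return A symmetric matrix with zero diagonal, rows/columns ordered and
#'   named as `tree$tip.label`.
#' @export
patristic_distances <- function(tree) {
  tree <- validate_phylo(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Phylogenetic covariance matrix with correlation-parameter transforms
#'
#' Brownian expected covariance (shared root-to-ancestor path length),
#' optionally rescaled by Pagel's lambda (off-diagonals multiplied by
#' `parameter`) or by an Ornstein-Uhlenbeck-style exponential decay in which
#' the correlation between tips i and j is `exp(-parameter * d_ij)` with
#' `d_ij` the patristic distance, scaled back to the Brownian tip variances.
#'
#' @param tree An [ape::phylo] object.
#' @param transform `"none"`, `"lambda"` or `"ou"`.
#' @param parameter lambda in `[0, 1]` or alpha `>= 0`; ignored for
#'   `"none"`.
#' @return An object of class `phylo_cov`: list with `matrix` (taxa x taxa),
#'   `transform`, `parameter`, `tips`.
#' @export
phylo_covariance <- function(tree, transform = c("none", "lambda", "ou"),
                             parameter = NULL) {
  transform <- match.arg(transform)
  tree <- validate_phylo(tree)
  v_bm <- ape::vcv.phylo(tree)
  v_bm <- v_bm[tree$tip.label, tree$tip.label]
  m <- switch(transform,
    none = v_bm,
    lambda = {
      if (is.null(parameter) || is.na(parameter) || parameter < 0 || parameter > 1) {
        abort("lambda must lie in [0, 1]")
      }
      transform_lambda(v_bm, parameter)
    },
    ou = {
      if (is.null(parameter) || is.na(parameter) || parameter < 0) {
        abort("alpha must be >= 0")
      }
      transform_ou(v_bm, patristic_distances(tree), parameter)
    }
  )
  structure(
    list(matrix = m, transform = transform,
         parameter = if (transform == "none") NA_real_ else parameter,
         tips = tree$tip.label),
    class = "phylo_cov"
  )
}

transform_lambda <- function(v_bm, lambda) {
  m <- v_bm * lambda
  diag(m) <- diag(v_bm)
  m
}

transform_ou <- function(v_bm, d_pat, alpha) {
  sd_tip <- sqrt(diag(v_bm))
  outer(sd_tip, sd_tip) * exp(-alpha * d_pat)
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("<phylo_cov> ", length(x$tips), " tips, transform = ", x$transform,
      if (!is.na(x$parameter)) paste0(" (", signif(x$parameter, 4), ")"), "\n",
      sep = "")
  invisible(x)
}

#' Write a labelled matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param file Path.
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
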