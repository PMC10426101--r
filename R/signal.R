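#' Fritz-Purvis D statistic for binary-trait phylogenetic signal
#'
#' Measures phylogenetic clumping of a binary trait. The observed statistic
#' `d_obs` sums, over internal nodes, the absolute differences between the
#' nodal values of each unordered pair of daughters, where a nodal value is
#' the mean of its daughters' values computed tips-to-root (so polytomies
#' contribute one term per daughter pair). `d_obs` is scaled between two
#' simulated calibration distributions:
#' \deqn{D = (d_obs - mean(d_Brownian)) / (mean(d_random) - mean(d_Brownian))}
#' `d_random` shuffles tip states (phylogenetically random, D = 1 on
#' average); `d_Brownian` thresholds a Brownian trait simulated on the same
#' tree at the observed prevalence (clumped as under gradual evolution,
#' D = 0 on average). Negative D indicates stronger-than-Brownian clumping.
#'
#' @param data Trait table (data frame with a taxon column), or a named 0/1
#'   vector keyed by tip label.
#' @param tree [ape::phylo] phylogeny.
#' @param trait Column name of the binary trait (ignored when `data` is a
#'   vector).
#' @param n_permutations Number of permutations/simulations per calibration
#'   distribution.
#' @param seed Integer seed (stored in the result; same seed, same result).
#' @param polytomy `"pairs"` (default): a polytomy contributes one term per
#'   unordered daughter pair. `"resolve"`: polytomies are randomly
#'   bifurcated first (seeded, zero-length new branches). On highly
#'   polytomous classification trees the all-pairs convention lets
#'   high-degree nodes dominate and can compress the calibration span, so
#'   `"resolve"` is recommended there.
#' @return An object of class `phylo_d`: `d_obs`, `D`, `p_random`
#'   (probability of clumping at least this strong under tip shuffling),
#'   `p_brownian`, `n_permutations`, `seed`, `n_tips`, `prevalence`.
#' @export
d_statistic <- function(data, tree, trait = NULL, n_permutations = 999,
                        seed = 1L, polytomy = c("pairs", "resolve")) {
  polytomy <- match.arg(polytomy)
  x <- if (is.data.frame(data)) {
    if (is.null(trait)) abort("supply `trait`, the binary column name")
    trait_vector(data, trait)
  } else {
    data
  }
  tree <- validate_phylo(tree)
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) abort("unnamed trait of wrong length")
    names(x) <- tree$tip.label
  }
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips)) {
    abort(paste0("trait missing for tips: ", paste(missing_tips, collapse = ", ")))
  }
  x <- x[tree$tip.label]
  if (anyNA(x)) abort("trait contains missing values")
  if (!is_binary01(x)) abort("trait must be strictly 0/1")
  if (length(unique(x)) < 2) abort("D undefined for a single-state trait")
  if (polytomy == "resolve" && !ape::is.binary(tree)) {
    tree <- with_seed(seed + 1L, ape::multi2di(tree, random = TRUE))
    tree$edge.length[is.na(tree$edge.length)] <- 0
    x <- x[tree$tip.label]
  }

  d_obs <- sister_diff_sum(tree, matrix(x, ncol = 1))[1]
  n_ones <- sum(x == 1)
  n <- length(x)

  res <- with_seed(seed, {
    shuffled <- vapply(seq_len(n_permutations), function(i) sample(x),
                       numeric(n))
    v_bm <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
    L <- chol(v_bm)
    z <- matrix(rnorm(n * n_permutations), n, n_permutations)
    lat <- crossprod(L, z)
    bm <- apply(lat, 2, threshold_top_k, k = n_ones)
    list(d_random = sister_diff_sum(tree, shuffled),
         d_brownian = sister_diff_sum(tree, bm))
  })
  mean_r <- mean(res$d_random)
  mean_b <- mean(res$d_brownian)
  D <- (d_obs - mean_b) / (mean_r - mean_b)
  structure(
    list(d_obs = d_obs, D = D,
         p_random = (1 + sum(res$d_random <= d_obs)) / (n_permutations + 1),
         p_brownian = (1 + sum(res$d_brownian <= d_obs)) / (n_permutations + 1),
         mean_d_random = mean_r, mean_d_brownian = mean_b,
         n_permutations = n_permutations, seed = as.integer(seed),
         n_tips = n, prevalence = n_ones / n),
    class = "phylo_d"
  )
}

threshold_top_k <- function(latent, k) {
  out <- numeric(length(latent))
  out[order(latent, decreasing = TRUE)[seq_len(k)]] <- 1
  out
}

# Sum over internal nodes of |v_i - v_j| across unordered daughter pairs,
# with nodal values computed tips-to-root as daughter means. Vectorised over
# the columns of the tip-state matrix.
sister_diff_sum <- function(tree, tip_states) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  vals <- matrix(0, n_tip + n_node, ncol(tip_states))
  vals[seq_len(n_tip), ] <- tip_states
  d <- numeric(ncol(tip_states))
  edge <- post$edge
  internal <- unique(edge[, 1])
  children <- split(edge[, 2], edge[, 1])
  for (node in internal) {   # postorder: children resolved before parents
    ch <- children[[as.character(node)]]
    cv <- vals[ch, , drop = FALSE]
    if (length(ch) == 2) {
      d <- d + abs(cv[1, ] - cv[2, ])
    } else {
      pairs <- combn(length(ch), 2)
      for (j in seq_len(ncol(pairs))) {
        d <- d + abs(cv[pairs[1, j], ] - cv[pairs[2, j], ])
      }
    }
    vals[node, ] <- colMeans(cv)
  }
  d
}

#' @export
print.phylo_d <- function(x, ...) {
  cat("Fritz-Purvis D = ", signif(x$D, 4),
      "  (d_obs = ", signif(x$d_obs, 4), ")\n",
      "p(random | clumping >= observed)  = ", signif(x$p_random, 4), "\n",
      "p(Brownian | clumping >= observed) = ", signif(x$p_brownian, 4), "\n",
      x$n_permutations, " permutations, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.phylo_d <- function(x, ...) {
  tibble::tibble(d_obs = x$d_obs, D = x$D, p_random = x$p_random,
                 p_brownian = x$p_brownian,
                 n_permutations = x$n_permutations, seed = x$seed,
                 n_tips = x$n_tips, prevalence = x$prevalence)
}

#' Mantel permutation test between two distance matrices
#'
#' Reports both the raw upper-triangle cross-product statistic `z` and the
#' standardised Mantel correlation `r`; significance is a one-tailed
#' permutation test (row/column permutations of `m2`), with p floored at
#' `1/(B+1)`.
#'
#' @param m1,m2 Symmetric distance matrices with zero diagonal over the
#'   same taxa (aligned by dimnames when present).
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: `z`, `r`, `p` (one-tailed,
#'   from `r`, or from `z` when `r` is undefined), `p_z`, `n_permutations`,
#'   `seed`, `n`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 9999, seed = 1L) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  check_symmetric_distance(m1, "m1")
  check_symmetric_distance(m2, "m2")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      abort("m1 and m2 cover different taxa")
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (!all(dim(m1) == dim(m2))) abort("m1 and m2 have different dimensions")
  n <- nrow(m1)
  v1 <- upper_tri_vals(m1)
  v2 <- upper_tri_vals(m2)
  z_obs <- sum(v1 * v2)
  const1 <- sd(v1) == 0
  const2 <- sd(v2) == 0
  r_obs <- if (const1 || const2) NA_real_ else cor(v1, v2)

  perm <- with_seed(seed, {
    z_perm <- numeric(n_permutations)
    r_perm <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      idx <- sample(n)
      vp <- upper_tri_vals(m2[idx, idx])
      z_perm[b] <- sum(v1 * vp)
      r_perm[b] <- if (is.na(r_obs)) NA_real_ else cor(v1, vp)
    }
    list(z = z_perm, r = r_perm)
  })
  p_z <- (1 + sum(perm$z >= z_obs)) / (n_permutations + 1)
  p_r <- if (is.na(r_obs)) NA_real_ else {
    (1 + sum(perm$r >= r_obs)) / (n_permutations + 1)
  }
  structure(
    list(z = z_obs, r = r_obs, p = if (is.na(r_obs)) p_z else p_r, p_z = p_z,
         n_permutations = n_permutations, seed = as.integer(seed), n = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: z = ", signif(x$z, 6), ", r = ", signif(x$r, 4),
      ", p = ", signif(x$p, 4), " (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(z = x$z, r = x$r, p = x$p, p_z = x$p_z,
                 n_permutations = x$n_permutations, seed = x$seed, n = x$n)
}

#' Binary-trait mismatch distances
#'
#' `d_ij = 0` if taxa i and j share the trait state, else 1. Used to test
#' geographic or phylogenetic patterning of a single binary trait.
#'
#' @param data Trait table or named 0/1 vector.
#' @param trait Column name when `data` is a data frame.
#' @return A symmetric 0/1 matrix with zero diagonal.
#' @export
trait_distance <- function(data, trait = NULL) {
  x <- if (is.data.frame(data)) trait_vector(data, trait) else data
  if (!is_binary01(x[!is.na(x)])) abort("trait must be strictly 0/1")
  m <- 1 * outer(x, x, "!=")
  dimnames(m) <- list(names(x), names(x))
  m
}

#' Great-circle distances between taxa
#'
#' Haversine distances in kilometres (Earth radius 6371 km).
#'
#' @param coords Data frame with columns `taxon`, `lat` (degrees, -90..90)
#'   and `lon` (degrees, -180..180).
#' @return A symmetric matrix (km) with taxa as dimnames.
#' @export
geographic_distances <- function(coords) {
  stopifnot(is.data.frame(coords))
  need <- c("lat", "lon")
  if (!all(need %in% names(coords))) abort("coords needs columns lat and lon")
  lat <- coords$lat; lon <- coords$lon
  if (any(is.na(lat)) || any(is.na(lon))) abort("missing coordinates")
  if (any(lat < -90 | lat > 90)) abort("latitude out of range [-90, 90]")
  if (any(lon < -180 | lon > 180)) abort("longitude out of range [-180, 180]")
  taxa <- as.character(coords[[guess_taxon_col(coords)]])
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  m <- 2 * 6371 * asin(sqrt(a))
  diag(m) <- 0
  dimnames(m) <- list(taxa, taxa)
  m
}
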