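# Phylogenetic beta diversity. Trees are ape "phylo" objects; the
# neighbor-joining construction and midpoint rooting delegate to
# ape/phangorn, while the UniFrac family is implemented here via a single
# postorder accumulation of per-branch community proportions.

.check_distance_matrix <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square",
                               call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > tol) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > tol)) {
    stop("distance matrix has non-zero diagonal", call. = FALSE)
  }
  if (any(d < -tol)) stop("negative distances", call. = FALSE)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps the standard agglomerative neighbor-joining construction;
#' negative branch lengths (an NJ artifact) are clamped to zero with the
#' deficit shifted to the sibling branch so leaf-to-leaf path lengths
#' between the affected pair are preserved.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return An unrooted ape `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                 edge.length = rep(d[1L, 2L] / 2, 2L),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    for (e in neg) {
      deficit <- tree$edge.length[e]
      parent <- tree$edge[e, 1L]
      sib <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sib)) {
        s <- sib[1L]
        tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
      }
      tree$edge.length[e] <- 0
    }
    message(length(neg), " negative NJ branch length(s) clamped to 0")
  }
  tree
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path;
#' pairwise leaf path lengths are preserved.
#'
#' @param tree An ape `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (length(tree$tip.label) == 2L) {
    total <- sum(tree$edge.length)
    tree$edge.length <- rep(total / 2, 2L)
    return(tree)
  }
  if (sum(tree$edge.length) == 0) {
    message("zero-length tree: rooting at first internal node")
    return(tree)
  }
  phangorn::midpoint(tree)
}

# per-branch descendant proportions of one or more profiles.
# profiles: named list of named numeric vectors over (a subset of) tips.
# returns a matrix branches x profiles; branch i is the edge above node
# tree$edge[i, 2].
.branch_proportions <- function(tree, profiles) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  out <- matrix(0, nrow(po$edge), length(profiles))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    extra <- setdiff(names(p), tips)
    if (length(extra)) {
      stop("profile leaf/leaves missing from tree: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    mass <- numeric(n_tip + n_node)
    mass[match(names(p), tips)] <- p
    for (e in seq_len(nrow(po$edge))) {
      mass[po$edge[e, 1L]] <- mass[po$edge[e, 1L]] + mass[po$edge[e, 2L]]
    }
    out[, k] <- mass[po$edge[, 2L]]
  }
  list(proportions = out, branch_lengths = po$edge.length)
}

#' Generalized UniFrac distance between two communities
#'
#' Computes `d^(alpha)`, where `alpha` in `[0, 1]` controls the
#' contribution of high-abundance branches:
#' `d = sum_i b_i (pA_i + pB_i)^alpha |pA_i - pB_i| / (pA_i + pB_i)`
#' divided by `sum_i b_i (pA_i + pB_i)^alpha`, summed over branches with
#' `pA_i + pB_i > 0`, where `p_Xi` is the fraction of community X
#' descending from branch i. `alpha = 1` is the classical weighted
#' (normalized) UniFrac.
#'
#' @param tree Rooted ape `phylo` tree with branch lengths.
#' @param profile_a,profile_b Named relative-abundance vectors over tree
#'   leaves, each summing to 1.
#' @param alpha Abundance weight exponent in `[0, 1]`.
#' @return Distance in `[0, 1]`.
#' @export
generalized_unifrac <- function(tree, profile_a, profile_b, alpha = 1) {
  stopifnot(inherits(tree, "phylo"), alpha >= 0, alpha <= 1)
  for (p in list(profile_a, profile_b)) {
    if (abs(sum(p) - 1) > 1e-6) {
      stop("profiles must sum to 1", call. = FALSE)
    }
  }
  bp <- .branch_proportions(tree, list(a = profile_a, b = profile_b))
  pa <- bp$proportions[, 1L]
  pb <- bp$proportions[, 2L]
  b <- bp$branch_lengths
  occ <- (pa + pb) > 0
  if (!any(occ)) return(0)
  s <- (pa + pb)[occ]
  num <- sum(b[occ] * s^alpha * abs(pa - pb)[occ] / s)
  den <- sum(b[occ] * s^alpha)
  if (den == 0) return(0)
  num / den
}

#' Unweighted UniFrac distance
#'
#' Presence/absence variant:
#' `sum_i b_i |1(pA_i > 0) - 1(pB_i > 0)| / sum_i b_i 1(pA_i + pB_i > 0)`.
#'
#' @inheritParams generalized_unifrac
#' @return Distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, profile_a, profile_b) {
  stopifnot(inherits(tree, "phylo"))
  bp <- .branch_proportions(tree, list(a = profile_a, b = profile_b))
  pa <- bp$proportions[, 1L]
  pb <- bp$proportions[, 2L]
  b <- bp$branch_lengths
  occ <- (pa + pb) > 0
  den <- sum(b[occ])
  if (den == 0) return(0)
  sum(b * abs((pa > 0) - (pb > 0))) / den
}

# variance-adjusted weighted UniFrac: each branch term is normalized by
# sqrt(m_i (m_total - m_i)) with m_i = pA_i + pB_i and m_total = 2
.vaw_unifrac <- function(tree, profile_a, profile_b) {
  bp <- .branch_proportions(tree, list(a = profile_a, b = profile_b))
  pa <- bp$proportions[, 1L]
  pb <- bp$proportions[, 2L]
  b <- bp$branch_lengths
  m <- pa + pb
  ok <- m > 0 & m < 2
  if (!any(ok)) return(0)
  w <- 1 / sqrt(m[ok] * (2 - m[ok]))
  num <- sum(b[ok] * abs(pa - pb)[ok] * w)
  den <- sum(b[ok] * m[ok] * w)
  if (den == 0) return(0)
  num / den
}

#' Pairwise UniFrac distance matrices for an OTU table
#'
#' Emits the requested variants: `d_W` (weighted, alpha = 1), `d_0.5`,
#' `d_0`, `d_U` (unweighted) and `d_VAW` (variance-adjusted weighted).
#'
#' @param table An [otu_table] with >= 2 samples; taxa must be tree
#'   leaves.
#' @param tree Rooted ape `phylo` tree with branch lengths.
#' @param variants Subset of `c("d_W", "d_0.5", "d_0", "d_U", "d_VAW")`.
#' @return Named list of symmetric sample x sample distance matrices.
#' @export
unifrac_matrix <- function(table, tree,
                           variants = c("d_W", "d_0.5", "d_0", "d_U",
                                        "d_VAW")) {
  stopifnot(inherits(table, "otu_table"))
  variants <- match.arg(variants, several.ok = TRUE)
  samples <- otu_samples(table)
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total: ",
         paste(samples[totals == 0], collapse = ", "), call. = FALSE)
  }
  profiles <- lapply(samples, function(s) {
    p <- table$counts[, s] / totals[s]
    setNames(p, otu_taxa(table))
  })
  names(profiles) <- samples
  pair_fun <- list(
    d_W = function(a, b) generalized_unifrac(tree, a, b, alpha = 1),
    `d_0.5` = function(a, b) generalized_unifrac(tree, a, b, alpha = 0.5),
    d_0 = function(a, b) generalized_unifrac(tree, a, b, alpha = 0),
    d_U = function(a, b) unweighted_unifrac(tree, a, b),
    d_VAW = function(a, b) .vaw_unifrac(tree, a, b))
  out <- lapply(setNames(variants, variants), function(v) {
    m <- matrix(0, length(samples), length(samples),
                dimnames = list(samples, samples))
    for (i in seq_along(samples)) {
      for (j in seq_len(i - 1L)) {
        m[i, j] <- m[j, i] <- pair_fun[[v]](profiles[[i]], profiles[[j]])
      }
    }
    m
  })
  out
}
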