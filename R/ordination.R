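# Ordination and group testing on distance matrices: classical principal
# coordinates analysis and permutational MANOVA (pseudo-F over squared
# distances with a label-permutation null).

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the positive eigenvalues. Axes with negative
#' eigenvalues (possible for non-Euclidean distances such as UniFrac) are
#' reported and dropped. The sign convention makes the largest-magnitude
#' loading of each axis positive.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return An object of class `pcoa_result`: `coordinates` (samples x
#'   axes), `eigenvalues` (all, descending), `proportion_explained`
#'   (over positive eigenvalues) and `n_negative`.
#' @export
pcoa <- function(d) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  a <- -0.5 * d^2
  b <- a - rowMeans(a) %o% rep(1, n) - rep(1, n) %o% colMeans(a) + mean(a)
  eig <- eigen(b, symmetric = TRUE)
  values <- eig$values
  tol <- 1e-8 * max(abs(values), 1e-300)
  pos <- which(values > tol)
  coords <- if (length(pos)) {
    eig$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(values[pos]), length(pos))
  } else {
    matrix(0, n, 0L)
  }
  if (ncol(coords)) {
    for (k in seq_len(ncol(coords))) {
      i_max <- which.max(abs(coords[, k]))
      if (coords[i_max, k] < 0) coords[, k] <- -coords[, k]
    }
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  rownames(coords) <- rownames(d)
  structure(list(
    coordinates = coords,
    eigenvalues = values,
    proportion_explained = if (length(pos)) values[pos] / sum(values[pos])
      else numeric(0),
    n_negative = sum(values < -tol)),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_negative))
  invisible(x)
}

# pseudo-F from squared distances via the standard partition
.permanova_f <- function(d2, groups) {
  n <- length(groups)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Permutational MANOVA on a distance matrix
#'
#' Pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g)), with sums
#' of squares computed from squared distances (total SS = sum of squared
#' distances / n; within-group SS analogously per group). The p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_permutations)` under
#' seeded random label permutations, or the exact proportion over all
#' distinct two-group label assignments when `exhaustive = TRUE`.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations Number of random permutations.
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all distinct label assignments instead of
#'   sampling (two groups only).
#' @return An object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- .check_distance_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) {
    stop("groups must match the distance matrix dimension", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  d2 <- d^2
  f_obs <- .permanova_f(d2, groups)
  if (!is.finite(f_obs)) {
    # constant distance matrix: no structure to test
    return(structure(list(pseudo_F = NaN, p_value = 1,
                          n_permutations = 0L, seed = as.integer(seed)),
                     class = "permanova_result"))
  }
  tol <- 1e-12
  if (exhaustive) {
    if (length(sizes) != 2L) {
      stop("exhaustive enumeration supports exactly 2 groups",
           call. = FALSE)
    }
    labels <- sort(unique(groups))
    n <- length(groups)
    k <- sum(groups == labels[1L])
    splits <- combn(n, k)
    f_all <- apply(splits, 2L, function(idx) {
      lab <- rep(labels[2L], n)
      lab[idx] <- labels[1L]
      .permanova_f(d2, lab)
    })
    p <- mean(f_all >= f_obs - tol)
    n_perm <- ncol(splits)
  } else {
    with_seed(seed, {
      exceed <- 0L
      for (i in seq_len(n_permutations)) {
        f_p <- .permanova_f(d2, sample(groups))
        if (is.finite(f_p) && f_p >= f_obs - tol) exceed <- exceed + 1L
      }
    })
    p <- (1 + exceed) / (1 + n_permutations)
    n_perm <- as.integer(n_permutations)
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_perm,
                 seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}
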