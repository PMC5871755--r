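# Alpha diversity: the inverse Simpson index (effective number of equally
# abundant taxa) and its rarefaction curve under subsampling without
# replacement.

#' Inverse Simpson diversity index
#'
#' `1 / sum(p_i^2)` with `p_i` the relative abundances; equals the number
#' of taxa for a perfectly even community and 1 for a monoculture.
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return A number >= 1.
#' @export
#' @examples
#' inverse_simpson(c(1, 1))  # 2
inverse_simpson <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("counts must have positive total", call. = FALSE)
  p <- counts / total
  1 / sum(p^2)
}

#' Rarefaction curve of inverse Simpson diversity
#'
#' At each depth, `n_reps` subsamples are drawn without replacement from
#' the individuals of the community and the inverse Simpson index of each
#' subsample is recorded.
#'
#' @param counts Non-negative integer vector of taxon counts.
#' @param depths Integer vector of subsampling depths (each <= total).
#' @param n_reps Replicates per depth.
#' @param seed Integer seed; the curve is deterministic given the seed.
#' @return An object of class `rarefaction_curve`: `depths`, `mean`,
#'   `sd`, `n_reps`, `seed`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 10L, seed = 1L) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 1L) || any(depths > total)) {
    stop("depths must lie in [1, total counts = ", total, "]",
         call. = FALSE)
  }
  individuals <- rep.int(seq_along(counts), counts)
  with_seed(seed, {
    stats_per_depth <- vapply(depths, function(d) {
      vals <- vapply(seq_len(n_reps), function(rep) {
        sub <- tabulate(sample(individuals, d), nbins = length(counts))
        inverse_simpson(sub)
      }, numeric(1))
      c(mean(vals), if (n_reps > 1L) sd(vals) else 0)
    }, numeric(2))
  })
  structure(list(depths = depths, mean = stats_per_depth[1L, ],
                 sd = stats_per_depth[2L, ], n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("<rarefaction_curve> %d depths x %d reps\n",
              length(x$depths), x$n_reps))
  invisible(x)
}
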