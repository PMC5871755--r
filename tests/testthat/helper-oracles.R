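# Independent oracles used to cross-check the package's implementations.
# They deliberately take different algorithmic routes from the code they
# verify.

# --- alignment ---------------------------------------------------------

# exhaustive enumeration of every global alignment of q vs r under a
# linear gap penalty; recursion over the three possible last columns.
enum_global_score <- function(q, r, match = 1, mismatch = -1, gap = -1) {
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (qc[i] == rc[j]) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(qc), length(rc))
}

# semi-global score as max over all reference substrings of a plain R
# Needleman-Wunsch with linear gaps (free reference end gaps by
# construction; independent of the C++ affine three-state DP).
oracle_semi_global_score <- function(q, r, match = 1, mismatch = -1,
                                     gap = -1) {
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  n <- length(qc)
  nw <- function(sub) {
    m <- length(sub)
    g <- matrix(0, n + 1L, m + 1L)
    g[, 1L] <- gap * (0:n)
    g[1L, ] <- gap * (0:m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        s <- if (qc[i] == sub[j]) match else mismatch
        g[i + 1L, j + 1L] <- max(g[i, j] + s, g[i, j + 1L] + gap,
                                 g[i + 1L, j] + gap)
      }
    }
    g[n + 1L, m + 1L]
  }
  best <- gap * n  # empty reference substring
  for (j0 in seq_along(rc)) {
    for (j1 in j0:length(rc)) {
      best <- max(best, nw(rc[j0:j1]))
    }
  }
  best
}

# --- UniFrac -----------------------------------------------------------

# per-edge leaf-set route: for every edge, sum the profile over the tips
# descending from it (phangorn::Descendants), then apply the formulas
# directly. Independent of the package's postorder accumulation.
oracle_generalized_unifrac <- function(tree, pa, pb, alpha) {
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= length(tree$tip.label)) child else
      phangorn::Descendants(tree, child, "tips")[[1L]]
    labels <- tree$tip.label[tips]
    a <- sum(pa[intersect(names(pa), labels)])
    b <- sum(pb[intersect(names(pb), labels)])
    if (a + b <= 0) next
    w <- (a + b)^alpha
    num <- num + tree$edge.length[e] * w * abs(a - b) / (a + b)
    den <- den + tree$edge.length[e] * w
  }
  if (den == 0) 0 else num / den
}

oracle_unweighted_unifrac <- function(tree, pa, pb) {
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= length(tree$tip.label)) child else
      phangorn::Descendants(tree, child, "tips")[[1L]]
    labels <- tree$tip.label[tips]
    a <- sum(pa[intersect(names(pa), labels)])
    b <- sum(pb[intersect(names(pb), labels)])
    if (a + b <= 0) next
    den <- den + tree$edge.length[e]
    num <- num + tree$edge.length[e] * abs((a > 0) - (b > 0))
  }
  if (den == 0) 0 else num / den
}

# random rooted tree and profile pair over its tips
random_unifrac_instance <- function(n_tips) {
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tips <- tree$tip.label
  make_profile <- function() {
    k <- sample(seq_len(n_tips), 1L)
    chosen <- sample(tips, k)
    p <- runif(k)
    setNames(p / sum(p), chosen)
  }
  list(tree = tree, pa = make_profile(), pb = make_profile())
}

# --- perMANOVA ---------------------------------------------------------

# pseudo-F via vegan's implementation (independent route)
vegan_pseudo_f <- function(d, groups) {
  df <- data.frame(g = factor(groups))
  fit <- suppressMessages(
    vegan::adonis2(stats::as.dist(d) ~ g, data = df, permutations = 1))
  fit$F[1L]
}

# --- fixtures ----------------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

# the bundled study-conditions fixture: 20 taxa, 4 confusable V3-V4 pairs
db20 <- function() {
  if (is.null(.fixture_cache$db20)) {
    .fixture_cache$db20 <- build_reference_db(
      20, n_confusable_groups = 4, group_size = 2, seed = 1)
  }
  .fixture_cache$db20
}

db_small <- function() {
  if (is.null(.fixture_cache$db_small)) {
    .fixture_cache$db_small <- build_reference_db(
      8, n_confusable_groups = 0, seed = 3)
  }
  .fixture_cache$db_small
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate exactly k positions of a sequence (substitutions at distinct sites)
mutate_k <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1L]]
  for (i in positions) {
    chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1L]
  }
  paste(chars, collapse = "")
}
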