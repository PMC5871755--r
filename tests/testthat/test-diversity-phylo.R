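test_that("inverse Simpson matches its closed forms", {
  expect_equal(inverse_simpson(c(1, 1)), 2)
  expect_equal(inverse_simpson(c(5, 0, 0)), 1)
  for (k in c(3, 7, 12)) {
    expect_equal(inverse_simpson(rep(4, k)), k)
  }
  expect_error(inverse_simpson(c(0, 0)), "positive total")
  expect_error(inverse_simpson(c(-1, 2)), "non-negative")
})

test_that("rarefaction is exact at full depth and degenerate at depth 1", {
  counts <- c(50, 30, 20)
  rc <- rarefaction_curve(counts, depths = c(1, 60, 100), n_reps = 20,
                          seed = 5)
  expect_equal(rc$mean[1L], 1)
  expect_equal(rc$sd[1L], 0)
  expect_equal(rc$mean[3L], inverse_simpson(counts))
  expect_equal(rc$sd[3L], 0)
  # large subsample stays within 3 sd of the full-sample value
  expect_lt(abs(rc$mean[2L] - inverse_simpson(counts)),
            3 * max(rc$sd[2L], 0.05))
  # deterministic given seed
  rc2 <- rarefaction_curve(counts, depths = c(1, 60, 100), n_reps = 20,
                           seed = 5)
  expect_identical(rc$mean, rc2$mean)
  expect_error(rarefaction_curve(counts, depths = 101), "depths")
})

test_that("neighbor joining reproduces closed-form branch lengths", {
  # 2 taxa: two equal half branches
  t2 <- nj_tree(matrix(c(0, 0.4, 0.4, 0), 2L, 2L,
                       dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(t2$edge.length, c(0.2, 0.2))

  # 3 taxa: bx = (dxy + dxz - dyz) / 2
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L, 3L,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  lens <- setNames(t3$edge.length,
                   t3$tip.label[t3$edge[, 2L]])
  expect_equal(lens[c("x", "y", "z")], c(x = 1, y = 2, z = 3))

  # additive 4-taxon matrix: NJ recovers the generating tree's distances
  gen <- parse_newick("((A:1,B:2):1,(C:3,D:4):2);")
  d4 <- ape::cophenetic.phylo(gen)
  t4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(t4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2L, 2L)), "not symmetric")
})

test_that("midpoint rooting splits the longest path and keeps distances", {
  t2 <- parse_newick("(A:1,B:3);")
  r2 <- midpoint_root(t2)
  expect_equal(r2$edge.length, c(2, 2))

  t4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  r4 <- midpoint_root(t4)
  d <- ape::cophenetic.phylo(r4)
  expect_equal(d["A", "C"], 4)

  set.seed(67)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    before <- ape::cophenetic.phylo(tr)
    after <- ape::cophenetic.phylo(midpoint_root(tr))
    expect_equal(after[rownames(before), colnames(before)], before,
                 tolerance = 1e-10)
  }
})

test_that("generalized UniFrac matches the hand-computed 3-leaf case", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  pa <- c(A = 1)
  pb <- c(B = 1)
  # occupied branches: A (b=1, |1-0|), B (b=2, |0-1|), AB (b=0.5, |1-1|=0)
  # alpha=1: num = 1 + 2 + 0 = 3; den = 1 + 2 + 0.5*2 = 4
  expect_equal(generalized_unifrac(tr, pa, pb, alpha = 1), 0.75)
  # identical profiles: 0 at every alpha
  for (alpha in c(0, 0.5, 1)) {
    expect_equal(generalized_unifrac(tr, pa, pa, alpha), 0)
  }
  # disjoint leaf sets on a star tree: 1 for every alpha
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  for (alpha in c(0, 0.5, 1)) {
    expect_equal(generalized_unifrac(star, c(A = 0.6, B = 0.4),
                                     c(C = 0.7, D = 0.3), alpha), 1)
  }
  expect_error(generalized_unifrac(tr, c(Z = 1), pb, 1), "missing from tree")
})

test_that("UniFrac agrees with the branch-enumeration oracle", {
  set.seed(71)
  for (i in 1:60) {
    inst <- random_unifrac_instance(sample(3:8, 1L))
    for (alpha in c(0, 0.5, 1)) {
      expect_equal(
        generalized_unifrac(inst$tree, inst$pa, inst$pb, alpha),
        oracle_generalized_unifrac(inst$tree, inst$pa, inst$pb, alpha),
        tolerance = 1e-12)
    }
    expect_equal(unweighted_unifrac(inst$tree, inst$pa, inst$pb),
                 oracle_unweighted_unifrac(inst$tree, inst$pa, inst$pb),
                 tolerance = 1e-12)
  }
})

test_that("unweighted UniFrac ignores abundance, weighted does not", {
  set.seed(73)
  tr <- ape::rtree(6)
  tips <- tr$tip.label
  support <- tips[1:4]
  p1 <- setNames(rep(0.25, 4), support)
  skew <- c(0.85, 0.05, 0.05, 0.05)
  p2 <- setNames(skew, support)
  q <- setNames(c(0.5, 0.5), tips[5:6])
  expect_equal(unweighted_unifrac(tr, p1, q),
               unweighted_unifrac(tr, p2, q), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(generalized_unifrac(tr, p1, q, 1),
                                generalized_unifrac(tr, p2, q, 1))))
})

test_that("UniFrac matrices are symmetric with duplicate-sample zeros", {
  db <- db_small()
  accs <- names(db$sequences)[1:5]
  lin <- db$lineages
  counts <- matrix(c(10, 5, 0, 3, 2,
                     10, 5, 0, 3, 2,
                     0, 1, 8, 4, 7), 5L, 3L,
                   dimnames = list(accs, c("s1", "s1dup", "s2")))
  tab <- otu_table(counts, lin)
  set.seed(79)
  tr <- ape::rtree(5, tip.label = accs)
  um <- unifrac_matrix(tab, tr)
  expect_setequal(names(um), c("d_W", "d_0.5", "d_0", "d_U", "d_VAW"))
  for (v in names(um)) {
    m <- um[[v]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 3L))
    expect_equal(m["s1", "s1dup"], 0)
  }
  # the weighted matrix equals the generalized form at alpha = 1
  profiles <- sweep(counts, 2L, colSums(counts), "/")
  expect_equal(um$d_W["s1", "s2"],
               generalized_unifrac(tr, profiles[, "s1"], profiles[, "s2"],
                                   alpha = 1))
})

test_that("PCoA recovers Euclidean configurations exactly", {
  # 3 collinear points
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3L, 3L,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(d)
  expect_equal(sum(res$eigenvalues > 1e-8), 1L)
  expect_equal(as.matrix(dist(res$coordinates[, 1L])),
               d, ignore_attr = TRUE, tolerance = 1e-9)

  # random 2-D points: the first two axes reproduce all distances
  set.seed(83)
  pts <- matrix(rnorm(16), 8L, 2L)
  d2 <- as.matrix(dist(pts))
  res2 <- pcoa(d2)
  expect_equal(as.matrix(dist(res2$coordinates[, 1:2])), d2,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(sum(res2$proportion_explained), 1, tolerance = 1e-12)
  # eigenvalues agree with the reference implementation in ape
  ref <- ape::pcoa(d2)
  expect_equal(res2$eigenvalues[1:2], ref$values$Eigenvalues[1:2],
               tolerance = 1e-9)

  # zero matrix: no positive axes
  z <- matrix(0, 3L, 3L)
  expect_equal(ncol(pcoa(z)$coordinates), 0L)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2L, 2L)), "not symmetric")
})

test_that("perMANOVA pseudo-F matches vegan and enumerates exactly", {
  set.seed(89)
  pts <- rbind(matrix(rnorm(8, 0), 4L, 2L),
               matrix(rnorm(8, 3), 4L, 2L))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  g <- rep(c("a", "b"), each = 4L)
  res <- permanova(d, g, n_permutations = 199, seed = 3)
  expect_equal(res$pseudo_F, vegan_pseudo_f(d, g), tolerance = 1e-10)

  # exact enumeration on n = 6, two groups of 3, against a brute-force
  # oracle built on vegan's F
  pts6 <- rbind(matrix(rnorm(6, 0), 3L, 2L), matrix(rnorm(6, 2), 3L, 2L))
  d6 <- as.matrix(dist(pts6))
  rownames(d6) <- colnames(d6) <- paste0("s", 1:6)
  g6 <- rep(c("a", "b"), each = 3L)
  res6 <- permanova(d6, g6, exhaustive = TRUE)
  splits <- combn(6, 3)
  f_obs <- vegan_pseudo_f(d6, g6)
  f_all <- apply(splits, 2L, function(idx) {
    lab <- rep("b", 6L); lab[idx] <- "a"
    vegan_pseudo_f(d6, lab)
  })
  expect_equal(res6$p_value, mean(f_all >= f_obs - 1e-12))
  expect_equal(res6$n_permutations, 20L)

  # identical group multisets: observed F is minimal, p = 1
  dup <- rbind(pts6[1:3, ], pts6[1:3, ])
  ddup <- as.matrix(dist(dup))
  rownames(ddup) <- colnames(ddup) <- paste0("s", 1:6)
  resdup <- permanova(ddup, g6, exhaustive = TRUE)
  expect_equal(resdup$p_value, 1)

  # constant distance matrix: p = 1 by convention
  cm <- matrix(1, 4L, 4L) - diag(4L)
  rownames(cm) <- colnames(cm) <- paste0("s", 1:4)
  rescm <- permanova(cm, rep(c("a", "b"), each = 2L))
  expect_equal(rescm$p_value, 1)

  expect_error(permanova(d, rep("a", 8L)), "at least 2 groups")
  expect_error(permanova(d, c("a", rep("b", 7L))), "at least 2 samples")
})

test_that("separated synthetic communities are detected by perMANOVA", {
  # two community structures with within-group noise well below the
  # between-group distance
  set.seed(97)
  centers <- rbind(c(0, 0), c(4, 4))
  pts <- do.call(rbind, lapply(1:2, function(g) {
    sweep(matrix(rnorm(10, sd = 0.5), 5L, 2L), 2L, centers[g, ], "+")
  }))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:10)
  res <- permanova(d, rep(c("a", "b"), each = 5L),
                   n_permutations = 999, seed = 7)
  expect_lte(res$p_value, 0.05)
})
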