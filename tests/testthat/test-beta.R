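dm_of <- function(v, labels) {
  m <- as.matrix(v)
  dimnames(m) <- list(labels, labels)
  m
}

test_that("UPGMA reproduces hand-computed merges and heights", {
  # two samples join at half their distance
  t2 <- upgma(dm_of(dist(c(0, 0.4)), c("A", "B")))
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  # ((A,B),C): merge at 1, then (8+8)/2 = 8 -> height 4
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- upgma(m)
  bt <- ape::branching.times(t3)
  expect_equal(sort(unname(bt)), c(1, 4))
  expect_equal(triplet_distance(t3, ape::read.tree(text = "((A,B),C);")), 0)

  # identical rows merge first at height zero
  m4 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("P", "Q", "R"), c("P", "Q", "R")))
  t4 <- upgma(m4)
  expect_equal(min(ape::branching.times(t4)), 0)

  expect_error(upgma(dm_of(dist(c(0, NA)), c("A", "B"))), "NA")
})

test_that("UPGMA recovers the topology of an ultrametric matrix", {
  set.seed(61)
  for (i in 1:5) {
    tr <- ape::rcoal(8)
    tr$tip.label <- paste0("s", 1:8)
    d <- ape::cophenetic.phylo(tr)
    rec <- upgma(d[order(rownames(d)), order(colnames(d))])
    expect_equal(triplet_distance(rec, tr), 0)
  }
})

test_that("UPGMA agrees with the phangorn reference implementation", {
  skip_if_not_installed("phangorn")
  set.seed(63)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    v <- matrix(runif(n * n, 0.1, 1), n, n)
    m <- (v + t(v)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    ours <- upgma(m)
    ref <- phangorn::upgma(stats::as.dist(m))
    expect_equal(triplet_distance(ours, ref), 0)
  }
})

test_that("triplet distance matches the worked example and brute force", {
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(triplet_distance(a, b), 4)
  expect_equal(triplet_distance(a, a), 0)

  # swapping a cherry changes nothing
  cat1 <- ape::read.tree(text = "(((A,B),C),D);")
  cat2 <- ape::read.tree(text = "(((B,A),C),D);")
  expect_equal(triplet_distance(cat1, cat2), 0)

  # a star resolves nothing: compatible counts 0, mismatch counts them all
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(triplet_distance(star, a), 0)
  expect_equal(triplet_distance(star, a, unresolved = "mismatch"), 4)

  expect_error(triplet_distance(a, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf-label sets")
})

test_that("triplet distance equals exhaustive enumeration on random trees", {
  set.seed(67)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    t1 <- random_rooted_tree(n, polytomies = i %% 2 == 0)
    t2 <- random_rooted_tree(n, polytomies = i %% 3 == 0)
    t2$tip.label <- sample(t1$tip.label)
    for (conv in c("compatible", "mismatch")) {
      expect_equal(triplet_distance(t1, t2, unresolved = conv),
                   oracle_triplet_distance(t1, t2, unresolved = conv),
                   label = sprintf("n=%d rep=%d conv=%s", n, i, conv))
    }
    # semimetric basics
    expect_equal(triplet_distance(t1, t1), 0)
    expect_equal(triplet_distance(t1, t2), triplet_distance(t2, t1))
    expect_lte(triplet_distance(t1, t2, unresolved = "mismatch"), choose(n, 3))
  }
})

test_that("reference trees are per-group polytomies under the root", {
  r <- reference_tree(c(A = "g1", B = "g1", C = "g2"))
  expect_equal(triplet_distance(r, ape::read.tree(text = "((A,B),C);"),
                                unresolved = "mismatch"), 0)

  r3 <- reference_tree(setNames(rep(c("x", "y", "z"), each = 20),
                                paste0("s", 1:60)))
  expect_equal(length(r3$tip.label), 60)
  expect_equal(r3$Nnode, 4)   # root + three group polytomies

  # one big polytomy resolves nothing; every resolved triplet of the other
  # tree counts under the mismatch convention
  one <- ape::read.tree(text = "(A,B,C,D);")
  cat1 <- ape::read.tree(text = "(((A,B),C),D);")
  expect_equal(triplet_distance(one, cat1, unresolved = "mismatch"),
               choose(4, 3))

  expect_error(reference_tree(c(A = "g1", B = "g1")), "2 groups")
})

test_that("PCoA reproduces Euclidean configurations", {
  # collinear points: PC1 recovers centered positions up to sign
  pos <- c(0, 1, 3)
  o <- pcoa(dm_of(dist(pos), c("a", "b", "c")), dims = 1)
  got <- o$coordinates[, 1]
  centered <- pos - mean(pos)
  expect_true(max(abs(got - centered)) < 1e-9 ||
                max(abs(got + centered)) < 1e-9)

  # 2-D configuration: recovery up to rotation/reflection
  set.seed(71)
  X <- cbind(rnorm(12), rnorm(12))
  o2 <- pcoa(dm_of(dist(X), paste0("p", 1:12)), dims = 2)
  Y <- o2$coordinates
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  resid <- norm(Yc %*% (s$v %*% t(s$u)) - Xc, "F")
  expect_lt(resid, 1e-8)
  expect_true(all(diff(o2$eigenvalues) <= 1e-9))

  # duplicate samples land on the same coordinates
  m <- dm_of(dist(c(0, 0, 2)), c("u", "v", "w"))
  o3 <- pcoa(m, dims = 1)
  expect_equal(o3$coordinates["u", 1], o3$coordinates["v", 1])

  expect_warning(pcoa(dm_of(dist(c(0, 1, 3)), c("a", "b", "c")), dims = 2),
                 "positive eigenvalue")
})

test_that("gradient correlation is sign-invariant and validated", {
  grad <- seq(0.3, 0.7, by = 0.05)
  fake_ord <- function(pc1) {
    structure(list(coordinates = cbind(PC1 = pc1),
                   eigenvalues = 1, labels = seq_along(pc1)),
              class = "d2_ordination")
  }
  expect_equal(gradient_correlation(fake_ord(2 * grad + 1), grad), 1)
  expect_equal(gradient_correlation(fake_ord(-grad), grad), 1)
  expect_equal(gradient_correlation(fake_ord(-grad), grad, signed = TRUE), -1)
  orth <- c(1, -1, rep(0, 7))
  orth <- orth - mean(orth)
  g2 <- grad - mean(grad)
  orth <- orth - sum(orth * g2) / sum(g2 * g2) * g2
  expect_equal(gradient_correlation(fake_ord(orth), grad), 0, tolerance = 1e-12)
  expect_error(gradient_correlation(fake_ord(rep(1, 9)), grad),
               "zero variance")
  expect_error(gradient_correlation(fake_ord(grad), grad[-1]), "length")
})
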