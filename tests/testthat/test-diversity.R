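test_that("simple-matching distance handles missingness by pairwise deletion", {
  g <- g_tbl(rbind(c(1, 2, 3, 0),
                   c(1, 2, 1, 2),
                   c(1, 2, 3, 0)))
  d <- as.matrix(genetic_distance(g))
  # hand count: markers 1-3 comparable, 2 match -> 1 - 2/3
  expect_equal(d["A01", "A02"], 1 - 2 / 3, tolerance = 1e-12)
  # identical rows at distance zero
  expect_equal(d["A01", "A03"], 0)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  # rows differing at every comparable marker
  g2 <- g_tbl(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(as.vector(genetic_distance(g2)), 1)
  # no comparable markers -> NA with warning
  g3 <- g_tbl(rbind(c(1, 0), c(0, 2)))
  expect_warning(d3 <- genetic_distance(g3), "no comparable")
  expect_true(is.na(as.vector(d3)))
})

test_that("UPGMA reproduces hand agglomeration and is ultrametric", {
  d <- as.dist(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- upgma_tree(d)
  # hand agglomeration: ((A:1,B:1):1,C:2)
  cop <- ape::cophenetic.phylo(tr)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 4)
  expect_equal(cop["B", "C"], 4)
  # pendant edges to A and B are 1; root-to-leaf depth equal (ultrametric)
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  # ultrametric on random matrices, and cophenetic >= input merge structure
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(runif(36, 0.2, 1), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    tri <- upgma_tree(as.dist(m))
    dep <- ape::node.depth.edgelength(tri)[seq_len(6)]
    expect_equal(max(dep) - min(dep), 0, tolerance = 1e-9)
  }
  expect_error(upgma_tree(as.dist(matrix(c(0, NA, NA, 0), 2))), "undefined")
})

test_that("UPGMA on an ultrametric matrix reproduces its cophenetic matrix", {
  set.seed(13)
  m <- matrix(runif(64), 8, 8)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(LETTERS[1:8], LETTERS[1:8])
  ultra <- ape::cophenetic.phylo(upgma_tree(as.dist(m)))  # ultrametric by construction
  again <- ape::cophenetic.phylo(upgma_tree(as.dist(ultra)))
  expect_equal(again[rownames(ultra), colnames(ultra)], ultra,
               tolerance = 1e-9)
})

test_that("neighbor joining recovers additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)): additive tip distances
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 5
  m["A", "D"] <- m["D", "A"] <- 3
  m["B", "C"] <- m["C", "B"] <- 6
  m["B", "D"] <- m["D", "B"] <- 4
  m["C", "D"] <- m["D", "C"] <- 4
  tr <- nj_tree(as.dist(m))
  cop <- ape::cophenetic.phylo(tr)
  expect_equal(cop[rownames(m), colnames(m)], m, tolerance = 1e-9)
  # star-like equidistant 3 taxa: equal pendant lengths
  s <- as.dist(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  st <- nj_tree(s)
  expect_equal(unname(st$edge.length), rep(1, 3))
  expect_error(nj_tree(as.dist(matrix(c(0, 1, 1, 0), 2))), ">= 3")
})

test_that("NJ branch lengths are non-negative after sibling correction", {
  set.seed(14)
  for (i in 1:10) {
    n <- 7
    m <- matrix(runif(n * n, 0.05, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(as.dist(m))
    expect_true(all(tr$edge.length >= 0))
    expect_setequal(tr$tip.label, letters[1:n])
  }
})

test_that("NJ on ultrametric input matches the UPGMA topology", {
  set.seed(15)
  for (i in 1:5) {
    m <- matrix(runif(49), 7, 7)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:7], letters[1:7])
    u <- upgma_tree(as.dist(m))
    ultra <- ape::cophenetic.phylo(u)
    lbl <- rownames(ultra)
    nj_t <- nj_tree(as.dist(ultra))
    expect_equal(ape::dist.topo(ape::unroot(u), ape::unroot(nj_t)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("PCA separates duplicated-row clusters and fixes signs", {
  g <- g_tbl(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1),
                   c(2, 2, 2, 2), c(2, 2, 2, 2)))
  p <- pca_genotypes(g, n_components = 2)
  # two-point geometry: PC1 carries all variance
  expect_equal(p$explained$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(length(unique(round(p$coordinates$PC1[1:2], 9))), 1)
  expect_true(abs(p$coordinates$PC1[1] - p$coordinates$PC1[3]) > 1)
  # constant matrix: zero variance everywhere
  gc <- g_tbl(matrix(1L, 5, 4))
  pc <- pca_genotypes(gc, n_components = 2)
  expect_equal(pc$explained$explained_variance, c(0, 0))
  # coordinates invariant under accession reordering (signs fixed)
  set.seed(16)
  gr <- g_tbl(matrix(sample(c(1L, 2L, 3L), 60, TRUE), 10, 6))
  p1 <- pca_genotypes(gr, n_components = 3)
  perm <- sample(10)
  p2 <- pca_genotypes(gr[perm, ], n_components = 3)
  reordered <- p2$coordinates[match(p1$coordinates$accession_id,
                                    p2$coordinates$accession_id), ]
  expect_equal(as.matrix(reordered[-1]), as.matrix(p1$coordinates[-1]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # explained fractions non-increasing, sum <= 1
  expect_true(all(diff(p1$explained$explained_variance) <= 1e-12))
  expect_lte(sum(p1$explained$explained_variance), 1 + 1e-12)
})

test_that("planted subpopulations are recovered by cutting the UPGMA tree", {
  skip_if_not_installed("mclust")
  pop <- simulate_population(n_accessions = 40, K_true = 2, fst = 0.5,
                             n_markers = 100, seed = 77)
  cl <- upgma_clusters(genetic_distance(pop$genotypes), k = 2)
  ari <- mclust::adjustedRandIndex(cl, pop$membership)
  expect_gte(ari, 0.9)
})

test_that("tidy, glance and autoplot work on PCA results", {
  set.seed(17)
  g <- g_tbl(matrix(sample(c(1L, 2L), 40, TRUE), 8, 5))
  p <- pca_genotypes(g, n_components = 2)
  td <- tidy(p)
  expect_equal(nrow(td), 16)
  expect_named(td, c("accession_id", "component", "coordinate"))
  gl <- glance(p)
  expect_named(gl, c("PC1", "PC2"))
  expect_s3_class(autoplot(p), "ggplot")
})
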