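test_that("square-root transform is element-wise and rejects negatives", {
  expect_equal(sqrt_transform(matrix(c(0.25, 0.75), 1)),
               matrix(c(0.5, sqrt(0.75)), 1))
  z <- matrix(0, 2, 3)
  expect_equal(sqrt_transform(z), z)
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sqrt_transform(b), b)  # idempotent only on 0/1 entries
  expect_error(sqrt_transform(matrix(-1)), "negative")
})

test_that("Bray-Curtis matches hand-evaluated cases and its range bounds", {
  m <- rbind(a = c(1, 0), b = c(0.5, 0.5), c = c(1, 0), d = c(0, 2))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 50)
  expect_equal(d["a", "c"], 0)       # identity of indiscernibles
  expect_equal(d["a", "d"], 100)     # disjoint support
  expect_identical(unclass(d), t(unclass(d)))
  expect_error(bray_curtis(rbind(x = c(0, 0), y = c(0, 0))), "all-zero pair")

  set.seed(121)
  r <- matrix(runif(60), 6, 10, dimnames = list(letters[1:6], NULL))
  dr <- bray_curtis(r)
  expect_true(all(dr >= 0 & dr <= 100))
})

test_that("Kulczynski similarity matches hand cases and vegan", {
  m <- rbind(x = c(1, 1), y = c(1, 0))
  s <- kulczynski_similarity(m)
  expect_equal(s["x", "y"], 75)                     # a=1, b=1, c=0
  expect_equal(s["x", "x"], 100)
  dis <- kulczynski_similarity(rbind(x = c(1, 0), y = c(0, 1)))
  expect_equal(dis["x", "y"], 0)                    # a = 0
  expect_error(kulczynski_similarity(rbind(x = c(1, 0), y = c(0, 0))),
               "all-zero row")

  skip_if_not_installed("vegan")
  set.seed(122)
  b <- matrix(rbinom(80, 1, 0.5), 8, 10, dimnames = list(letters[1:8], NULL))
  b[rowSums(b) == 0, 1] <- 1
  ours <- (100 - kulczynski_similarity(b)) / 100
  ref <- as.matrix(vegan::vegdist(b, method = "kulczynski", binary = TRUE))
  expect_equal(unclass(ours), ref, tolerance = 1e-12, ignore_attr = TRUE)

  r <- matrix(runif(80), 8, 10, dimnames = list(letters[1:8], NULL))
  expect_equal(unclass(bray_curtis(r)) / 100,
               as.matrix(vegan::vegdist(r, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCO reproduces the n = 2 closed form and degenerate cases", {
  d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- pco(d)
  expect_equal(r$eigenvalues[1], 8)
  expect_equal(sort(unname(r$coordinates[, 1])), c(-2, 2))

  # three mutually equidistant samples: two equal positive eigenvalues
  d3 <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  r3 <- pco(d3)
  pos <- r3$eigenvalues[r3$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2])

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  rz <- pco(z)
  expect_equal(ncol(rz$coordinates), 0L)
  expect_true(all(abs(rz$eigenvalues) < 1e-12))
})

test_that("PCO preserves Euclidean-embeddable distances", {
  set.seed(123)
  pts <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:8], letters[1:8])
  r <- pco(D)
  expect_lt(max(abs(as.matrix(dist(r$coordinates)) - D)), 1e-6)
  expect_equal(r$negative_mass, 0, tolerance = 1e-9)

  # invariance (up to sign canonicalization) under sample reordering
  perm <- sample(8)
  r2 <- pco(D[perm, perm])
  expect_equal(abs(r2$coordinates[letters[1:8], 1]),
               abs(r$coordinates[, 1]), tolerance = 1e-8)

  # cross-check the eigenvalues against classical MDS
  cmd <- cmdscale(as.dist(D), k = 3, eig = TRUE)
  expect_equal(r$eigenvalues[1:3], cmd$eig[1:3], tolerance = 1e-8)
})

test_that("UPGMA merges by group average and slices into nested partitions", {
  ids <- c("a", "b", "c", "d")
  s <- matrix(50, 4, 4, dimnames = list(ids, ids))
  diag(s) <- 100
  s["a", "b"] <- s["b", "a"] <- 90
  s["c", "d"] <- s["d", "c"] <- 90
  dend <- upgma(structure(s, class = c("similarity_matrix", "matrix")))
  expect_equal(sort(dend$heights_similarity), c(50, 90, 90))

  cuts <- slice_dendrogram(dend, c(75, 95))
  expect_equal(max(cuts[["75"]]), 2L)
  expect_equal(max(cuts[["95"]]), 4L)
  expect_equal(cuts[["75"]][["a"]], cuts[["75"]][["b"]])
  expect_false(cuts[["75"]][["a"]] == cuts[["75"]][["c"]])

  # all similarities 100: one cluster at height 100
  s1 <- matrix(100, 3, 3, dimnames = list(ids[1:3], ids[1:3]))
  d1 <- upgma(structure(s1, class = c("similarity_matrix", "matrix")))
  expect_true(all(d1$heights_similarity == 100))
  expect_equal(max(slice_dendrogram(d1, 100)[[1]]), 1L)

  # nested refinement across the standard overlay thresholds
  set.seed(124)
  b <- matrix(rbinom(120, 1, 0.5), 8, 15,
              dimnames = list(paste0("g", 1:8), NULL))
  b[rowSums(b) == 0, 1] <- 1
  dend2 <- upgma(kulczynski_similarity(b))
  cuts2 <- slice_dendrogram(dend2, c(75, 80, 85, 90, 95))
  for (i in 1:4) {
    lo <- cuts2[[i]]; hi <- cuts2[[i + 1]]
    # refinement: genomes together at the higher threshold stay together below
    for (cl in unique(hi)) {
      members <- names(hi)[hi == cl]
      expect_length(unique(lo[members]), 1L)
    }
    expect_gte(max(hi), max(lo))
  }

  # slicing at t = 0-equivalent (all merges kept) gives one cluster
  expect_equal(max(slice_dendrogram(dend2, 1e-9)[[1]]), 1L)
})

test_that("Newick export round-trips through ape", {
  ids <- c("a", "b", "c")
  s <- matrix(c(100, 90, 40, 90, 100, 40, 40, 40, 100), 3, 3,
              dimnames = list(ids, ids))
  dend <- upgma(structure(s, class = c("similarity_matrix", "matrix")))
  nwk <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, ids)

  f <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(dend, f)
  expect_setequal(ape::read.tree(f)$tip.label, ids)
})

test_that("similarity converts to dissimilarity as 100 - s", {
  s <- matrix(c(100, 80, 80, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- similarity_to_dissimilarity(s)
  expect_equal(d["a", "b"], 20)
  expect_equal(unname(diag(unclass(d))), c(0, 0))
})

test_that("synthetic habitat groups separate on PCO axis 1 of pI spectra", {
  col <- synthesize_collection(small_two_habitat_config(seed = 125))
  spectra <- pi_spectrum_table(col$proteomes)
  d <- bray_curtis(sqrt_transform(spectra))
  r <- pco(d)
  md <- col$metadata
  ax1 <- r$coordinates[, 1]
  g1 <- ax1[md$genome_id[md$habitat == "marine"]]
  g2 <- ax1[md$genome_id[md$habitat == "freshwater"]]
  between <- abs(mean(g1) - mean(g2))
  within <- mean(c(abs(g1 - mean(g1)), abs(g2 - mean(g2))))
  expect_gt(between, within)
})
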