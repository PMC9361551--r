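test_that("identical proteins cluster into one family, unrelated ones split", {
  set.seed(101)
  shared <- random_protein_string(220)
  ps <- list(
    proteome("g1", c(shared = shared, solo1 = random_protein_string(180))),
    proteome("g2", c(shared = shared, solo2 = random_protein_string(180))),
    proteome("g3", c(shared = shared))
  )
  cl <- cluster_proteins(ps)
  sizes <- sort(vapply(cl$members, nrow, 0L))
  expect_equal(unname(sizes), c(1L, 1L, 3L))
  big <- cl$members[[which.max(vapply(cl$members, nrow, 0L))]]
  expect_setequal(big$genome_id, c("g1", "g2", "g3"))
})

test_that("protein clustering reproduces the synthetic ground-truth partition", {
  col <- synthesize_collection(small_two_habitat_config(seed = 103))
  cl <- cluster_proteins(col$proteomes)
  expect_equal(length(cl$members), length(col$truth$family_members))
  recovered <- lapply(cl$members, function(d)
    sort(paste(d$genome_id, d$protein_id)))
  truth <- lapply(names(col$truth$family_members), function(f)
    sort(paste(col$truth$family_members[[f]], f)))
  expect_setequal(vapply(recovered, paste, "", collapse = "|"),
                  vapply(truth, paste, "", collapse = "|"))
  # and the derived matrix matches the truth matrix up to family labels
  pa <- pa_from_clusters(cl)
  pa_truth <- pa_from_truth(col$truth)
  expect_setequal(unname(apply(unclass(pa)[, colnames(pa_truth)], 1, paste,
                               collapse = "")),
                  unname(apply(unclass(pa_truth), 1, paste, collapse = "")))
})

test_that("pangenome partition follows the printed occupancy rules", {
  mk <- function(occs, n) {
    m <- matrix(0L, length(occs), n,
                dimnames = list(sprintf("f%02d", seq_along(occs)),
                                sprintf("g%02d", seq_len(n))))
    for (i in seq_along(occs)) m[i, seq_len(occs[i])] <- 1L
    pa_matrix(m)
  }
  p20 <- partition_pangenome(mk(c(20, 19, 18, 2, 1, 10), 20))
  expect_identical(unname(p20$category),
                   c("strict_core", "soft_core", "shell", "cloud", "cloud",
                     "shell"))
  p100 <- partition_pangenome(mk(c(100, 95, 94, 2, 50), 100))
  expect_identical(unname(p100$category),
                   c("strict_core", "soft_core", "shell", "cloud", "shell"))
  # precedence: occupancy 2 of 3 is cloud, not shell
  p3 <- partition_pangenome(mk(c(3, 2), 3))
  expect_identical(unname(p3$category), c("strict_core", "cloud"))
  empty <- structure(matrix(0L, 0, 5,
                            dimnames = list(character(0),
                                            sprintf("g%02d", 1:5))),
                     occupancy = integer(0), class = c("pa_matrix", "matrix"))
  expect_error(partition_pangenome(empty), "empty")
  expect_error(partition_pangenome(mk(c(2, 1), 2)), ">= 3 genomes")
  expect_equal(sum(p20$totals), 6L)
})

test_that("partition matches a brute-force re-count on random matrices", {
  set.seed(105)
  for (i in 1:40) {
    pa <- random_pa(sample(5:50, 1), sample(3:20, 1))
    p <- partition_pangenome(pa)
    expect_identical(p$category, brute_force_partition(pa))
  }
  # plus a handful at the larger end of the documented range
  for (i in 1:5) {
    pa <- random_pa(200, 50)
    expect_identical(partition_pangenome(pa)$category,
                     brute_force_partition(pa))
  }
})

test_that("category counts are invariant under row/column permutation", {
  set.seed(106)
  pa <- random_pa(30, 10)
  p <- partition_pangenome(pa)
  perm <- pa_matrix(unclass(pa)[sample.int(30), sample.int(10)])
  expect_equal(partition_pangenome(perm)$totals, p$totals)
})

test_that("rarefaction curves are monotone and pinned at g = 1", {
  set.seed(107)
  pa <- random_pa(60, 12)
  rc <- rarefaction_curves(pa, R = 25, seed = 9)
  expect_true(all(diff(t(rc$core)) <= 0))
  expect_true(all(diff(t(rc$pan)) >= 0))
  expect_equal(rc$core[, 1], rc$pan[, 1])

  # identical genomes: both curves constant, core == pan
  m <- matrix(1L, 10, 5, dimnames = list(sprintf("f%d", 1:10),
                                         sprintf("g%d", 1:5)))
  rc2 <- rarefaction_curves(pa_matrix(m), R = 5, seed = 1)
  expect_true(all(rc2$core == 10L))
  expect_true(all(rc2$pan == 10L))

  # determinism under the same seed
  rc3 <- rarefaction_curves(pa, R = 25, seed = 9)
  expect_identical(rc$core, rc3$core)
})

test_that("habitat profiles count occupancy and flag specific families", {
  pa <- pa_matrix(matrix(
    c(1, 1, 0, 0, 0,   # 2/3 freshwater, 0/2 marine -> freshwater-specific
      1, 1, 1, 1, 1,   # everywhere -> no flag
      0, 1, 1, 1, 1,   # all marine but also 2/3 freshwater -> no flag
      1, 0, 0, 1, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("f1", "f2", "f3", "f4"),
                    c("fw1", "fw2", "fw3", "m1", "m2"))))
  md <- strain_metadata(data.frame(
    genome_id = c("fw1", "fw2", "fw3", "m1", "m2"),
    habitat = c("freshwater", "freshwater", "freshwater", "marine", "marine"),
    subcluster = c("5.2", "5.2", "5.2", "5.1", "5.1")))
  hp <- habitat_gene_profile(pa, md)
  expect_equal(hp$habitat_counts["f1", "freshwater"], 2)
  expect_equal(hp$habitat_counts["f1", "marine"], 0)
  expect_equal(hp$specific[["f1"]], "freshwater")
  expect_true(is.na(hp$specific[["f2"]]))
  expect_true(is.na(hp$specific[["f3"]]))
  expect_true(is.na(hp$specific[["f4"]]))  # present in both habitats
  expect_equal(hp$habitat_sizes[["freshwater"]], 3L)

  expect_error(habitat_gene_profile(pa, md[-1, ]), "missing from metadata")
})

test_that("ground-truth habitat-specific families are all flagged, no false flags", {
  col <- synthesize_collection(small_two_habitat_config(seed = 109))
  pa <- pa_from_truth(col$truth)
  hp <- habitat_gene_profile(pa, col$metadata)
  truth_spec <- col$truth$family_habitat
  for (f in names(truth_spec)) {
    if (truth_spec[[f]] == "none") {
      expect_true(is.na(hp$specific[[f]]))
    } else {
      expect_equal(hp$specific[[f]], truth_spec[[f]])
    }
  }
})
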