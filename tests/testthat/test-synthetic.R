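test_that("soft-core occupancy planning follows the 95% arithmetic", {
  # 20 genomes: smallest k with k/20 >= 0.95 and k < 20 is 19
  cfg <- synthetic_config(
    seed = 1,
    groups = list(group_spec("a", "marine", "5.1", 20, c(5, 0.2), 0.5,
                             divergence = 0.01)),
    pool = pool_spec(n_strict_core = 1, n_soft_core = 1, n_shell = 0,
                     n_cloud = 0, n_habitat_specific = 0,
                     mean_gene_bp = 300, spacer_bp = 30))
  pool <- build_gene_pool(cfg)
  expect_equal(pool$families$occupancy[pool$families$class == "soft_core"],
               19L)

  # 10 genomes: no integer k satisfies both constraints
  cfg10 <- synthetic_config(
    seed = 1,
    groups = list(group_spec("a", "marine", "5.1", 10, c(5, 0.2), 0.5,
                             divergence = 0.01)),
    pool = pool_spec(n_strict_core = 1, n_soft_core = 1, n_shell = 0,
                     n_cloud = 0, n_habitat_specific = 0,
                     mean_gene_bp = 300, spacer_bp = 30))
  expect_error(build_gene_pool(cfg10), "soft core infeasible")
})

test_that("cloud families land in 1-2 genomes and strict core in all", {
  cfg <- synthetic_config(
    seed = 5,
    groups = list(group_spec("a", "marine", "5.1", 5, c(5, 0.2), 0.5,
                             divergence = 0.01)),
    pool = pool_spec(n_strict_core = 2, n_soft_core = 0, n_shell = 0,
                     n_cloud = 6, n_habitat_specific = 0,
                     mean_gene_bp = 300, spacer_bp = 30))
  pool <- build_gene_pool(cfg)
  occ <- pool$families$occupancy
  cls <- pool$families$class
  expect_true(all(occ[cls == "cloud"] %in% 1:2))
  expect_true(all(occ[cls == "strict_core"] == 5L))
})

test_that("evolve_family honours its substitution kernel", {
  set.seed(41)
  anc <- random_dna_string(30000, gc = 0.5)
  expect_identical(evolve_family(anc, 0, 0.5, seed = 3), anc)
  # determinism, including the degenerate p = 1 case
  expect_identical(evolve_family(anc, 1, 0.6, seed = 9),
                   evolve_family(anc, 1, 0.6, seed = 9))

  # p = 0.05: realized identity within 3 binomial SD of the closed form
  p <- 0.05
  d <- evolve_family(anc, p, 0.5, seed = 17)
  obs <- mean(strsplit(anc, "")[[1]] == strsplit(d, "")[[1]])
  expected <- expected_identity(anc, p, 0.5) / 100
  se <- sqrt(expected * (1 - expected) / nchar(anc))
  expect_lt(abs(obs - expected), 3 * se)
  expect_equal(nchar(d), nchar(anc))  # no indels
})

test_that("synthesized collections are deterministic byte for byte", {
  cfg <- small_two_habitat_config(seed = 77)
  c1 <- synthesize_collection(cfg)
  c2 <- synthesize_collection(small_two_habitat_config(seed = 77))
  expect_identical(c1$assemblies, c2$assemblies)
  expect_identical(c1$proteomes, c2$proteomes)
  expect_identical(c1$truth, c2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_collection(c1, d1); write_collection(c2, d2)
  gid <- names(c1$assemblies)[1]
  expect_identical(readBin(file.path(d1, paste0(gid, ".fna")), "raw", 1e6),
                   readBin(file.path(d2, paste0(gid, ".fna")), "raw", 1e6))
})

test_that("realized GC tracks the group target", {
  cfg <- synthetic_config(
    seed = 13,
    groups = list(group_spec("a", "marine", "5.1", 3, c(100, 0), 0.60,
                             divergence = 0.01, divergence_from_pool = 0)),
    pool = pool_spec(n_strict_core = 20, n_soft_core = 0, n_shell = 0,
                     n_cloud = 0, n_habitat_specific = 0,
                     mean_gene_bp = 900, spacer_bp = 100))
  col <- synthesize_collection(cfg)
  gc <- vapply(col$assemblies, gc_content, 0)
  expect_true(all(abs(gc - 60) < 1))
})

test_that("opposing acidity shifts produce the marine-acidic pI contrast", {
  col <- synthesize_collection(small_two_habitat_config(seed = 19))
  md <- col$metadata
  mean_pi <- vapply(col$proteomes, function(p) mean(protein_pi(p$proteins)), 0)
  marine <- mean(mean_pi[md$genome_id[md$habitat == "marine"]])
  fresh <- mean(mean_pi[md$genome_id[md$habitat == "freshwater"]])
  expect_lt(marine, fresh)
})

test_that("collection structure matches its ground truth", {
  cfg <- small_two_habitat_config(seed = 23)
  col <- synthesize_collection(cfg)
  truth <- col$truth
  ids <- col$metadata$genome_id
  expect_setequal(names(col$assemblies), ids)

  # every feature carries its family id, matches a protein, and has a
  # codon-aligned length inside the contig
  for (gid in ids) {
    feats <- col$features[[gid]]$features
    expect_setequal(feats$feature_id, names(col$proteomes[[gid]]$proteins))
    expect_true(all((feats$end - feats$start + 1L) %% 3L == 0L))
    expect_true(all(feats$end <= nchar(col$assemblies[[gid]]$contigs[1])))
  }

  # family membership is consistent with the emitted features
  for (f in names(truth$family_members)) {
    carriers <- ids[vapply(ids, function(gid)
      f %in% col$features[[gid]]$features$feature_id, TRUE)]
    expect_setequal(carriers, truth$family_members[[f]])
  }

  # habitat-specific families occur only in genomes of that habitat
  hab_fams <- names(truth$family_habitat)[truth$family_habitat != "none"]
  for (f in hab_fams) {
    habs <- unique(col$metadata$habitat[match(truth$family_members[[f]],
                                              col$metadata$genome_id)])
    expect_identical(habs, truth$family_habitat[[f]])
  }

  # expected ANI bounds and symmetry
  expect_true(all(truth$expected_ani >= 70 & truth$expected_ani <= 100))
  expect_identical(truth$expected_ani, t(truth$expected_ani))

  # translated genes match the emitted proteomes before the acidity shift
  # only where the shift is zero; here check lengths instead
  for (gid in ids[1:2]) {
    feats <- col$features[[gid]]$features
    plen <- nchar(col$proteomes[[gid]]$proteins[feats$feature_id])
    expect_equal(unname(plen), (feats$end - feats$start + 1L) / 3L)
  }
})

test_that("groups with zero genomes are rejected", {
  expect_error(
    synthesize_collection(synthetic_config(
      seed = 2,
      groups = list(group_spec("a", "marine", "5.1", 0, c(5, 1), 0.5)),
      pool = pool_spec(n_strict_core = 1, n_soft_core = 0, n_shell = 0,
                       n_cloud = 0, n_habitat_specific = 0))),
    "n_genomes = 0")
  expect_error(synthetic_config(seed = NULL, groups = list()), "seed")
})
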