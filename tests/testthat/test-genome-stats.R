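test_that("GC content follows the N-exclusion rule", {
  expect_equal(gc_content(genome_assembly("g", c(c1 = "GGCC"))), 100)
  expect_equal(gc_content(genome_assembly("g", c(c1 = "ATAT"))), 0)
  expect_equal(gc_content(genome_assembly("g", c(c1 = "ATGCN"))), 50)
  expect_error(gc_content(genome_assembly("g", c(c1 = "NNNN"))),
               "undefined")
})

test_that("median intergenic spacer pools clamped gaps across contigs", {
  a <- genome_assembly("g", c(c1 = strrep("A", 400)))
  ft <- feature_table("g", data.frame(
    contig_id = "c1", start = c(1L, 151L, 351L), end = c(100L, 300L, 400L),
    strand = "+", feature_id = c("x", "y", "z")), a)
  expect_equal(median_intergenic_spacer(ft, a), 50L)

  # overlapping CDS contribute a gap of 0
  ov <- feature_table("g", data.frame(
    contig_id = "c1", start = c(1L, 50L, 351L), end = c(100L, 200L, 400L),
    strand = "+", feature_id = c("x", "y", "z")), a)
  expect_equal(median_intergenic_spacer(ov, a), 75L)  # gaps {0, 150}, rounded up

  single <- feature_table("g", data.frame(
    contig_id = "c1", start = 1L, end = 100L, strand = "+",
    feature_id = "x"), a)
  expect_error(median_intergenic_spacer(single, a), "undefined")
})

test_that("median intergenic spacer is invariant to contig order and translation", {
  set.seed(51)
  a <- genome_assembly("g", c(c1 = random_dna_string(2000),
                              c2 = random_dna_string(1500)))
  df <- data.frame(
    contig_id = c("c1", "c1", "c1", "c2", "c2"),
    start = c(10L, 200L, 900L, 5L, 700L),
    end = c(150L, 700L, 1400L, 600L, 1200L),
    strand = "+", feature_id = letters[1:5])
  base <- median_intergenic_spacer(feature_table("g", df, a), a)

  perm <- df[c(4, 1, 5, 2, 3), ]
  expect_equal(median_intergenic_spacer(feature_table("g", perm, a), a), base)

  shifted <- df
  shifted$start <- shifted$start + 100L
  shifted$end <- shifted$end + 100L
  a2 <- genome_assembly("g", c(c1 = random_dna_string(2100),
                               c2 = random_dna_string(1600)))
  expect_equal(median_intergenic_spacer(feature_table("g", shifted, a2), a2),
               base)
})

test_that("coding density times genome size equals merged CDS bp", {
  set.seed(52)
  a <- genome_assembly("g", c(c1 = random_dna_string(3000)))
  # overlapping features: merged span is 1..500 plus 1000..1500
  ft <- feature_table("g", data.frame(
    contig_id = "c1", start = c(1L, 200L, 1000L), end = c(400L, 500L, 1500L),
    strand = "+", feature_id = c("a", "b", "c")), a)
  d <- genome_descriptors(a, ft)
  expect_equal(d$coding_density * d$size_bp, 500 + 501)
  expect_equal(d$n_cds, 3L)
  expect_equal(d$size_bp, 3000)
})

test_that("group summaries report mean and sample SD", {
  desc <- data.frame(genome_id = c("g1", "g2", "g3"),
                     size_bp = c(2e6, 3e6, 5e6), gc_percent = c(50, 60, 55),
                     n_cds = c(2000L, 3000L, 2500L),
                     median_intergenic_bp = c(50L, 60L, 70L),
                     coding_density = c(0.9, 0.8, 0.85))
  md <- strain_metadata(data.frame(
    genome_id = c("g1", "g2", "g3"),
    habitat = c("marine", "marine", "freshwater"),
    subcluster = c("5.1", "5.1", "5.2")))
  s <- summarize_groups(desc, md, "habitat")
  marine_size <- s[s$group == "marine" & s$descriptor == "size_bp", ]
  expect_equal(marine_size$mean, 2.5e6)
  expect_equal(marine_size$sd, sd(c(2e6, 3e6)))
  fresh_size <- s[s$group == "freshwater" & s$descriptor == "size_bp", ]
  expect_equal(fresh_size$n, 1L)
  expect_true(is.na(fresh_size$sd))
})

test_that("one-way ANOVA matches hand-computed examples", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$F, 1.5)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "degenerate F")
  expect_error(one_way_anova(list(c(1, 2), c(3))), ">= 2 values")
})

test_that("two-group ANOVA satisfies F = t^2 on random data", {
  set.seed(53)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    r <- one_way_anova(list(x, y))
    expect_equal(r$F, pooled_t(x, y)^2, tolerance = 1e-10)
  }
})

test_that("F p-values match a numeric-quadrature oracle of the F density", {
  f_density <- function(x, d1, d2) {
    exp((d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(x) -
          ((d1 + d2) / 2) * log(1 + d1 * x / d2) - lbeta(d1 / 2, d2 / 2))
  }
  cases <- expand.grid(f = c(0.3, 1.5, 4.2, 10), d1 = c(1, 2, 5),
                       d2 = c(4, 10, 30))
  for (i in seq_len(nrow(cases))) {
    p_quad <- integrate(f_density, cases$f[i], Inf, d1 = cases$d1[i],
                        d2 = cases$d2[i], rel.tol = 1e-10)$value
    p_pkg <- picopan:::f_pvalue(cases$f[i], cases$d1[i], cases$d2[i])
    expect_equal(p_pkg, p_quad, tolerance = 1e-6)
  }
})

test_that("pairwise ANOVA separates synthetic habitat size contrasts", {
  col <- synthesize_collection(small_two_habitat_config(seed = 61))
  desc <- do.call(rbind, lapply(names(col$assemblies), function(gid)
    genome_descriptors(col$assemblies[[gid]], col$features[[gid]])))
  res <- pairwise_anova(desc, col$metadata, "habitat", "gc_percent")
  expect_equal(nrow(res), 1L)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$df_within, nrow(desc) - 2L)
})
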