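# Shared fixtures: all data is generated in code.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna_string <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein_string <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# point-mutate a protein at the given per-residue rate
mutate_protein <- function(s, rate) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) x[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(x, collapse = "")
}

# a small two-habitat collection: fast enough for clustering tests
small_two_habitat_config <- function(seed = 11) {
  synthetic_config(
    seed = seed,
    groups = list(
      group_spec("m", "marine", "5.1", n_genomes = 4, genome_kb = c(10, 1),
                 gc_target = 0.58, acidity_shift = +0.10,
                 divergence = 0.02, divergence_from_pool = 0.10),
      group_spec("f", "freshwater", "5.2", n_genomes = 4,
                 genome_kb = c(11, 1), gc_target = 0.62,
                 acidity_shift = -0.10, divergence = 0.02,
                 divergence_from_pool = 0.10)
    ),
    pool = pool_spec(n_strict_core = 5, n_soft_core = 0, n_shell = 3,
                     n_cloud = 2, n_habitat_specific = 2,
                     mean_gene_bp = 450, spacer_bp = 60)
  )
}

# random binary presence/absence matrix with no empty families
random_pa <- function(n_fam, n_gen) {
  m <- matrix(rbinom(n_fam * n_gen, 1L, runif(1, 0.2, 0.8)),
              n_fam, n_gen,
              dimnames = list(sprintf("f%03d", seq_len(n_fam)),
                              sprintf("g%03d", seq_len(n_gen))))
  empty <- rowSums(m) == 0L
  m[empty, sample.int(n_gen, 1L)] <- 1L
  pa_matrix(m)
}

# independent brute-force re-count of the pangenome partition rules
brute_force_partition <- function(pa) {
  n <- ncol(pa)
  vapply(rownames(pa), function(f) {
    occ <- 0L
    for (g in colnames(pa)) if (unclass(pa)[f, g] == 1L) occ <- occ + 1L
    if (occ == n) "strict_core"
    else if (occ >= 0.95 * n) "soft_core"
    else if (occ <= 2L) "cloud"
    else "shell"
  }, "")
}

# grid-scan oracle for the isoelectric point: finest pH with charge > 0,
# refined to the midpoint of the bracketing grid step
grid_pi <- function(sequence, pka = pka_table(), step = 1e-4) {
  grid <- seq(0, 14, by = step)
  ch <- net_charge(sequence, grid, pka)
  if (ch[1] <= 0) return(0)
  if (ch[length(ch)] >= 0) return(14)
  i <- max(which(ch > 0))
  (grid[i] + grid[i + 1]) / 2
}

# pooled-variance two-sample t statistic, implemented independently of
# one_way_anova
pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
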