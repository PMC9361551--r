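BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Group specification for the synthetic collection generator
#'
#' One group is a set of strains sharing a habitat, a sub-cluster, a genome
#' size distribution, a GC target, a proteome acidity shift and a divergence
#' level. Groups play the role of the species-level clusters the collection
#' is meant to contain.
#'
#' @param name Unique group name (used to build genome ids).
#' @param habitat One of `marine`, `brackish`, `freshwater`.
#' @param subcluster One of `5.1`, `5.2`, `5.3`.
#' @param n_genomes Number of genomes in the group.
#' @param genome_kb Length-2 numeric `c(mean, sd)` of genome size in kb.
#' @param gc_target Whole-genome GC fraction in (0, 1).
#' @param acidity_shift delta in \[-0.15, 0.15\]: fraction of basic residues
#'   (K, R) moved to acidic ones (D, E) in every protein when positive;
#'   the reverse move when negative. Controls the proteome pI contrast.
#' @param divergence Within-group per-site substitution probability in
#'   \[0, 0.3\] applied from the group ancestor to each genome.
#' @param divergence_from_pool Per-site substitution probability from the
#'   shared ancestral gene pool to this group's ancestor; sets the deep
#'   between-group divergence (default 0.15, i.e. between-group ANI far
#'   below the species threshold).
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, habitat, subcluster, n_genomes,
                       genome_kb, gc_target, acidity_shift = 0,
                       divergence = 0.02, divergence_from_pool = 0.15) {
  stopifnot(is.character(name), nzchar(name),
            habitat %in% HABITATS, as.character(subcluster) %in% SUBCLUSTERS,
            n_genomes >= 0, length(genome_kb) == 2L, all(genome_kb >= 0),
            gc_target > 0, gc_target < 1,
            acidity_shift >= -0.15, acidity_shift <= 0.15,
            divergence >= 0, divergence <= 0.3,
            divergence_from_pool >= 0, divergence_from_pool <= 0.3)
  structure(list(name = name, habitat = habitat,
                 subcluster = as.character(subcluster),
                 n_genomes = as.integer(n_genomes),
                 genome_kb = as.numeric(genome_kb),
                 gc_target = gc_target, acidity_shift = acidity_shift,
                 divergence = divergence,
                 divergence_from_pool = divergence_from_pool),
            class = "group_spec")
}

#' Gene-pool specification for the synthetic collection generator
#'
#' Declares how many gene families of each occupancy class the collection
#' carries: strict core (all genomes), soft core (>= 95% but not all),
#' shell (intermediate), cloud (1-2 genomes) and habitat-specific families
#' (present in every genome of one habitat, absent elsewhere).
#'
#' @param n_strict_core,n_soft_core,n_shell,n_cloud Family counts (>= 0).
#' @param n_habitat_specific Families per habitat present in the config.
#' @param mean_gene_bp Mean ancestral gene length (bp); lengths are drawn
#'   from Normal(mean, 10% of mean), rounded to a multiple of 3, min 90.
#' @param spacer_bp Mean intergenic spacer length (bp); spacer lengths are
#'   geometric with this mean.
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(n_strict_core = 28, n_soft_core = 6, n_shell = 24,
                      n_cloud = 12, n_habitat_specific = 4,
                      mean_gene_bp = 900, spacer_bp = 120) {
  counts <- c(n_strict_core, n_soft_core, n_shell, n_cloud,
              n_habitat_specific)
  stopifnot(all(counts >= 0), mean_gene_bp >= 90, spacer_bp >= 0)
  structure(list(n_strict_core = as.integer(n_strict_core),
                 n_soft_core = as.integer(n_soft_core),
                 n_shell = as.integer(n_shell),
                 n_cloud = as.integer(n_cloud),
                 n_habitat_specific = as.integer(n_habitat_specific),
                 mean_gene_bp = mean_gene_bp, spacer_bp = spacer_bp),
            class = "pool_spec")
}

#' Synthetic collection configuration
#'
#' @param seed Integer seed; mandatory, all randomness flows from it via
#'   stable per-genome substreams so insertion order cannot change outputs.
#' @param groups List of [group_spec()] objects with unique names.
#' @param pool A [pool_spec()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed, groups, pool = pool_spec()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory: no implicit randomness")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, TRUE, "group_spec")))
  nms <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("group names must be unique")
  structure(list(seed = as.integer(seed), groups = setNames(groups, nms),
                 pool = pool),
            class = "synthetic_config")
}

#' Default study-scale configuration
#'
#' A reduced-scale analogue of a marine/brackish/freshwater cluster-5
#' collection: marine genomes are the smallest with the lowest GC and an
#' acid-shifted proteome; freshwater genomes are the largest, GC-rich and
#' basic-shifted; brackish genomes sit between. Group sizes keep the
#' marine < freshwater imbalance of field collections.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
default_config <- function(seed) {
  synthetic_config(
    seed = seed,
    groups = list(
      group_spec("marine51", "marine", "5.1", n_genomes = 12,
                 genome_kb = c(60, 5.5), gc_target = 0.585,
                 acidity_shift = +0.10, divergence = 0.015),
      group_spec("brackish52", "brackish", "5.2", n_genomes = 4,
                 genome_kb = c(64.5, 8.9), gc_target = 0.64,
                 acidity_shift = +0.03, divergence = 0.025),
      group_spec("fresh52", "freshwater", "5.2", n_genomes = 13,
                 genome_kb = c(70, 9.8), gc_target = 0.64,
                 acidity_shift = -0.10, divergence = 0.030),
      group_spec("fresh53", "freshwater", "5.3", n_genomes = 4,
                 genome_kb = c(62, 6.0), gc_target = 0.53,
                 acidity_shift = -0.10, divergence = 0.020)
    ),
    pool = pool_spec()
  )
}

# ---- seeded substreams -----------------------------------------------------

# 32-bit FNV-1a style hash of a string, reduced to a valid set.seed() value.
stable_hash <- function(key) {
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

substream_seed <- function(seed, ...) {
  stable_hash(paste(c(seed, ...), collapse = "\r"))
}

# Evaluate code under a derived RNG stream, restoring the caller's stream.
with_substream <- function(seed, key, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, key))
  force(code)
}

# ---- sequence primitives ---------------------------------------------------

base_freqs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = base_freqs(gc))
}

# Deterministically remap stop codons (TAA/TAG -> TAT, TGA -> TGT) so
# ancestral genes are stop-free without rejection sampling.
make_stop_free <- function(bases) {
  n <- length(bases)
  stopifnot(n %% 3L == 0L)
  starts <- seq.int(1L, n, 3L)
  codons <- paste0(bases[starts], bases[starts + 1L], bases[starts + 2L])
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) bases[starts[hit] + 2L] <- "T"
  bases
}

#' Evolve a sequence by per-site substitution
#'
#' Each site is substituted independently with probability `p`; the
#' replacement base is drawn with G/C probability `gc_target` (and may equal
#' the original, so the realized difference rate is below `p`). No indels:
#' lengths are preserved, which keeps the expected identity of a pair in
#' closed form.
#'
#' @param ancestor Nucleotide string.
#' @param p Per-site substitution probability in \[0, 0.3\] (values up to 1
#'   are accepted for the degenerate full-randomization case).
#' @param gc_target GC fraction of the substitution target distribution.
#' @param seed Optional integer; when given, the call is deterministic and
#'   leaves the caller's RNG stream untouched.
#' @return The descendant nucleotide string, same length as `ancestor`.
#' @export
evolve_family <- function(ancestor, p, gc_target, seed = NULL) {
  stopifnot(p >= 0, p <= 1, gc_target > 0, gc_target < 1)
  if (!is.null(seed)) {
    return(with_substream(seed, "evolve", evolve_family(ancestor, p, gc_target)))
  }
  x <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < p)
  if (length(hit)) x[hit] <- random_bases(length(hit), gc_target)
  paste(x, collapse = "")
}

#' Expected identity of a descendant against its direct ancestor
#'
#' Closed form for the substitution kernel of [evolve_family()]: a site
#' matches unless it is substituted (prob `p`) to a different base, so
#' identity = `(1 - p) + p * sum(f_b * q_b)` with `f` the ancestor base
#' composition and `q` the substitution target distribution.
#'
#' @param ancestor Nucleotide string (composition is taken from it).
#' @param p Per-site substitution probability.
#' @param gc_target GC fraction of the substitution target distribution.
#' @return Expected percent identity in \[0, 100\].
#' @export
expected_identity <- function(ancestor, p, gc_target) {
  f <- table(factor(strsplit(ancestor, "", fixed = TRUE)[[1]], levels = BASES))
  f <- as.numeric(f) / sum(f)
  q <- base_freqs(gc_target)
  100 * ((1 - p) + p * sum(f * q))
}

# Row-stochastic 4x4 substitution kernel of evolve_family().
sub_kernel <- function(p, gc) {
  q <- base_freqs(gc)
  K <- (1 - p) * diag(4) + p * matrix(q, 4, 4, byrow = TRUE)
  dimnames(K) <- list(BASES, BASES)
  K
}

# Expected identity between two genomes at the ends of a star path:
# pool ancestor -> group ancestor(s) -> genome. Same-group pairs share the
# group step; different-group pairs only share the pool ancestor.
expected_pair_identity <- function(ga, gb, base_gc) {
  c0 <- base_freqs(base_gc)
  if (identical(ga$name, gb$name)) {
    cg <- as.numeric(c0 %*% sub_kernel(ga$divergence_from_pool, ga$gc_target))
    K <- sub_kernel(ga$divergence, ga$gc_target)
    sum(cg * rowSums(K * K)) * 100
  } else {
    Ka <- sub_kernel(ga$divergence_from_pool, ga$gc_target) %*%
      sub_kernel(ga$divergence, ga$gc_target)
    Kb <- sub_kernel(gb$divergence_from_pool, gb$gc_target) %*%
      sub_kernel(gb$divergence, gb$gc_target)
    sum(c0 * rowSums(Ka * Kb)) * 100
  }
}

# ---- gene pool -------------------------------------------------------------

# Smallest occupancy count classified as soft core: k/n >= 0.95 with k < n.
soft_core_occupancy <- function(n_genomes) {
  k <- as.integer(ceiling(0.95 * n_genomes))
  if (k >= n_genomes) {
    stop("soft core infeasible with ", n_genomes, " genomes: the smallest ",
         "k with k/", n_genomes, " >= 0.95 is ", k, ", which is not < ",
         n_genomes, " (need at least 20 genomes)")
  }
  k
}

genome_ids_of <- function(config) {
  unlist(lapply(config$groups, function(g) {
    if (g$n_genomes == 0L) character(0)
    else sprintf("%s_%02d", g$name, seq_len(g$n_genomes))
  }), use.names = FALSE)
}

genome_group_of <- function(config) {
  unlist(unname(lapply(config$groups, function(g) {
    setNames(rep(g$name, g$n_genomes),
             sprintf("%s_%02d", g$name, seq_len(g$n_genomes)))
  })))
}

#' Build the ancestral gene pool and its occupancy plan
#'
#' Draws one ancestral, stop-codon-free nucleotide sequence per gene family
#' and plans which genomes carry each family: strict-core families go to all
#' genomes; soft-core families to the smallest count `k` with
#' `k/n >= 0.95` and `k < n`; cloud families to 1-2 genomes; shell families
#' to an intermediate count; habitat-specific families to every genome of
#' their habitat. Accessory families with occupancy >= 2 are constrained to
#' span at least two habitats (when possible) so the habitat-specificity
#' ground truth is unambiguous.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `families` (data.frame: family_id, class, habitat,
#'   length_bp, occupancy), `sequences` (named ancestral sequences),
#'   `members` (named list: family -> genome ids), `spacer_lengths`
#'   (per-family ancestral spacer lengths) and `base_gc`.
#' @export
build_gene_pool <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  pool <- config$pool
  ids <- genome_ids_of(config)
  n <- length(ids)
  if (n < 1L) stop("configuration has no genomes")
  if (pool$n_soft_core > 0L) soft_core_occupancy(n)  # fail early

  habitats <- unique(vapply(config$groups, `[[`, "", "habitat"))
  hab_of <- unlist(unname(lapply(config$groups, function(g) {
    setNames(rep(g$habitat, g$n_genomes),
             sprintf("%s_%02d", g$name, seq_len(g$n_genomes)))
  })))

  fam <- data.frame(
    family_id = character(0), class = character(0), habitat = character(0),
    stringsAsFactors = FALSE)
  add <- function(fam, k, class, habitat = "none") {
    if (k == 0L) return(fam)
    rbind(fam, data.frame(
      family_id = sprintf("fam_%s_%s%03d", class,
                          if (habitat == "none") "" else paste0(habitat, "_"),
                          seq_len(k)),
      class = class, habitat = habitat, stringsAsFactors = FALSE))
  }
  fam <- add(fam, pool$n_strict_core, "strict_core")
  fam <- add(fam, pool$n_soft_core, "soft_core")
  fam <- add(fam, pool$n_shell, "shell")
  fam <- add(fam, pool$n_cloud, "cloud")
  for (h in habitats) fam <- add(fam, pool$n_habitat_specific, "habitat", h)
  if (nrow(fam) == 0L) stop("gene pool is empty: all family counts are 0")

  base_gc <- mean(vapply(config$groups, `[[`, 0, "gc_target"))

  fam$length_bp <- with_substream(seed, "pool_lengths", {
    len <- round(rnorm(nrow(fam), pool$mean_gene_bp,
                       0.10 * pool$mean_gene_bp) / 3) * 3
    as.integer(pmax(90L, len))
  })

  sequences <- setNames(vector("character", nrow(fam)), fam$family_id)
  for (i in seq_len(nrow(fam))) {
    sequences[i] <- with_substream(seed, c("pool_seq", fam$family_id[i]), {
      paste(make_stop_free(random_bases(fam$length_bp[i], base_gc)),
            collapse = "")
    })
  }

  # Occupancy assignment. Shell occupancies are drawn between 3 and the last
  # count below the soft-core cut; multi-genome accessory families get seeded
  # into two habitats first so no non-specific family can look specific.
  members <- with_substream(seed, "occupancy", {
    out <- vector("list", nrow(fam))
    names(out) <- fam$family_id
    soft_k <- if (pool$n_soft_core > 0L) soft_core_occupancy(n) else NA_integer_
    shell_max <- min(as.integer(ceiling(0.95 * n)) - 1L, n - 1L)
    pick_spanning <- function(k) {
      if (k >= 2L && length(habitats) >= 2L) {
        h2 <- sample(habitats, 2L)
        first <- c(sample(ids[hab_of == h2[1]], 1L),
                   sample(ids[hab_of == h2[2]], 1L))
        rest <- setdiff(ids, first)
        sort(c(first, if (k > 2L) sample(rest, k - 2L)))
      } else {
        sort(sample(ids, k))
      }
    }
    for (i in seq_len(nrow(fam))) {
      out[[i]] <- switch(
        fam$class[i],
        strict_core = ids,
        soft_core = pick_spanning(soft_k),
        shell = {
          if (shell_max < 3L) {
            stop("shell infeasible with ", n, " genomes: no occupancy in [3, ",
                 shell_max, "]")
          }
          pick_spanning(sample(3:shell_max, 1L))
        },
        cloud = pick_spanning(sample(seq_len(min(2L, n)), 1L)),
        habitat = ids[hab_of == fam$habitat[i]]
      )
    }
    out
  })
  fam$occupancy <- lengths(members)

  spacer_lengths <- with_substream(seed, "spacers", {
    if (pool$spacer_bp <= 0) {
      setNames(integer(nrow(fam)), fam$family_id)
    } else {
      setNames(rgeom(nrow(fam), prob = 1 / (pool$spacer_bp + 1)),
               fam$family_id)
    }
  })

  list(families = fam, sequences = sequences, members = members,
       spacer_lengths = spacer_lengths, base_gc = base_gc)
}

# Category implied by an occupancy count under the partition rules; used to
# label ground truth consistently with partition_pangenome().
occupancy_category <- function(occupancy, n_genomes) {
  ifelse(occupancy == n_genomes, "strict_core",
         ifelse(occupancy / n_genomes >= 0.95, "soft_core",
                ifelse(occupancy <= 2, "cloud", "shell")))
}

# ---- collection synthesis --------------------------------------------------

translate_genes <- function(gene_seqs) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(gene_seqs), no.init.codon = TRUE))
  chartr("*", "X", aa)
}

apply_acidity_shift <- function(protein, delta) {
  if (delta == 0) return(protein)
  x <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (delta > 0) {
    from <- c("K", "R"); to <- c("D", "E")
  } else {
    from <- c("D", "E"); to <- c("K", "R")
  }
  pos <- which(x %in% from)
  pos <- pos[runif(length(pos)) < abs(delta)]
  if (length(pos)) x[pos] <- sample(to, length(pos), replace = TRUE)
  paste(x, collapse = "")
}

#' Synthesize a habitat-structured genome collection with ground truth
#'
#' Builds the ancestral gene pool, evolves a group ancestor per group
#' (deep divergence, group GC target), then evolves each genome from its
#' group ancestor (within-group divergence). Each genome is one contig:
#' alternating ancestral spacers and evolved genes in canonical family
#' order, padded with non-coding filler to its drawn target size. Group
#' non-coding sequence is generated at a compensated GC so realized
#' whole-genome GC matches the group's `gc_target`. Proteomes are the
#' standard-code translations with the group's acidity shift applied;
#' substitution-created internal stop codons are recorded as `X`.
#'
#' @param config A [synthetic_config()].
#' @return List with `assemblies`, `features`, `proteomes` (each a named
#'   list), `metadata` ([strain_metadata()]) and `truth` (ground truth:
#'   family categories and memberships, habitat labels, expected pairwise
#'   ANI, genome-to-group map).
#' @export
synthesize_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n0 <- vapply(config$groups, `[[`, 0L, "n_genomes")
  if (any(n0 == 0L)) {
    stop("group '", names(which(n0 == 0L))[1], "' has n_genomes = 0")
  }
  seed <- config$seed
  pool <- build_gene_pool(config)
  fam <- pool$families
  ids <- genome_ids_of(config)
  n <- length(ids)
  group_of <- genome_group_of(config)

  # carried families per genome, canonical (pool) order
  carried <- lapply(setNames(ids, ids), function(gid) {
    fam$family_id[vapply(pool$members[fam$family_id],
                         function(m) gid %in% m, TRUE)]
  })

  # per-genome target sizes, drawn in their own substream
  target_bp <- vapply(ids, function(gid) {
    g <- config$groups[[group_of[gid]]]
    with_substream(seed, c("size", gid),
                   max(0, round(rnorm(1, g$genome_kb[1], g$genome_kb[2]) * 1000)))
  }, 0)

  gene_len <- setNames(fam$length_bp, fam$family_id)
  spacer_len <- pool$spacer_lengths

  assemblies <- list(); features <- list(); proteomes <- list()

  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    gids <- ids[group_of == gname]

    group_genes <- with_substream(seed, c("group_genes", gname), {
      vapply(pool$sequences, evolve_family, "",
             p = g$divergence_from_pool, gc_target = g$gc_target)
    })

    coding_bp <- vapply(gids, function(gid) sum(gene_len[carried[[gid]]]), 0)
    spacer_bp <- vapply(gids, function(gid) sum(spacer_len[carried[[gid]]]), 0)
    filler_bp <- pmax(target_bp[gids] - coding_bp - spacer_bp, 0)
    noncoding_bp <- spacer_bp + filler_bp

    # GC of group non-coding sequence chosen so whole-genome GC ~ gc_target
    gc_genes <- {
      counts <- Biostrings::letterFrequency(
        Biostrings::DNAStringSet(group_genes), c("G", "C"))
      w <- vapply(names(group_genes),
                  function(f) sum(vapply(gids, function(gid)
                    f %in% carried[[gid]], TRUE)), 0)
      sum(rowSums(counts) * w) / sum(nchar(group_genes) * w)
    }
    mean_nc <- mean(noncoding_bp)
    gc_nc <- if (mean_nc > 0) {
      (g$gc_target * mean(coding_bp + noncoding_bp) -
         gc_genes * mean(coding_bp)) / mean_nc
    } else g$gc_target
    gc_nc <- min(max(gc_nc, 0.02), 0.98)

    group_spacers <- with_substream(seed, c("group_spacers", gname), {
      setNames(vapply(spacer_len, function(L) {
        if (L == 0L) "" else paste(random_bases(L, gc_nc), collapse = "")
      }, ""), names(spacer_len))
    })
    max_filler <- max(0, max(filler_bp))
    group_filler <- with_substream(seed, c("group_filler", gname), {
      if (max_filler == 0) "" else paste(random_bases(max_filler, gc_nc),
                                         collapse = "")
    })

    for (gid in gids) {
      res <- with_substream(seed, c("genome", gid), {
        fams <- carried[[gid]]
        genes <- vapply(group_genes[fams], evolve_family, "",
                        p = g$divergence, gc_target = g$gc_target)
        spacers <- vapply(group_spacers[fams], function(s) {
          if (nchar(s) == 0L) "" else
            evolve_family(s, g$divergence, g$gc_target)
        }, "")
        filler <- if (filler_bp[gid] > 0) {
          evolve_family(substr(group_filler, 1L, filler_bp[gid]),
                        g$divergence, g$gc_target)
        } else ""

        parts <- character(2L * length(fams) + 1L)
        starts <- integer(length(fams)); ends <- integer(length(fams))
        at <- 0L
        for (k in seq_along(fams)) {
          parts[2L * k - 1L] <- spacers[k]
          at <- at + nchar(spacers[k])
          parts[2L * k] <- genes[k]
          starts[k] <- at + 1L
          at <- at + nchar(genes[k])
          ends[k] <- at
        }
        parts[2L * length(fams) + 1L] <- filler
        contig <- paste(parts, collapse = "")

        prot <- translate_genes(genes)
        prot <- vapply(prot, apply_acidity_shift, "", delta = g$acidity_shift)
        names(prot) <- fams
        list(contig = contig, starts = starts, ends = ends,
             fams = fams, prot = prot)
      })
      contig_id <- paste0(gid, "_c1")
      assemblies[[gid]] <- genome_assembly(gid,
                                           setNames(res$contig, contig_id))
      features[[gid]] <- feature_table(
        gid,
        data.frame(contig_id = contig_id, start = res$starts,
                   end = res$ends, strand = "+", feature_id = res$fams,
                   stringsAsFactors = FALSE),
        assembly = assemblies[[gid]])
      proteomes[[gid]] <- proteome(gid, res$prot)
    }
  }

  metadata <- strain_metadata(data.frame(
    genome_id = ids,
    habitat = vapply(ids, function(i) config$groups[[group_of[i]]]$habitat, ""),
    subcluster = vapply(ids, function(i)
      config$groups[[group_of[i]]]$subcluster, ""),
    stringsAsFactors = FALSE))

  expected_ani <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      expected_ani[i, j] <- expected_pair_identity(
        config$groups[[group_of[ids[i]]]], config$groups[[group_of[ids[j]]]],
        pool$base_gc)
    }
  }

  truth <- list(
    family_category = setNames(occupancy_category(fam$occupancy, n),
                               fam$family_id),
    family_habitat = setNames(fam$habitat, fam$family_id),
    family_members = pool$members,
    expected_ani = expected_ani,
    genome_group = group_of,
    base_gc = pool$base_gc
  )

  list(assemblies = assemblies, features = features, proteomes = proteomes,
       metadata = metadata, truth = truth)
}

#' Write a synthetic collection to disk
#'
#' Emits one nucleotide FASTA, one GFF3 and one protein FASTA per genome,
#' plus `metadata.tsv` and `truth.json`.
#'
#' @param collection Output of [synthesize_collection()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(collection$assemblies)) {
    write_fasta(collection$assemblies[[gid]],
                file.path(dir, paste0(gid, ".fna")))
    write_feature_table(collection$features[[gid]],
                        file.path(dir, paste0(gid, ".gff")))
    write_fasta(collection$proteomes[[gid]],
                file.path(dir, paste0(gid, ".faa")))
  }
  write_metadata(collection$metadata, file.path(dir, "metadata.tsv"))
  truth <- collection$truth
  truth$expected_ani <- as.data.frame(truth$expected_ani)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
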