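#' Cluster proteins into gene families by reciprocal homology
#'
#' All-vs-all protein comparison across (and within) proteomes; directed
#' hits passing the identity and query-coverage thresholds become undirected
#' edges when reciprocal (coverage holds in both directions), and families
#' are the connected components of that graph. Singleton proteins form
#' singleton families. Components are order-free, so the clustering is
#' deterministic under any input ordering.
#'
#' @param proteomes Named list of [proteome()] objects (>= 2).
#' @param min_identity Percent identity threshold (default 30, the
#'   conventional homology cut-off).
#' @param min_coverage Percent query coverage, strict (default 50, i.e.
#'   > 50% of the query must align).
#' @param min_shared_kmers 4-mer prefilter for candidate pairs (0 disables).
#' @param min_score Minimum raw BLOSUM62 alignment score, the analogue of a
#'   search tool's E-value cut-off (default 60).
#' @return List of class `gene_family_clusters` with `members` (named list:
#'   family_id -> data.frame(genome_id, protein_id)) and `assignment`
#'   (data.frame: genome_id, protein_id, family_id).
#' @export
cluster_proteins <- function(proteomes, min_identity = 30, min_coverage = 50,
                             min_shared_kmers = 2L, min_score = 60) {
  stopifnot(length(proteomes) >= 2L)
  gids <- vapply(proteomes, `[[`, "", "genome_id")
  all_seqs <- unlist(lapply(proteomes, `[[`, "proteins"), use.names = FALSE)
  node_genome <- rep(gids, vapply(proteomes, function(p)
    length(p$proteins), 0L))
  node_protein <- unlist(lapply(proteomes, function(p) names(p$proteins)),
                         use.names = FALSE)
  node_id <- paste(node_genome, node_protein, sep = "\r")
  names(all_seqs) <- node_id

  km <- protein_kmers(all_seqs)
  pairs <- candidate_pairs(km, km, min_shared_kmers)
  pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]  # unordered, no self
  hits <- align_protein_pairs(pairs, all_seqs, all_seqs)
  edges <- hits[hits$identity >= min_identity &
                  hits$score >= min_score &
                  hits$cov_a > min_coverage &
                  hits$cov_b > min_coverage, c("a", "b"), drop = FALSE]

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = node_id, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  membership <- comp$membership[node_id]
  first <- order(vapply(seq_len(comp$no),
                        function(cc) min(which(membership == cc)), 0L))
  membership <- match(membership, first)
  fam_id <- sprintf("fam%05d", membership)

  assignment <- data.frame(genome_id = node_genome,
                           protein_id = node_protein,
                           family_id = fam_id, stringsAsFactors = FALSE)
  members <- lapply(split(assignment[c("genome_id", "protein_id")],
                          assignment$family_id), function(d) {
    rownames(d) <- NULL
    d
  })
  structure(list(members = members, assignment = assignment,
                 genomes = unname(gids)),
            class = "gene_family_clusters")
}

#' Presence/absence matrix from gene-family clusters
#'
#' Occupancy counts genomes, not genes: paralogs within a genome collapse
#' to a single presence.
#'
#' @param clusters A [cluster_proteins()] result.
#' @return A [pa_matrix()] (families x genomes).
#' @export
pa_from_clusters <- function(clusters) {
  fams <- names(clusters$members)
  genomes <- clusters$genomes
  m <- matrix(0L, length(fams), length(genomes),
              dimnames = list(fams, genomes))
  for (f in fams) {
    m[f, unique(clusters$members[[f]]$genome_id)] <- 1L
  }
  pa_matrix(m)
}

#' Presence/absence matrix from synthetic ground truth
#'
#' @param truth `truth` element of [synthesize_collection()] output.
#' @return A [pa_matrix()].
#' @export
pa_from_truth <- function(truth) {
  fams <- names(truth$family_members)
  genomes <- names(truth$genome_group)
  m <- matrix(0L, length(fams), length(genomes),
              dimnames = list(fams, genomes))
  for (f in fams) m[f, truth$family_members[[f]]] <- 1L
  pa_matrix(m)
}

#' Partition a pangenome into strict core, soft core, shell and cloud
#'
#' Categories are evaluated in order and are mutually exclusive: a family
#' present in all genomes is strict core; otherwise present in >= 95% of
#' genomes is soft core; otherwise present in at most 2 genomes is cloud;
#' everything else is shell. The strict > soft > cloud > shell precedence
#' resolves small-n conflicts (occupancy 2 of 3 is cloud, not shell).
#'
#' @param pa A [pa_matrix()] with >= 3 genomes.
#' @param soft_core_fraction Soft-core occupancy fraction (default 0.95).
#' @param cloud_max Cloud occupancy ceiling (default 2 genomes).
#' @return List of class `pangenome_partition` with `category` (named by
#'   family), `totals` and `percent` per category, `n_genomes`.
#' @export
partition_pangenome <- function(pa, soft_core_fraction = 0.95,
                                cloud_max = 2L) {
  if (nrow(pa) == 0L) stop("empty presence/absence matrix")
  n <- ncol(pa)
  if (n < 3L) stop("pangenome partition needs >= 3 genomes")
  occ <- attr(pa, "occupancy")
  category <- ifelse(occ == n, "strict_core",
                     ifelse(occ / n >= soft_core_fraction, "soft_core",
                            ifelse(occ <= cloud_max, "cloud", "shell")))
  lv <- c("strict_core", "soft_core", "shell", "cloud")
  totals <- table(factor(category, levels = lv))
  structure(list(category = setNames(category, rownames(pa)),
                 totals = setNames(as.integer(totals), lv),
                 percent = setNames(100 * as.numeric(totals) / nrow(pa), lv),
                 n_genomes = n),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat("<pangenome_partition> ", sum(x$totals), " families over ",
      x$n_genomes, " genomes:\n", sep = "")
  for (k in names(x$totals)) {
    cat(sprintf("  %-11s %5d (%.1f%%)\n", k, x$totals[[k]], x$percent[[k]]))
  }
  invisible(x)
}

#' Core and pangenome rarefaction curves
#'
#' For each of `R` random genome orderings, the running intersection (core)
#' and union (pangenome) of gene-family sets as genomes are added one at a
#' time.
#'
#' @param pa A [pa_matrix()].
#' @param R Number of permutations (default 100).
#' @param seed Integer seed.
#' @return List of class `rarefaction_curves` with `core` and `pan`
#'   (R x n_genomes integer matrices) and a `summary` data.frame
#'   (g, mean_core, sd_core, mean_pan, sd_pan).
#' @export
rarefaction_curves <- function(pa, R = 100L, seed = 1L) {
  stopifnot(R >= 1L)
  n <- ncol(pa)
  m <- unclass(pa)
  core <- matrix(0L, R, n)
  pan <- matrix(0L, R, n)
  with_substream(seed, "rarefaction", {
    for (r in seq_len(R)) {
      ord <- sample.int(n)
      inter <- m[, ord[1]] == 1L
      uni <- inter
      core[r, 1] <- sum(inter); pan[r, 1] <- sum(uni)
      if (n > 1L) for (g in 2:n) {
        inter <- inter & (m[, ord[g]] == 1L)
        uni <- uni | (m[, ord[g]] == 1L)
        core[r, g] <- sum(inter); pan[r, g] <- sum(uni)
      }
    }
  })
  summary <- data.frame(
    g = seq_len(n),
    mean_core = colMeans(core),
    sd_core = apply(core, 2, sd),
    mean_pan = colMeans(pan),
    sd_pan = apply(pan, 2, sd))
  structure(list(core = core, pan = pan, summary = summary, R = R,
                 seed = seed),
            class = "rarefaction_curves")
}

#' Per-habitat and per-sub-cluster gene-family occupancy profiles
#'
#' Counts, per family, the genomes carrying it in each habitat and each
#' sub-cluster. A family is flagged habitat-specific when it is present in
#' at least `min_fraction` of one habitat's genomes and in none of the
#' other habitats' (requires >= 2 habitats in the metadata).
#'
#' @param pa A [pa_matrix()].
#' @param metadata A [strain_metadata()] covering every genome.
#' @param min_fraction Presence fraction required in the focal habitat
#'   (default 0.5).
#' @return List of class `habitat_profile` with `habitat_counts`,
#'   `habitat_sizes`, `subcluster_counts`, `subcluster_sizes` and
#'   `specific` (named character: habitat name or `NA`).
#' @export
habitat_gene_profile <- function(pa, metadata, min_fraction = 0.5) {
  miss <- setdiff(colnames(pa), metadata$genome_id)
  if (length(miss)) stop("genome missing from metadata: ", miss[1])
  md <- metadata[match(colnames(pa), metadata$genome_id), ]
  count_by <- function(groups) {
    g <- factor(groups)
    counts <- sapply(levels(g), function(lv)
      rowSums(unclass(pa)[, g == lv, drop = FALSE]))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(pa),
                                               dimnames = list(rownames(pa),
                                                               levels(g)))
    counts
  }
  hab_counts <- count_by(md$habitat)
  hab_sizes <- table(md$habitat)[colnames(hab_counts)]
  sc_counts <- count_by(md$subcluster)
  sc_sizes <- table(md$subcluster)[colnames(sc_counts)]

  specific <- rep(NA_character_, nrow(pa))
  names(specific) <- rownames(pa)
  if (ncol(hab_counts) >= 2L) {
    frac <- sweep(hab_counts, 2, as.numeric(hab_sizes), "/")
    for (h in colnames(hab_counts)) {
      others <- setdiff(colnames(hab_counts), h)
      hit <- frac[, h] >= min_fraction &
        rowSums(hab_counts[, others, drop = FALSE]) == 0L
      specific[hit] <- h
    }
  }
  structure(list(habitat_counts = hab_counts,
                 habitat_sizes = setNames(as.integer(hab_sizes),
                                          names(hab_sizes)),
                 subcluster_counts = sc_counts,
                 subcluster_sizes = setNames(as.integer(sc_sizes),
                                             names(sc_sizes)),
                 specific = specific, min_fraction = min_fraction),
            class = "habitat_profile")
}
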