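#' Cut an assembly into consecutive non-overlapping fragments
#'
#' Windows of `fragment_bp` are taken per contig; the terminal remainder
#' shorter than `fragment_bp` is discarded, and contigs shorter than one
#' fragment contribute nothing.
#'
#' @param assembly A [genome_assembly()].
#' @param fragment_bp Fragment length (>= 100); 1020 bp follows the
#'   fragment-ANI convention.
#' @return Character vector of fragment sequences.
#' @export
fragment_genome <- function(assembly, fragment_bp = 1020L) {
  stopifnot(fragment_bp >= 100L)
  frags <- unlist(lapply(assembly$contigs, function(s) {
    n_full <- nchar(s) %/% fragment_bp
    if (n_full == 0L) return(character(0))
    starts <- (seq_len(n_full) - 1L) * fragment_bp + 1L
    substring(s, starts, starts + fragment_bp - 1L)
  }), use.names = FALSE)
  short <- sum(nchar(assembly$contigs) < fragment_bp)
  if (short > 0L) {
    message(short, " contig(s) shorter than ", fragment_bp,
            " bp contribute no fragments in '", assembly$genome_id, "'")
  }
  frags
}

# k-mer start positions table of a sequence: data.table(kmer, pos).
# High-copy k-mers (simple repeats) are dropped to keep seeding unambiguous.
kmer_table <- function(seq, k, max_copies = 10L) {
  n <- nchar(seq)
  if (n < k) {
    return(data.table::data.table(kmer = character(0), pos = integer(0)))
  }
  pos <- seq_len(n - k + 1L)
  dt <- data.table::data.table(kmer = substring(seq, pos, pos + k - 1L),
                               pos = pos)
  dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
  counts <- dt[, .N, by = "kmer"]
  dt[dt$kmer %in% counts$kmer[counts$N <= max_copies]]
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Maximum-scoring contiguous segment of a match/mismatch vector under
# +1/-2 scoring (cumsum/cummin form of the maximum-subarray recursion).
best_local_segment <- function(matches) {
  s <- ifelse(matches, 1, -2)
  pre <- c(0, cumsum(s))
  L <- length(s)
  m <- cummin(pre[seq_len(L)])
  gain <- pre[-1] - m
  j <- which.max(gain)
  if (gain[j] <= 0) return(list(len = 0L, identity = 0))
  i <- which(pre[seq_len(j)] == m[j])[1]  # segment is (i, j] of s
  len <- j - i + 1L
  list(len = len, identity = sum(matches[i:j]) / len)
}

# Directed fragment-ANI of query fragments against a reference sequence.
# Seeds shared k-mers (both strands), votes for the dominant diagonal
# offset per fragment, then scores a gap-free comparison at that offset.
directed_ani <- function(fragments, ref_seq, k = 15L, min_identity = 30,
                         min_coverage = 70) {
  nf <- length(fragments)
  if (nf == 0L || nchar(ref_seq) < k) {
    return(list(identities = numeric(0), n_total = nf, n_retained = 0L))
  }
  refs <- list(fwd = kmer_table(ref_seq, k), rev = kmer_table(revcomp(ref_seq), k))
  flen <- nchar(fragments)

  qdt <- data.table::rbindlist(lapply(seq_len(nf), function(i) {
    t <- kmer_table(fragments[i], k)
    if (nrow(t)) t$frag <- i
    t
  }), fill = TRUE)

  best <- vector("list", 2L)
  for (s in 1:2) {
    rt <- refs[[s]]
    if (nrow(rt) == 0L || nrow(qdt) == 0L) next
    hits <- merge(qdt, rt, by = "kmer", allow.cartesian = TRUE,
                  suffixes = c("_q", "_r"))
    if (nrow(hits) == 0L) next
    hits$offset <- hits$pos_r - hits$pos_q + 1L
    votes <- hits[, .N, by = c("frag", "offset")]
    data.table::setorderv(votes, c("frag", "N", "offset"), c(1L, -1L, 1L))
    top <- votes[!duplicated(votes$frag)]
    top$strand <- s
    best[[s]] <- top
  }
  best <- data.table::rbindlist(best[!vapply(best, is.null, TRUE)])
  if (is.null(best) || nrow(best) == 0L) {
    return(list(identities = numeric(0), n_total = nf, n_retained = 0L))
  }
  data.table::setorderv(best, c("frag", "N", "strand"), c(1L, -1L, 1L))
  best <- best[!duplicated(best$frag)]

  ref_strands <- c(ref_seq, revcomp(ref_seq))
  rlen <- nchar(ref_seq)
  identities <- numeric(0)
  for (r in seq_len(nrow(best))) {
    i <- best$frag[r]
    off <- best$offset[r]
    L <- flen[i]
    rs <- max(1L, off)
    re <- min(rlen, off + L - 1L)
    if (re < rs) next
    qs <- rs - off + 1L
    qe <- re - off + 1L
    qchars <- strsplit(substr(fragments[i], qs, qe), "", fixed = TRUE)[[1]]
    rchars <- strsplit(substr(ref_strands[best$strand[r]], rs, re), "",
                       fixed = TRUE)[[1]]
    # local trimming: score the best contiguous segment (+1 match,
    # -2 mismatch), emulating the local alignment a search tool would
    # report; a fragment straddling a homology boundary is scored on its
    # alignable part only
    seg <- best_local_segment(qchars == rchars)
    if (seg$len == 0L) next
    aligned_frac <- seg$len / L
    ident <- 100 * seg$identity
    if (ident >= min_identity && 100 * aligned_frac >= min_coverage) {
      identities <- c(identities, ident)
    }
  }
  list(identities = identities, n_total = nf,
       n_retained = length(identities))
}

#' Pairwise fragment-based average nucleotide identity
#'
#' The query is cut into `fragment_bp` windows; each fragment is placed on
#' the reference by shared-k-mer seeding (k = 15, both strands) followed by
#' gap-free scoring at the winning diagonal. Fragments whose best placement
#' reaches at least `min_identity` percent identity over at least
#' `min_coverage` percent of the fragment are retained; the directed ANI is
#' their mean identity, and the reported ANI is the mean of the two directed
#' values (explicit symmetrization).
#'
#' @param query,reference [genome_assembly()] objects.
#' @param fragment_bp Fragment length (default 1020).
#' @param min_identity Retention threshold on percent identity (default 30).
#' @param min_coverage Retention threshold on percent of fragment aligned
#'   (default 70).
#' @param k Seed k-mer length (default 15).
#' @return List of class `ani_result` with `query_id`, `ref_id`, `ani`
#'   (`NA` when no fragment is retained in either direction),
#'   `n_fragments_total`, `n_fragments_retained`.
#' @export
pairwise_ani <- function(query, reference, fragment_bp = 1020L,
                         min_identity = 30, min_coverage = 70, k = 15L) {
  ref_seq <- paste(reference$contigs, collapse = paste(rep("N", k), collapse = ""))
  qry_seq <- paste(query$contigs, collapse = paste(rep("N", k), collapse = ""))
  d1 <- directed_ani(suppressMessages(fragment_genome(query, fragment_bp)),
                     ref_seq, k, min_identity, min_coverage)
  d2 <- directed_ani(suppressMessages(fragment_genome(reference, fragment_bp)),
                     qry_seq, k, min_identity, min_coverage)
  directed <- c(if (d1$n_retained > 0L) mean(d1$identities),
                if (d2$n_retained > 0L) mean(d2$identities))
  ani <- if (length(directed)) mean(directed) else NA_real_
  structure(list(query_id = query$genome_id, ref_id = reference$genome_id,
                 ani = ani,
                 n_fragments_total = d1$n_total + d2$n_total,
                 n_fragments_retained = d1$n_retained + d2$n_retained),
            class = "ani_result")
}

#' All-pairs ANI matrix
#'
#' @param assemblies Named list of [genome_assembly()] objects (>= 2).
#' @param ... Passed to [pairwise_ani()].
#' @return Symmetric numeric matrix with diagonal 100; pairs with no
#'   retained fragments are `NA` (missing, not 0).
#' @export
ani_matrix <- function(assemblies, ...) {
  stopifnot(length(assemblies) >= 2L)
  ids <- vapply(assemblies, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- pairwise_ani(assemblies[[i]], assemblies[[j]], ...)
      m[i, j] <- r$ani
      m[j, i] <- r$ani
    }
  }
  m
}

#' Threshold clustering of genomes into species or clades
#'
#' Builds a graph with an edge for every pair above the ANI threshold
#' (strictly > 95 for species, >= 90 for clades, following the respective
#' conventions) and returns its connected components (single linkage, the
#' weakest assumption). Missing pairs contribute no edge.
#'
#' @param ani Symmetric ANI matrix (percent scale, `NA` = missing pair).
#' @param level `"species"` or `"clade"`.
#' @param threshold Override the level's default threshold.
#' @return List of class `species_cluster_set` with `level`, `threshold`,
#'   `clusters` (list of genome-id vectors, a disjoint cover) and
#'   `membership` (named integer vector).
#' @export
cluster_by_ani_threshold <- function(ani, level = c("species", "clade"),
                                     threshold = NULL) {
  level <- match.arg(level)
  stopifnot(is.matrix(ani), !is.null(rownames(ani)),
            !anyDuplicated(rownames(ani)))
  if (is.null(threshold)) threshold <- if (level == "species") 95 else 90
  pass <- if (level == "species") {
    !is.na(ani) & ani > threshold
  } else {
    !is.na(ani) & ani >= threshold
  }
  diag(pass) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(pass, mode = "max")
  comp <- igraph::components(g)
  membership <- comp$membership
  # canonical numbering by first label occurrence
  first <- order(vapply(seq_len(comp$no),
                        function(cc) min(which(membership == cc)), 0L))
  renum <- match(seq_len(comp$no), first)
  membership <- setNames(renum[membership], rownames(ani))
  clusters <- split(names(membership), membership)
  names(clusters) <- NULL
  structure(list(level = level, threshold = threshold,
                 clusters = clusters, membership = membership),
            class = "species_cluster_set")
}

#' @export
print.species_cluster_set <- function(x, ...) {
  cat("<species_cluster_set> level=", x$level, " threshold=", x$threshold,
      ": ", length(x$clusters), " cluster(s)\n", sep = "")
  invisible(x)
}
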