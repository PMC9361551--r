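# ---- protein-protein comparison shared by AAI and family clustering --------

# Distinct k-mer set per protein (k = 4 prefilter).
protein_kmers <- function(seqs, k = 4L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
}

# Candidate unordered pairs across two id-disjoint protein sets, by shared
# distinct k-mer count. min_shared = 0 disables the prefilter.
candidate_pairs <- function(kmA, kmB, min_shared = 2L) {
  if (min_shared <= 0L) {
    return(expand.grid(a = names(kmA), b = names(kmB),
                       stringsAsFactors = FALSE))
  }
  dtA <- data.table::data.table(
    kmer = unlist(kmA, use.names = FALSE),
    a = rep(names(kmA), lengths(kmA)))
  dtB <- data.table::data.table(
    kmer = unlist(kmB, use.names = FALSE),
    b = rep(names(kmB), lengths(kmB)))
  if (nrow(dtA) == 0L || nrow(dtB) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  hits <- merge(dtA, dtB, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  counts <- hits[, .N, by = c("a", "b")]
  as.data.frame(counts[counts$N >= min_shared, c("a", "b")])
}

# Ends-free global alignment of protein pairs; returns per-pair score,
# percent identity (matches / alignment columns excluding terminal gaps) and
# the two directed coverages (aligned residues / sequence length).
align_protein_pairs <- function(pairs, seqsA, seqsB) {
  if (nrow(pairs) == 0L) {
    return(data.frame(a = character(0), b = character(0), score = numeric(0),
                      identity = numeric(0), cov_a = numeric(0),
                      cov_b = numeric(0)))
  }
  out <- vector("list", 0L)
  for (b in unique(pairs$b)) {
    qa <- pairs$a[pairs$b == b]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqsA[qa]), Biostrings::AAString(seqsB[[b]]),
      type = "overlap", substitutionMatrix = "BLOSUM62",
      gapOpening = 12, gapExtension = 1)
    pat <- as.character(Biostrings::alignedPattern(aln))
    width <- nchar(pat)
    pat_res <- width - vapply(gregexpr("-", pat, fixed = TRUE),
                              function(g) sum(g > 0L), 0L)
    sub <- as.character(Biostrings::alignedSubject(aln))
    sub_res <- nchar(sub) - vapply(gregexpr("-", sub, fixed = TRUE),
                                   function(g) sum(g > 0L), 0L)
    out[[length(out) + 1L]] <- data.frame(
      a = qa, b = b,
      score = Biostrings::score(aln),
      identity = ifelse(width > 0L,
                        100 * Biostrings::nmatch(aln) / width, 0),
      cov_a = 100 * pat_res / nchar(seqsA[qa]),
      cov_b = 100 * sub_res / nchar(seqsB[[b]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pairwise average amino acid identity (AAI)
#'
#' All-vs-all protein comparison between two proteomes (4-mer prefilter,
#' then ends-free global alignment with BLOSUM62 scoring). Directed best
#' hits must reach `min_identity` percent identity and `min_coverage`
#' percent query coverage; bidirectional best-hit (BBH) pairs are retained
#' and AAI is their mean percent identity.
#'
#' @param proteome_a,proteome_b [proteome()] objects.
#' @param min_identity Percent identity threshold (default 30).
#' @param min_coverage Percent query coverage threshold (default 50).
#' @param min_shared_kmers Prefilter: candidate pairs must share at least
#'   this many distinct 4-mers (0 disables).
#' @param min_score Minimum raw BLOSUM62 alignment score; plays the role of
#'   the E-value cut-off of a database search, excluding chance ends-free
#'   alignments between unrelated short proteins (default 60).
#' @return List of class `aai_result` with `id_a`, `id_b`, `aai` (`NA` when
#'   no BBH pair exists) and `n_bbh_pairs`.
#' @export
pairwise_aai <- function(proteome_a, proteome_b, min_identity = 30,
                         min_coverage = 50, min_shared_kmers = 2L,
                         min_score = 60) {
  stopifnot(inherits(proteome_a, "proteome"), inherits(proteome_b, "proteome"))
  sa <- proteome_a$proteins
  sb <- proteome_b$proteins
  pairs <- candidate_pairs(protein_kmers(sa), protein_kmers(sb),
                           min_shared_kmers)
  hits <- align_protein_pairs(pairs, sa, sb)
  hits <- hits[hits$identity >= min_identity & hits$score >= min_score, ,
               drop = FALSE]

  best_of <- function(h, by, cov) {
    h <- h[h[[cov]] >= min_coverage, , drop = FALSE]
    if (nrow(h) == 0L) return(h)
    other <- setdiff(c("a", "b"), by)
    h <- h[order(h[[by]], -h$score, h[[other]]), , drop = FALSE]
    h[!duplicated(h[[by]]), , drop = FALSE]
  }
  fwd <- best_of(hits, "a", "cov_a")   # each A protein's best B hit
  rev <- best_of(hits, "b", "cov_b")   # each B protein's best A hit
  key_f <- paste(fwd$a, fwd$b); key_r <- paste(rev$a, rev$b)
  bbh <- fwd[key_f %in% key_r, , drop = FALSE]
  aai <- if (nrow(bbh)) mean(bbh$identity) else NA_real_
  structure(list(id_a = proteome_a$genome_id, id_b = proteome_b$genome_id,
                 aai = aai, n_bbh_pairs = nrow(bbh)),
            class = "aai_result")
}

#' All-pairs AAI matrix
#'
#' @param proteomes Named list of [proteome()] objects (>= 2).
#' @param ... Passed to [pairwise_aai()].
#' @return Symmetric numeric matrix, diagonal 100, `NA` for undefined pairs.
#' @export
aai_matrix <- function(proteomes, ...) {
  stopifnot(length(proteomes) >= 2L)
  ids <- vapply(proteomes, `[[`, "", "genome_id")
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- pairwise_aai(proteomes[[i]], proteomes[[j]], ...)
      m[i, j] <- m[j, i] <- r$aai
    }
  }
  m
}
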