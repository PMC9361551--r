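#' Element-wise square-root transform
#'
#' Applied to relative-frequency tables before Bray-Curtis resemblance
#' (transform first, then resemblance).
#'
#' @param x Numeric matrix or data.frame with non-negative entries.
#' @return Matrix of element-wise square roots.
#' @export
sqrt_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative entry: square-root transform undefined")
  sqrt(x)
}

#' Bray-Curtis dissimilarity matrix (0-100 scale)
#'
#' `d(x, y) = 100 * sum(|x - y|) / sum(x + y)` on non-negative rows.
#'
#' @param rows Numeric matrix, one sample per row, with rownames.
#' @return Symmetric matrix of class `dissimilarity_matrix`, zero diagonal.
#' @export
bray_curtis <- function(rows) {
  rows <- as.matrix(rows)
  if (any(rows < 0)) stop("Bray-Curtis requires non-negative entries")
  n <- nrow(rows)
  labels <- rownames(rows)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      tot <- sum(rows[i, ] + rows[j, ])
      if (tot == 0) {
        stop("Bray-Curtis undefined for the all-zero pair (",
             labels[i], ", ", labels[j], ")")
      }
      d[i, j] <- d[j, i] <- 100 * sum(abs(rows[i, ] - rows[j, ])) / tot
    }
  }
  structure(d, class = c("dissimilarity_matrix", "matrix"))
}

#' Kulczynski similarity matrix on presence/absence rows (0-100 scale)
#'
#' With `a` shared presences and `b`, `c` the presences unique to each row:
#' `S = 100 * 0.5 * (a/(a+b) + a/(a+c))`.
#'
#' @param rows Binary matrix, one sample per row, each row with >= 1
#'   presence.
#' @return Symmetric matrix of class `similarity_matrix`, diagonal 100.
#' @export
kulczynski_similarity <- function(rows) {
  rows <- as.matrix(rows)
  if (!all(rows %in% c(0, 1))) stop("Kulczynski requires binary rows")
  if (any(rowSums(rows) == 0)) {
    stop("Kulczynski undefined for an all-zero row")
  }
  n <- nrow(rows)
  labels <- rownames(rows)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  s <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- sum(rows[i, ] == 1 & rows[j, ] == 1)
      ab <- sum(rows[i, ])
      ac <- sum(rows[j, ])
      s[i, j] <- s[j, i] <- 100 * 0.5 * (a / ab + a / ac)
    }
  }
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' Convert a 0-100 similarity matrix to a dissimilarity matrix
#'
#' Fixed as `d = 100 - s` (the PRIMER-style convention for 0-100 scales).
#'
#' @param s Similarity matrix.
#' @return `dissimilarity_matrix`.
#' @export
similarity_to_dissimilarity <- function(s) {
  d <- 100 - unclass(as.matrix(s))
  structure(d, class = c("dissimilarity_matrix", "matrix"))
}

#' Principal coordinates analysis (PCO)
#'
#' Gower double-centering of `-d^2 / 2` followed by a full
#' eigendecomposition. Coordinates are returned for positive eigenvalues
#' only; the magnitude of the negative eigenvalue mass is reported so
#' metric distortion can be judged (no Lingoes/Cailliez correction is
#' applied). Axis signs are canonicalized so the first nonzero coordinate
#' on each axis is positive, making outputs comparable across runs.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal), n >= 2.
#' @return List of class `pco_result` with `eigenvalues` (all, descending),
#'   `coordinates` (n x n_positive), `percent_variation` (relative to the
#'   positive eigenvalue sum) and `negative_mass`.
#' @export
pco <- function(d) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  stopifnot(n >= 2L, isTRUE(all.equal(d, t(d), tolerance = 1e-9)))
  labels <- rownames(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  g <- (g + t(g)) / 2
  eig <- eigen(g, symmetric = TRUE)
  ev <- eig$values
  tol <- max(abs(ev)) * 1e-9 + 1e-12
  pos <- which(ev > tol)
  if (length(pos) == 0L) {
    coords <- matrix(numeric(0), n, 0, dimnames = list(labels, NULL))
  } else {
    coords <- eig$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(ev[pos]), nrow = length(pos))
    # sign canonicalization: first nonzero loading positive
    for (k in seq_len(ncol(coords))) {
      nz <- which(abs(coords[, k]) > tol)
      if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
    }
    dimnames(coords) <- list(labels, paste0("PCO", seq_len(ncol(coords))))
  }
  structure(list(
    eigenvalues = ev,
    coordinates = coords,
    percent_variation = if (length(pos)) 100 * ev[pos] / sum(ev[pos])
                        else numeric(0),
    negative_mass = sum(abs(ev[ev < -tol]))),
    class = "pco_result")
}

#' Group-average (UPGMA) clustering on a similarity matrix
#'
#' Iteratively merges the most similar pair with group-average updating;
#' merge heights are recorded on the similarity scale (descending from
#' 100). Ties are broken deterministically by lexicographic label order
#' (labels are sorted before clustering).
#'
#' @param s `similarity_matrix` (0-100).
#' @return List of class `similarity_dendrogram` wrapping the `hclust`
#'   tree, with `heights_similarity` and `labels`.
#' @export
upgma <- function(s) {
  s <- unclass(as.matrix(s))
  stopifnot(nrow(s) >= 2L)
  labels <- rownames(s)
  ord <- order(labels)
  s <- s[ord, ord]
  h <- stats::hclust(stats::as.dist(100 - s), method = "average")
  structure(list(hclust = h, labels = h$labels,
                 heights_similarity = 100 - h$height),
            class = "similarity_dendrogram")
}

#' Slice a similarity dendrogram at one or more thresholds
#'
#' Cutting at threshold `t` removes every merge whose similarity is below
#' `t`; the remaining subtrees are the clusters. Increasing `t` refines the
#' partition (never merges clusters).
#'
#' @param dend A [upgma()] result.
#' @param thresholds Similarity thresholds in (0, 100]; default
#'   `c(75, 80, 85, 90, 95)`.
#' @return Named list (one element per threshold) of membership vectors.
#' @export
slice_dendrogram <- function(dend, thresholds = c(75, 80, 85, 90, 95)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 100))
  out <- lapply(thresholds, function(t) {
    k <- stats::cutree(dend$hclust, h = 100 - t)
    setNames(as.integer(k), names(k))
  })
  names(out) <- as.character(thresholds)
  out
}

#' Export a similarity dendrogram as Newick
#'
#' Branch lengths are on the dissimilarity (100 - similarity) scale.
#'
#' @param dend A [upgma()] result.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
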