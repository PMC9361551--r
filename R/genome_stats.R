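#' GC content of an assembly
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param assembly A [genome_assembly()].
#' @return GC percentage in \[0, 100\].
#' @export
gc_content <- function(assembly) {
  set <- Biostrings::DNAStringSet(assembly$contigs)
  counts <- colSums(Biostrings::letterFrequency(set, c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) {
    stop("GC content undefined: assembly '", assembly$genome_id,
         "' contains no unambiguous bases")
  }
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Median intergenic spacer of a genome
#'
#' Per contig, CDS are sorted by start and the gap between consecutive
#' features is `max(0, next_start - end - 1)` (overlaps contribute 0, not a
#' negative value). Gaps are pooled across contigs, strand-agnostic, and
#' contig ends contribute nothing (contig-edge gaps are meaningless on draft
#' genomes). The median of an even pool is the mean of the central pair,
#' rounded half up to an integer bp.
#'
#' @param features A [feature_table()].
#' @param assembly Matching [genome_assembly()] (bounds re-validated).
#' @return Median intergenic spacer in integer bp.
#' @export
median_intergenic_spacer <- function(features, assembly = NULL) {
  f <- features$features
  gaps <- unlist(lapply(split(f, f$contig_id), function(d) {
    if (nrow(d) < 2L) return(numeric(0))
    d <- d[order(d$start), , drop = FALSE]
    pmax(0, d$start[-1L] - d$end[-nrow(d)] - 1L)
  }), use.names = FALSE)
  if (length(gaps) < 1L) {
    stop("median intergenic spacer undefined: fewer than 2 CDS on every contig")
  }
  m <- median(gaps)
  as.integer(floor(m + 0.5))
}

# Total bp covered by CDS after merging overlapping spans on each contig.
merged_cds_bp <- function(features) {
  f <- features$features
  sum(vapply(split(f, f$contig_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    covered <- 0L
    cur_s <- d$start[1L]; cur_e <- d$end[1L]
    if (nrow(d) > 1L) for (i in 2:nrow(d)) {
      if (d$start[i] <= cur_e + 1L) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        covered <- covered + (cur_e - cur_s + 1L)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    covered + (cur_e - cur_s + 1L)
  }, 0L))
}

#' Per-genome descriptive statistics
#'
#' Genome size, GC percentage, CDS count, median intergenic spacer and
#' coding density (merged CDS bp over genome bp).
#'
#' @param assembly A [genome_assembly()].
#' @param features The matching [feature_table()].
#' @return One-row `data.frame` with columns `genome_id`, `size_bp`,
#'   `gc_percent`, `n_cds`, `median_intergenic_bp`, `coding_density`.
#' @export
genome_descriptors <- function(assembly, features) {
  size_bp <- sum(nchar(assembly$contigs))
  data.frame(
    genome_id = assembly$genome_id,
    size_bp = size_bp,
    gc_percent = gc_content(assembly),
    n_cds = nrow(features$features),
    median_intergenic_bp = median_intergenic_spacer(features, assembly),
    coding_density = merged_cds_bp(features) / size_bp,
    stringsAsFactors = FALSE
  )
}

#' Group means and standard deviations of genome descriptors
#'
#' @param descriptors `data.frame` of per-genome descriptors (rows bound
#'   from [genome_descriptors()]).
#' @param metadata A [strain_metadata()] covering every genome.
#' @param group_by `"habitat"` or `"subcluster"`.
#' @return `data.frame` with one row per group and descriptor: `group`,
#'   `descriptor`, `n`, `mean`, `sd` (sample SD, `NA` for n = 1).
#' @export
summarize_groups <- function(descriptors, metadata,
                             group_by = c("habitat", "subcluster")) {
  group_by <- match.arg(group_by)
  miss <- setdiff(descriptors$genome_id, metadata$genome_id)
  if (length(miss)) stop("no metadata for genome: ", miss[1])
  grp <- metadata[[group_by]][match(descriptors$genome_id,
                                    metadata$genome_id)]
  vars <- c("size_bp", "gc_percent", "n_cds", "median_intergenic_bp",
            "coding_density")
  out <- do.call(rbind, lapply(split(descriptors, grp), function(d) {
    data.frame(group = grp[match(d$genome_id[1], descriptors$genome_id)],
               descriptor = vars,
               n = nrow(d),
               mean = vapply(vars, function(v) mean(d[[v]]), 0),
               sd = vapply(vars, function(v)
                 if (nrow(d) >= 2L) sd(d[[v]]) else NA_real_, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- one-way ANOVA with a hand-implemented F p-value -----------------------

# Regularized incomplete beta I_x(a, b) via the Lentz continued fraction
# (the p-value route is implemented here rather than delegated, so the F
# tail probability is reproducible from first principles).
reg_inc_beta <- function(x, a, b) {
  stopifnot(x >= 0, x <= 1, a > 0, b > 0)
  if (x == 0) return(0)
  if (x == 1) return(1)
  lfront <- a * log(x) + b * log1p(-x) - log(a) -
    (lgamma(a) + lgamma(b) - lgamma(a + b))
  # use the symmetry I_x(a,b) = 1 - I_{1-x}(b,a) where the CF converges fast
  if (x > (a + 1) / (a + b + 2)) {
    return(1 - reg_inc_beta(1 - x, b, a))
  }
  tiny <- 1e-300
  f <- 1; c0 <- 1; d <- 0
  for (m in 0:400) {
    if (m == 0) {
      num <- 1
    } else if (m %% 2 == 0) {
      k <- m / 2
      num <- k * (b - k) * x / ((a + 2 * k - 1) * (a + 2 * k))
    } else {
      k <- (m - 1) / 2
      num <- -(a + k) * (a + b + k) * x / ((a + 2 * k) * (a + 2 * k + 1))
    }
    d <- 1 + num * d
    if (abs(d) < tiny) d <- tiny
    d <- 1 / d
    c0 <- 1 + num / c0
    if (abs(c0) < tiny) c0 <- tiny
    f <- f * c0 * d
    if (abs(1 - c0 * d) < 1e-15) break
  }
  exp(lfront) * (f - 1)  # continued fraction form of I_x(a,b)
}

# Upper tail of the F distribution via the incomplete beta identity
# P(F > f) = I_{d2/(d2 + d1 f)}(d2/2, d1/2).
f_pvalue <- function(f, df1, df2) {
  if (f <= 0) return(1)
  reg_inc_beta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

#' Classical one-way ANOVA
#'
#' F = MS_between / MS_within with df (k - 1, N - k); the p-value is the
#' upper F tail computed through the regularized incomplete beta function
#' (continued-fraction implementation in this package).
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List of class `anova_result` with `F`, `df_between`, `df_within`,
#'   `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  N <- length(all_v)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0) {
    if (ssb == 0) {
      return(structure(list(F = 0, df_between = k - 1L, df_within = N - k,
                            p = 1), class = "anova_result"))
    }
    stop("degenerate F: zero within-group variance with unequal group means")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  structure(list(F = f, df_between = k - 1L, df_within = as.integer(N - k),
                 p = f_pvalue(f, k - 1, N - k)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4f on (%d, %d) df, p = %.4g\n",
              x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Pairwise two-group ANOVA tests between habitats or sub-clusters
#'
#' Runs a two-group one-way ANOVA for every unordered pair of groups, one
#' descriptor at a time. No multiple-testing correction is applied; all
#' pairwise p-values are reported.
#'
#' @param descriptors Per-genome descriptor table.
#' @param metadata A [strain_metadata()].
#' @param group_by `"habitat"` or `"subcluster"`.
#' @param descriptor Column of `descriptors` to test.
#' @return `data.frame` with columns `group1`, `group2`, `F`, `df_between`,
#'   `df_within`, `p`.
#' @export
pairwise_anova <- function(descriptors, metadata,
                           group_by = c("habitat", "subcluster"),
                           descriptor = "size_bp") {
  group_by <- match.arg(group_by)
  stopifnot(descriptor %in% names(descriptors))
  grp <- metadata[[group_by]][match(descriptors$genome_id,
                                    metadata$genome_id)]
  values <- split(descriptors[[descriptor]], grp)
  values <- values[lengths(values) >= 2L]
  gs <- names(values)
  if (length(gs) < 2L) stop("need >= 2 groups with >= 2 genomes each")
  pairs <- utils::combn(gs, 2L)
  out <- apply(pairs, 2L, function(pr) {
    a <- one_way_anova(values[pr])
    data.frame(group1 = pr[1], group2 = pr[2], F = a$F,
               df_between = a$df_between, df_within = a$df_within, p = a$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
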