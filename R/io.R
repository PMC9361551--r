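#' Read a FASTA file as an assembly or proteome
#'
#' Sequences are uppercased on read; characters outside the declared
#' alphabet (nucleotide: `ACGTN`; protein: 20 amino acids plus `XBZ`) are
#' rejected with an error naming the record and position. Any line wrapping
#' is accepted.
#'
#' @param path FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param genome_id Identifier for the resulting object; defaults to the
#'   file name without extension.
#' @return A [genome_assembly()] or [proteome()].
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein"),
                       genome_id = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[anyDuplicated(ids)], "' in ", path)
  }
  seqs <- setNames(as.character(set), ids)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna|faa)$", "", basename(path))
  }
  if (alphabet == "nucleotide") {
    genome_assembly(genome_id, seqs)
  } else {
    proteome(genome_id, seqs)
  }
}

#' Write an assembly or proteome to FASTA
#'
#' Sequences are wrapped at 70 characters per line.
#'
#' @param x A [genome_assembly()] or [proteome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "genome_assembly")) x$contigs else x$proteins
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a CDS feature table (GFF3 subset or 5-column TSV)
#'
#' Two dialects are accepted: the CDS subset of GFF3 (9 tab-separated
#' columns; lines whose type is not `CDS` are skipped and counted), or a
#' headerless 5-column TSV `contig_id  start  end  strand  feature_id`.
#' Coordinates are 1-based inclusive in both dialects. Features are
#' validated against the paired assembly.
#'
#' @param path Input file.
#' @param assembly The paired [genome_assembly()] used for bounds checks.
#' @return A [feature_table()]; the number of skipped non-CDS lines is
#'   attached as attribute `n_skipped`.
#' @export
read_feature_table <- function(path, assembly) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no feature records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  n_skipped <- 0L
  if (all(nf == 9L)) {
    type <- vapply(fields, `[[`, "", 3L)
    keep <- type == "CDS"
    n_skipped <- sum(!keep)
    if (n_skipped > 0L) {
      message(n_skipped, " non-CDS line(s) skipped in ", basename(path))
    }
    fields <- fields[keep]
    if (length(fields) == 0L) stop("no CDS records in ", path)
    attr_col <- vapply(fields, `[[`, "", 9L)
    ids <- sub("^.*ID=([^;]+).*$", "\\1", attr_col)
    df <- data.frame(
      contig_id = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 4L)),
      end = as.integer(vapply(fields, `[[`, "", 5L)),
      strand = vapply(fields, `[[`, "", 7L),
      feature_id = ids,
      stringsAsFactors = FALSE
    )
  } else if (all(nf == 5L)) {
    df <- data.frame(
      contig_id = vapply(fields, `[[`, "", 1L),
      start = as.integer(vapply(fields, `[[`, "", 2L)),
      end = as.integer(vapply(fields, `[[`, "", 3L)),
      strand = vapply(fields, `[[`, "", 4L),
      feature_id = vapply(fields, `[[`, "", 5L),
      stringsAsFactors = FALSE
    )
  } else {
    stop("feature table must be uniform GFF3 (9 columns) or 5-column TSV; ",
         "found rows with ", paste(unique(nf), collapse = "/"), " fields")
  }
  ft <- feature_table(assembly$genome_id, df, assembly = assembly)
  attr(ft, "n_skipped") <- n_skipped
  ft
}

#' Write a feature table as GFF3 (CDS lines)
#'
#' @param ft A [feature_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  f <- ft$features
  lines <- c("##gff-version 3",
             paste(f$contig_id, "picopan", "CDS", f$start, f$end, ".",
                   f$strand, "0", paste0("ID=", f$feature_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary gene presence/absence matrix
#'
#' TSV with a `family_id` first column, genome ids in the header, and cells
#' in `{0, 1}`. Per-family occupancy (number of genomes with the family
#' present) is precomputed and attached.
#'
#' @param path Input TSV.
#' @return Integer matrix (families x genomes) of class `pa_matrix` with an
#'   `occupancy` attribute.
#' @export
read_pa_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("presence/absence table needs header + rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    stop("ragged row in presence/absence table (expected ", nf[1],
         " fields, found ", paste(setdiff(unique(nf), nf[1]), collapse = "/"),
         ")")
  }
  header <- fields[[1]]
  genomes <- header[-1]
  if (anyDuplicated(genomes)) stop("duplicate genome id in header")
  body <- fields[-1]
  fam <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(fam)) stop("duplicate family_id")
  cells <- t(vapply(body, function(x) x[-1], character(length(genomes))))
  if (length(genomes) == 1L) cells <- matrix(cells, ncol = 1L)
  if (!all(cells %in% c("0", "1"))) {
    bad <- cells[!cells %in% c("0", "1")][1]
    stop("non-binary cell '", bad, "' in presence/absence table")
  }
  m <- matrix(as.integer(cells), nrow = length(fam),
              dimnames = list(fam, genomes))
  pa_matrix(m)
}

#' Construct a presence/absence matrix object
#'
#' @param m Binary integer matrix, families in rows, genomes in columns,
#'   with dimnames.
#' @return `pa_matrix` object with per-family `occupancy` attribute.
#' @export
pa_matrix <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (!all(m %in% c(0L, 1L))) stop("presence/absence matrix must be binary")
  storage.mode(m) <- "integer"
  structure(m, occupancy = rowSums(m), class = c("pa_matrix", "matrix"))
}

#' Write a presence/absence matrix
#'
#' @param pa `pa_matrix` object.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pa_matrix <- function(pa, path) {
  df <- data.frame(family_id = rownames(pa), unclass(pa)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labelled square matrix (ANI, resemblance) to TSV
#'
#' The matrix must be symmetric within `1e-9` and carry the fixed diagonal
#' of its kind (100 for similarity matrices, 0 for dissimilarity matrices).
#' Values round-trip losslessly at 6 decimal places.
#'
#' @param labels Row/column labels.
#' @param values Square numeric matrix; `NA` marks undefined pairs.
#' @param path Output TSV.
#' @param diagonal Expected diagonal value, 100 or 0.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(labels, values, path, diagonal = c(100, 0)) {
  diagonal <- match.arg(as.character(diagonal[1]), c("100", "0"))
  diagonal <- as.numeric(diagonal)
  values <- as.matrix(values)
  n <- length(labels)
  stopifnot(nrow(values) == n, ncol(values) == n)
  asym <- abs(values - t(values))
  if (any(asym > 1e-9, na.rm = TRUE) ||
      any(is.na(values) != is.na(t(values)))) {
    stop("matrix is not symmetric within 1e-9")
  }
  if (any(abs(diag(values) - diagonal) > 1e-9, na.rm = TRUE)) {
    stop("diagonal must be ", diagonal)
  }
  out <- matrix(sprintf("%.6f", values), n, n)
  out[is.na(values)] <- "NA"
  df <- data.frame(label = labels, out, stringsAsFactors = FALSE)
  names(df) <- c("label", labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' @param path Input TSV written by [write_square_matrix()].
#' @return Numeric matrix with row/column labels.
#' @export
read_square_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, colnames(df)[-1])
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels disagree in ", path)
  }
  m
}

#' Read a strain metadata TSV
#'
#' Fixed header `genome_id  habitat  subcluster  pigment`; unknown extra
#' columns are preserved as an attribute but ignored by the pipeline.
#'
#' @param path Input TSV.
#' @return A [strain_metadata()] table.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  md <- strain_metadata(df)
  extra <- setdiff(names(df), c("genome_id", "habitat", "subcluster", "pigment"))
  if (length(extra)) attr(md, "extra_columns") <- df[extra]
  md
}

#' Write a strain metadata TSV
#'
#' @param md A [strain_metadata()] table.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  df <- as.data.frame(md)
  extra <- attr(md, "extra_columns")
  if (!is.null(extra)) df <- cbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
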