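#' @importFrom stats median rnorm runif setNames sd rgeom
#' @importFrom utils read.delim write.table head
NULL

# data.table is used with standard query syntax inside this package
.datatable.aware <- TRUE

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "B", "Z")
HABITATS <- c("marine", "brackish", "freshwater")
SUBCLUSTERS <- c("5.1", "5.2", "5.3")
PIGMENTS <- c("PC-rich", "PE-rich")

#' Genome assembly for a single strain
#'
#' A genome is an ordered set of contigs over the nucleotide alphabet
#' `A, C, G, T, N`. Lowercase input is normalized to uppercase; any other
#' character is rejected rather than coerced, so downstream statistics
#' (GC content, fragment identity) stay well defined.
#'
#' @param genome_id Non-empty strain identifier.
#' @param contigs Named character vector of contig sequences; names are
#'   contig ids and must be unique.
#' @return An object of class `genome_assembly` with fields `genome_id` and
#'   `contigs`.
#' @export
genome_assembly <- function(genome_id, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(contigs) == 0L) {
    stop("assembly '", genome_id, "' has no contigs")
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig id in assembly '", genome_id, "'")
  }
  contigs <- toupper(contigs)
  check_alphabet(contigs, NUC_ALPHABET, names(contigs))
  if (any(nchar(contigs) < 1L)) stop("contig of length 0 in '", genome_id, "'")
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "genome_assembly")
}

#' Predicted proteome for a single strain
#'
#' @param genome_id Strain identifier.
#' @param proteins Named character vector of protein sequences over the 20
#'   amino-acid letters plus the ambiguity codes `X`, `B`, `Z`.
#' @return An object of class `proteome`.
#' @export
proteome <- function(genome_id, proteins) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(proteins) == 0L) stop("proteome '", genome_id, "' is empty")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("protein ids must be present and unique in '", genome_id, "'")
  }
  proteins <- toupper(proteins)
  check_alphabet(proteins, AA_ALPHABET, names(proteins))
  if (any(nchar(proteins) < 1L)) stop("zero-length protein in '", genome_id, "'")
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "proteome")
}

#' CDS feature table for a single strain
#'
#' Coordinates are 1-based inclusive (GFF3 convention). Features are
#' validated against the paired assembly's contig bounds and stored sorted
#' by `(contig_id, start)`.
#'
#' @param genome_id Strain identifier.
#' @param features `data.frame` with columns `contig_id`, `start`, `end`,
#'   `strand` (`+`/`-`), `feature_id`.
#' @param assembly Optional [genome_assembly()] to validate bounds against.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(genome_id, features, assembly = NULL) {
  need <- c("contig_id", "start", "end", "strand", "feature_id")
  if (!all(need %in% names(features))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  }
  features <- as.data.frame(features)[need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- which(features$start > features$end)
  if (length(bad)) {
    stop("feature '", features$feature_id[bad[1]], "': start > end")
  }
  if (any(features$start < 1L)) stop("coordinates are 1-based; start < 1")
  if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(assembly)) {
    unknown <- setdiff(features$contig_id, names(assembly$contigs))
    if (length(unknown)) {
      stop("feature on unknown contig: ", unknown[1])
    }
    clen <- nchar(assembly$contigs)[match(features$contig_id,
                                          names(assembly$contigs))]
    over <- which(features$end > clen)
    if (length(over)) {
      stop("feature '", features$feature_id[over[1]],
           "' extends past contig end (", features$end[over[1]], " > ",
           clen[over[1]], ")")
    }
  }
  features <- features[order(features$contig_id, features$start), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(genome_id = genome_id, features = features),
            class = "feature_table")
}

#' Strain metadata table
#'
#' Maps each genome to its habitat (`marine`, `brackish`, `freshwater`),
#' sub-cluster (`5.1`, `5.2`, `5.3`) and optional pigment type.
#'
#' @param df `data.frame` with columns `genome_id`, `habitat`, `subcluster`
#'   and optionally `pigment`.
#' @return An object of class `strain_metadata` (a validated data.frame).
#' @export
strain_metadata <- function(df) {
  need <- c("genome_id", "habitat", "subcluster")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id in metadata")
  if (!all(df$habitat %in% HABITATS)) {
    stop("habitat must be one of: ", paste(HABITATS, collapse = ", "))
  }
  if (!all(as.character(df$subcluster) %in% SUBCLUSTERS)) {
    stop("subcluster must be one of: ", paste(SUBCLUSTERS, collapse = ", "))
  }
  if (!"pigment" %in% names(df)) df$pigment <- NA_character_
  df$pigment[!is.na(df$pigment) & df$pigment == ""] <- NA_character_
  ok <- is.na(df$pigment) | df$pigment %in% PIGMENTS
  if (!all(ok)) stop("pigment must be PC-rich, PE-rich or NA")
  out <- data.frame(genome_id = as.character(df$genome_id),
                    habitat = as.character(df$habitat),
                    subcluster = as.character(df$subcluster),
                    pigment = as.character(df$pigment),
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_metadata", "data.frame")
  out
}

# Fail with record name and first offending position if any character falls
# outside the declared alphabet.
check_alphabet <- function(seqs, alphabet, ids) {
  pattern <- paste0("[^", paste(alphabet, collapse = ""), "]")
  hit <- regexpr(pattern, seqs)
  bad <- which(hit > 0L)
  if (length(bad)) {
    i <- bad[1]
    stop("illegal character '", substr(seqs[i], hit[i], hit[i]),
         "' in record '", ids[i], "' at position ", hit[i])
  }
  invisible(TRUE)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", x$genome_id, ": ", length(x$contigs),
      " contig(s), ", sum(nchar(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome> ", x$genome_id, ": ", length(x$proteins),
      " protein(s)\n", sep = "")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", x$genome_id, ": ", nrow(x$features),
      " feature(s)\n", sep = "")
  invisible(x)
}
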