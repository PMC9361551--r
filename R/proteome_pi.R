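#' pKa table for the composition-only protein charge model
#'
#' Defaults follow the EMBOSS set: one N-terminal and one C-terminal group
#' per chain plus the ionizable side chains of K, R, H (basic) and D, E, C,
#' Y (acidic). The table is a plain named list, so alternative constant
#' sets can be swapped in.
#'
#' @param nterm,cterm Terminal pKas.
#' @param K,R,H Basic side-chain pKas.
#' @param D,E,C,Y Acidic side-chain pKas.
#' @return List of class `pka_table` with `basic` and `acidic` named
#'   vectors.
#' @export
pka_table <- function(nterm = 8.6, cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
                      D = 3.9, E = 4.1, C = 8.5, Y = 10.1) {
  basic <- c(nterm = nterm, K = K, R = R, H = H)
  acidic <- c(cterm = cterm, D = D, E = E, C = C, Y = Y)
  all_pka <- c(basic, acidic)
  if (any(all_pka <= 0) || any(all_pka >= 14)) {
    stop("all pKa values must lie in (0, 14)")
  }
  structure(list(basic = basic, acidic = acidic), class = "pka_table")
}

# Counts of each ionizable group per sequence (rows) including the termini.
ionizable_counts <- function(sequences, pka = pka_table()) {
  groups <- c(names(pka$basic), names(pka$acidic))
  res <- setdiff(groups, c("nterm", "cterm"))
  counts <- matrix(0, length(sequences), length(groups),
                   dimnames = list(NULL, groups))
  counts[, "nterm"] <- 1
  counts[, "cterm"] <- 1
  for (r in res) {
    counts[, r] <- nchar(sequences) -
      nchar(gsub(r, "", sequences, fixed = TRUE))
  }
  counts
}

# Net charge at each pH (columns) for each composition row (rows).
charge_from_counts <- function(counts, pH, pka = pka_table()) {
  out <- matrix(0, nrow(counts), length(pH))
  for (g in names(pka$basic)) {
    out <- out + outer(counts[, g], 1 / (1 + 10^(pH - pka$basic[[g]])))
  }
  for (g in names(pka$acidic)) {
    out <- out - outer(counts[, g], 1 / (1 + 10^(pka$acidic[[g]] - pH)))
  }
  out
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch composition model:
#' `charge(pH) = sum_basic 1/(1 + 10^(pH - pKa)) -
#'  sum_acidic 1/(1 + 10^(pKa - pH))`, with one N-terminal and one
#' C-terminal group plus counted side chains. `X`, `B` and `Z` are treated
#' as non-ionizable. The charge is strictly decreasing in pH, which
#' guarantees a unique isoelectric point.
#'
#' @param sequence Protein sequence (single string).
#' @param pH Numeric vector of pH values.
#' @param pka A [pka_table()].
#' @return Net charge at each pH.
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  drop(charge_from_counts(ionizable_counts(sequence, pka), pH, pka))
}

# Net charge for each composition row at its own pH value.
charge_at <- function(counts, pH_vec, pka = pka_table()) {
  out <- numeric(nrow(counts))
  for (g in names(pka$basic)) {
    out <- out + counts[, g] / (1 + 10^(pH_vec - pka$basic[[g]]))
  }
  for (g in names(pka$acidic)) {
    out <- out - counts[, g] / (1 + 10^(pka$acidic[[g]] - pH_vec))
  }
  out
}

# Vectorized bisection on composition rows.
pi_from_counts <- function(counts, pka = pka_table(), tol = 1e-4) {
  n <- nrow(counts)
  lo <- rep(0, n)
  hi <- rep(14, n)
  # clamp when no sign change exists in [0, 14]
  done_lo <- charge_at(counts, lo, pka) <= 0
  done_hi <- charge_at(counts, hi, pka) >= 0
  n_iter <- ceiling(log2(14 / tol))
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    pos <- charge_at(counts, mid, pka) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  out <- (lo + hi) / 2
  out[done_lo] <- 0
  out[done_hi] <- 14
  out
}

#' Isoelectric point of a protein
#'
#' The unique root of [net_charge()] on pH in \[0, 14\], found by bisection
#' to an interval narrower than `tol` (default 1e-4); clamped to the
#' boundary when the charge does not change sign on \[0, 14\].
#'
#' @param sequence Protein sequence (single string) or character vector of
#'   sequences.
#' @param pka A [pka_table()].
#' @param tol Bisection interval-width tolerance.
#' @return Numeric pI value(s).
#' @export
protein_pi <- function(sequence, pka = pka_table(), tol = 1e-4) {
  stopifnot(all(nchar(sequence) >= 1L))
  pi_from_counts(ionizable_counts(sequence, pka), pka, tol)
}

#' Whole-proteome isoelectric-point spectrum
#'
#' Per-protein pIs reduced to relative frequencies over 28 half-open bins
#' of width 0.5 on \[0, 14) with the final bin closed at 14; each protein
#' is weighted equally.
#'
#' @param prot A [proteome()].
#' @param pka A [pka_table()].
#' @return List of class `pi_spectrum` with `genome_id`, `frequencies`
#'   (length 28, sums to 1, named by bin lower bound) and `n_proteins`.
#' @export
pi_spectrum <- function(prot, pka = pka_table()) {
  stopifnot(inherits(prot, "proteome"))
  if (length(prot$proteins) == 0L) stop("empty proteome")
  pis <- protein_pi(prot$proteins, pka)
  bin <- pmin(floor(pis / 0.5), 27)  # pI = 14 falls in the last, closed bin
  freq <- tabulate(bin + 1L, nbins = 28L) / length(pis)
  names(freq) <- sprintf("%.1f", seq(0, 13.5, by = 0.5))
  structure(list(genome_id = prot$genome_id, frequencies = freq,
                 n_proteins = length(pis)),
            class = "pi_spectrum")
}

#' pI spectra of several proteomes as one table
#'
#' @param proteomes Named list of [proteome()] objects.
#' @param pka A [pka_table()].
#' @return Numeric matrix, one row per genome, 28 frequency columns
#'   labelled by bin lower bound.
#' @export
pi_spectrum_table <- function(proteomes, pka = pka_table()) {
  rows <- lapply(proteomes, function(p) pi_spectrum(p, pka)$frequencies)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(proteomes, `[[`, "", "genome_id")
  m
}
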