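# Average residue masses (Da) as used by EMBOSS pepstats; the residue mass
# is the amino-acid mass minus one water, so a peptide MW is the residue sum
# plus one water (18.0153 Da).
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

# ambiguity codes: X = mean residue, B = mean(D,N), Z = mean(E,Q), U -> C mass
.residue_mass_ext <- c(
  .residue_mass,
  X = mean(.residue_mass),
  B = mean(.residue_mass[c("D", "N")]),
  Z = mean(.residue_mass[c("E", "Q")]),
  U = unname(.residue_mass["C"])
)

# EMBOSS default pKa table (Epk.dat); ambiguous and U residues are treated
# as non-ionizable, disulfides are ignored (all cysteines free)
.pka_default <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
                  D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

aa_counts <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), names(.residue_mass_ext))
  if (length(bad))
    abort(paste0("unknown residue(s): ", paste(bad, collapse = "")))
  table(factor(chars, levels = names(.residue_mass_ext)))
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), matching the
#' EMBOSS pepstats mass table. Ambiguous residues contribute the mean of
#' their candidate masses (`X` the mean over all twenty); selenocysteine
#' (`U`) is given the cysteine mass.
#'
#' @param sequence Amino-acid string (no `*`; see [read_fasta()] which
#'   strips trailing stops).
#' @return Molecular weight in daltons.
#' @examples
#' compute_mw("G")  # 75.07 Da
#' @export
compute_mw <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    abort("sequence must be a single non-empty string")
  cnt <- aa_counts(sequence)
  sum(cnt * .residue_mass_ext[names(cnt)]) + .water_mass
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups (N-terminus,
#' C-terminus, and the side chains of K, R, H, D, E, C, Y):
#' positive groups contribute \eqn{1/(1+10^{pH-pKa})}, negative groups
#' \eqn{-1/(1+10^{pKa-pH})}. The default pKa set is the EMBOSS pepstats
#' table.
#'
#' @param sequence Amino-acid string.
#' @param ph pH in `[0, 14]`.
#' @param pka Named numeric vector of pKa values; names `Nterm`, `Cterm`,
#'   `K`, `R`, `H`, `D`, `E`, `C`, `Y`.
#' @return Signed net charge (elementary charges).
#' @export
net_charge <- function(sequence, ph, pka = .pka_default) {
  if (!is.numeric(ph) || ph < 0 || ph > 14) abort("pH must lie in [0, 14]")
  cnt <- aa_counts(sequence)
  basic <- c(Nterm = 1, cnt[c("K", "R", "H")])
  names(basic) <- c("Nterm", "K", "R", "H")
  acidic <- c(Cterm = 1, cnt[c("D", "E", "C", "Y")])
  names(acidic) <- c("Cterm", "D", "E", "C", "Y")
  pos <- sum(basic / (1 + 10^(ph - pka[names(basic)])))
  neg <- sum(acidic / (1 + 10^(pka[names(acidic)] - ph)))
  unname(pos - neg)
}

#' Isoelectric point of a protein
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' `[0, 14]` to a tolerance of 1e-4 pH units. Since every charge term is
#' strictly decreasing in pH the crossing is unique; the two termini always
#' ionize, so a crossing exists for any valid sequence. (A degenerate call
#' with no ionizable group returns 7.0 with a warning rather than erroring,
#' so batch jobs never abort.)
#'
#' @inheritParams net_charge
#' @param tol Bisection stopping width in pH units.
#' @return Isoelectric point in pH units.
#' @examples
#' compute_pi("GG")  # midpoint of the two terminal pKas, 6.1
#' @export
compute_pi <- function(sequence, pka = .pka_default, tol = 1e-4) {
  cnt <- aa_counts(sequence)
  n_ionizable <- 2 + sum(cnt[c("K", "R", "H", "D", "E", "C", "Y")])
  if (n_ionizable == 0) {
    warn("sequence has no ionizable group; returning pI = 7.0")
    return(7.0)
  }
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, pka)
  if (f_lo <= 0) return(lo)
  if (net_charge(sequence, hi, pka) >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical profile of a protein set
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns
#'   (e.g. from [read_fasta()]).
#' @return A tibble with columns `protein_id`, `length`, `mw_da`, `pi`.
#' @export
physico_profile <- function(proteins) {
  tibble::tibble(
    protein_id = proteins$protein_id,
    length = nchar(proteins$sequence),
    mw_da = vapply(proteins$sequence, compute_mw, numeric(1), USE.NAMES = FALSE),
    pi = vapply(proteins$sequence, compute_pi, numeric(1), USE.NAMES = FALSE)
  )
}

#' Compare pI or MW distributions of identified proteins to a reference
#'
#' Bins both collections on a shared axis and returns per-bin fractions,
#' for checking that the identified proteins are an unbiased slice of the
#' reference proteome. Also reports the proportion of basic proteins
#' (pI > 7.0) in each collection.
#'
#' @param profiles Tibble from [physico_profile()] for the identified set.
#' @param reference Same, for the reference proteome.
#' @param axis `"pi"` (pH units) or `"mw"` (daltons).
#' @param bins Strictly increasing bin edges covering both collections.
#' @return An object of class `distribution_comparison`: a tibble with
#'   `bin_lo`, `bin_hi`, `identified_fraction`, `reference_fraction`, with
#'   attributes `axis`, `basic_identified`, `basic_reference`.
#' @export
profile_distributions <- function(profiles, reference, axis = c("pi", "mw"),
                                  bins = NULL) {
  axis <- match.arg(axis)
  if (nrow(profiles) == 0 || nrow(reference) == 0)
    abort("both collections must be non-empty")
  col <- if (axis == "pi") "pi" else "mw_da"
  x <- profiles[[col]]; y <- reference[[col]]
  if (is.null(bins)) {
    bins <- if (axis == "pi") seq(2, 14, by = 1) else
      c(0, 10e3, 20e3, 30e3, 40e3, 50e3, 75e3, 100e3, 150e3, 250e3, Inf)
    bins[1] <- min(bins[1], floor(min(x, y)))
    bins[length(bins)] <- max(bins[length(bins)], ceiling(max(x, y)))
  }
  if (any(diff(bins) <= 0)) abort("bin edges must be strictly increasing")
  cut_frac <- function(v) {
    h <- table(cut(v, bins, include.lowest = TRUE))
    as.numeric(h) / length(v)
  }
  out <- tibble::tibble(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1],
    identified_fraction = cut_frac(x),
    reference_fraction = cut_frac(y)
  )
  structure(out, class = c("distribution_comparison", class(out)),
            axis = axis,
            basic_identified = mean(profiles$pi > 7.0),
            basic_reference = mean(reference$pi > 7.0))
}

#' @exportS3Method
autoplot.distribution_comparison <- function(object, ...) {
  axis <- attr(object, "axis")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("identified_fraction", "reference_fraction"),
                              names_to = "set", values_to = "fraction")
  long$set <- sub("_fraction", "", long$set)
  long$bin <- factor(sprintf("%.3g-%.3g", long$bin_lo, long$bin_hi),
                     levels = unique(sprintf("%.3g-%.3g", long$bin_lo, long$bin_hi)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = if (axis == "pi") "pI (pH units)" else "MW (Da)",
                  y = "fraction of proteins", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
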