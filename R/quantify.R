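#' Filter proteins by replicate-consistent identification
#'
#' A shotgun run identifies only a fraction of the proteins present, so
#' comparative analysis is restricted to proteins identified reproducibly:
#' a (variety, condition) group "passes" for a protein when every replicate
#' in the group has SpC >= `min_spc`. Which groups must pass is set by
#' `scope`:
#' \describe{
#'   \item{`any-group`}{(default) at least one group passes. Zeros elsewhere
#'     later receive the pseudocount, which is the only reading compatible
#'     with both a strict all-replicates filter and the near on/off
#'     expression ratios (hundreds-fold) such data show.}
#'   \item{`per-comparison`}{both groups of at least one variety pass.}
#'   \item{`all-groups`}{every group passes.}
#' }
#'
#' @param counts Wide count tibble ([read_count_table()]).
#' @param design Design tibble ([read_design()]).
#' @param min_spc Minimum SpC per replicate (default 2).
#' @param scope Filter scope, see Details.
#' @return An object of class `filter_report`: list with `retained_ids`,
#'   `dropped` (tibble of `protein_id`, `reason`), `group_pass` (tibble of
#'   per-protein pass flags per group), and the parameters used.
#' @export
apply_replicate_filter <- function(counts, design,
                                   min_spc = 2,
                                   scope = c("any-group", "per-comparison", "all-groups")) {
  scope <- match.arg(scope)
  if (min_spc < 0) abort("min_spc must be nonnegative")
  m <- counts_to_matrix(counts)
  missing_samples <- setdiff(design$sample_id, colnames(m))
  if (length(missing_samples))
    abort(paste0("design samples absent from counts: ",
                 paste(missing_samples, collapse = ", ")))
  groups <- split(design$sample_id, paste(design$variety, design$condition, sep = "."))
  pass <- vapply(groups, function(s) {
    matrixStats_rowMins <- apply(m[, s, drop = FALSE], 1, min)
    matrixStats_rowMins >= min_spc
  }, logical(nrow(m)))
  if (is.null(dim(pass))) pass <- matrix(pass, nrow = 1, dimnames = list(rownames(m), names(groups)))
  retained <- switch(scope,
    "any-group" = rowSums(pass) > 0,
    "all-groups" = rowSums(pass) == ncol(pass),
    "per-comparison" = {
      varieties <- unique(design$variety)
      keep <- rep(FALSE, nrow(m))
      for (v in varieties) {
        gcols <- grep(paste0("^", v, "\\."), colnames(pass))
        keep <- keep | rowSums(pass[, gcols, drop = FALSE]) == length(gcols)
      }
      keep
    })
  dropped <- tibble::tibble(
    protein_id = rownames(m)[!retained],
    reason = sprintf("no group meets SpC >= %s in all replicates (scope %s)",
                     format(min_spc), scope)
  )
  structure(list(
    retained_ids = rownames(m)[retained],
    dropped = dropped,
    group_pass = tibble::as_tibble(pass) |>
      dplyr::mutate(protein_id = rownames(m), .before = 1),
    min_spc = min_spc, scope = scope
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("replicate filter (min SpC %s, scope %s): %d retained, %d dropped\n",
              format(x$min_spc), x$scope, length(x$retained_ids), nrow(x$dropped)))
  invisible(x)
}

#' @exportS3Method
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(protein_id = x$retained_ids, retained = TRUE,
                   reason = NA_character_),
    dplyr::mutate(x$dropped, retained = FALSE)[c("protein_id", "retained", "reason")]
  )
}

#' Replace zero spectral counts with a pseudocount
#'
#' Over the retained proteins only, zeros (non-identification in a run)
#' become `epsilon` on the SpC scale before length division and NSAF
#' normalization, making the subsequent ln transform defined and allowing
#' near on/off proteins to yield large finite ratios.
#'
#' @param counts Wide count tibble.
#' @param retained Character vector of protein ids, or a `filter_report`.
#' @param epsilon Pseudocount added to zero SpC (default 0.1).
#' @return Wide tibble restricted to retained proteins, numeric cells.
#' @export
add_pseudocount <- function(counts, retained = counts$protein_id, epsilon = 0.1) {
  if (inherits(retained, "filter_report")) retained <- retained$retained_ids
  if (!is.numeric(epsilon) || epsilon <= 0) abort("epsilon must be > 0")
  if (length(retained) == 0) abort("retained set is empty")
  missing <- setdiff(retained, counts$protein_id)
  if (length(missing)) abort(paste0("retained ids absent from counts: ",
                                    paste(head(missing, 5), collapse = ", ")))
  sub <- counts[match(retained, counts$protein_id), ]
  m <- counts_to_matrix(sub)
  m[m == 0] <- epsilon
  matrix_to_counts(m)
}

#' NSAF normalization of spectral counts
#'
#' Computes the normalized spectral count of protein *k* in a sample as
#' \deqn{NSpC_k = \frac{(SpC/L)_k}{\sum_{i=1}^{n} (SpC/L)_i}}
#' where *L* is the residue length and the sum runs over the retained
#' proteins within that sample, so each sample column sums to one. Apply
#' [add_pseudocount()] first so that every entry is positive.
#'
#' @param adjusted_counts Wide (pseudocounted) count tibble.
#' @param lengths Named numeric vector of residue lengths, or a tibble with
#'   `protein_id` and `length` columns ([read_fasta()] output works).
#' @return Wide tibble of NSpC values, same shape as the input.
#' @export
nsaf_normalize <- function(adjusted_counts, lengths) {
  if (is.data.frame(lengths))
    lengths <- setNames(lengths$length, lengths$protein_id)
  m <- counts_to_matrix(adjusted_counts)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    abort(paste0("no length for protein(s): ", paste(head(missing, 5), collapse = ", ")))
  L <- lengths[rownames(m)]
  if (any(L <= 0)) abort("protein lengths must be > 0")
  saf <- m / L
  denom <- colSums(saf)
  if (any(denom <= 0)) abort("zero NSAF denominator in a sample")
  matrix_to_counts(sweep(saf, 2, denom, "/"))
}

#' Replicate reproducibility (pairwise R-squared) of NSpC values
#'
#' Squared Pearson correlation of NSpC vectors for each replicate pair
#' within each (variety, condition) group, on the untransformed NSpC scale.
#' Values around 0.8-0.95 indicate reproducible label-free quantification.
#'
#' @param nspc Wide NSpC tibble ([nsaf_normalize()]).
#' @param design Design tibble.
#' @return A tibble with `variety`, `condition`, `sample_a`, `sample_b`,
#'   `r2`; group means are in attribute `group_means` (tibble with
#'   `variety`, `condition`, `mean_r2`).
#' @export
replicate_r2 <- function(nspc, design) {
  m <- counts_to_matrix(nspc)
  groups <- dplyr::group_split(dplyr::group_by(design, .data$variety, .data$condition))
  rows <- purrr::map_dfr(groups, function(g) {
    s <- g$sample_id
    if (length(s) < 2) abort("each group needs >= 2 replicates for R^2")
    pairs <- utils::combn(s, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- m[, pairs[1, j]]; b <- m[, pairs[2, j]]
      r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warn(sprintf("constant NSpC vector in %s/%s; R^2 undefined",
                     g$variety[1], g$condition[1]))
        NA_real_
      } else cor(a, b)^2
      tibble::tibble(variety = g$variety[1], condition = g$condition[1],
                     sample_a = pairs[1, j], sample_b = pairs[2, j], r2 = r2)
    })
  })
  gm <- dplyr::summarise(dplyr::group_by(rows, .data$variety, .data$condition),
                         mean_r2 = mean(.data$r2, na.rm = TRUE), .groups = "drop")
  structure(rows, group_means = gm)
}
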