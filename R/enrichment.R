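#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` annotated proteins in a sample of `n` from a background of `N`
#' of which `K` carry the annotation. Computed by summing terms in
#' log-space (log-binomials plus log-sum-exp) so small tails are stable.
#' Equivalent to a one-sided Fisher exact test on the 2x2 table.
#'
#' @param k Observed successes in the sample.
#' @param K Successes in the background.
#' @param n Sample size.
#' @param N Background size.
#' @return The upper-tail probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    abort("need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  j <- seq(k, min(K, n))
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1; a thin
#' validated wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"` (Benjamini-Yekutieli, valid
#'   under arbitrary dependence among the tests).
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p_values, method = method)
}

#' GO singular enrichment of a protein list against a genome background
#'
#' For each GO term with at least `min_term_size` annotated background
#' proteins, tests over-representation in the input list with the
#' hypergeometric upper tail and adjusts across all tested terms with
#' Benjamini-Hochberg. Following the singular-enrichment convention, the
#' universe is restricted to annotated proteins within each namespace:
#' n = |input proteins with >= 1 term in the namespace|, N = |background
#' proteins with >= 1 term in the namespace|. Annotations are used as given
#' in the flat input file; no GO-DAG ancestor propagation is performed.
#'
#' @param de_ids Character vector of input (e.g. differentially expressed)
#'   protein ids.
#' @param annotations Tibble from [read_go_annotations()] (`protein_id`,
#'   `go_id`, `namespace`).
#' @param background_ids Character vector of background protein ids
#'   (typically the whole annotated genome).
#' @param min_term_size Minimum annotated background proteins per term.
#' @param fdr_cut Report terms with FDR at or below this (default 0.05).
#' @param descriptions Optional named character vector mapping go_id to a
#'   human-readable description.
#' @param method FDR method, `"BH"` or `"BY"`.
#' @return An object of class `go_enrichment`; `tidy()` gives the rows at
#'   `fdr <= fdr_cut` ordered by namespace then p-value with columns
#'   `go_id`, `description`, `namespace`, `k_input`, `K_genome`, `p_value`,
#'   `fdr`; the full tested table is in `$all_terms`.
#' @export
go_enrichment <- function(de_ids, annotations, background_ids,
                          min_term_size = 2, fdr_cut = 0.05,
                          descriptions = NULL, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(de_ids) == 0) abort("input protein list is empty")
  if (nrow(annotations) == 0) abort("annotation map is empty; cannot run enrichment")
  orphans <- setdiff(de_ids, background_ids)
  if (length(orphans)) {
    warn(sprintf("%d input proteins absent from the background; excluded", length(orphans)))
    de_ids <- intersect(de_ids, background_ids)
  }
  ann <- annotations[annotations$protein_id %in% background_ids, ]
  ann$namespace[is.na(ann$namespace)] <- "unspecified"
  ann <- dplyr::distinct(ann, .data$protein_id, .data$go_id, .data$namespace)
  tested <- purrr::map_dfr(split(ann, ann$namespace), function(a) {
    universe <- unique(a$protein_id)
    n <- length(intersect(de_ids, universe))
    N <- length(universe)
    if (n == 0) return(tibble::tibble())
    per_term <- dplyr::summarise(
      dplyr::group_by(a, .data$go_id),
      namespace = .data$namespace[1],
      K_genome = dplyr::n_distinct(.data$protein_id),
      k_input = length(intersect(unique(.data$protein_id), de_ids)),
      .groups = "drop")
    per_term <- per_term[per_term$K_genome >= min_term_size, ]
    if (nrow(per_term) == 0) return(tibble::tibble())
    per_term$n_input <- n
    per_term$N_background <- N
    per_term$p_value <- vapply(seq_len(nrow(per_term)), function(i)
      hypergeom_upper_tail(per_term$k_input[i], per_term$K_genome[i], n, N),
      numeric(1))
    per_term
  })
  if (nrow(tested) == 0) abort("no testable terms (input list has no annotated proteins)")
  tested$fdr <- bh_fdr(tested$p_value, method = method)
  tested$description <- if (is.null(descriptions)) tested$go_id else
    dplyr::coalesce(unname(descriptions[tested$go_id]), tested$go_id)
  tested <- tested[order(tested$namespace, tested$p_value, tested$go_id), ]
  cols <- c("go_id", "description", "namespace", "k_input", "K_genome",
            "n_input", "N_background", "p_value", "fdr")
  tested <- tibble::as_tibble(tested[cols])
  structure(list(all_terms = tested, fdr_cut = fdr_cut,
                 n_input = length(de_ids), method = method),
            class = "go_enrichment")
}

#' @export
print.go_enrichment <- function(x, ...) {
  sig <- tidy(x)
  cat(sprintf("GO enrichment: %d terms tested, %d at FDR <= %.3g (%s)\n",
              nrow(x$all_terms), nrow(sig), x$fdr_cut, x$method))
  invisible(x)
}

#' @exportS3Method
tidy.go_enrichment <- function(x, ...) {
  out <- x$all_terms[x$all_terms$fdr <= x$fdr_cut, ]
  out[c("go_id", "description", "namespace", "k_input", "K_genome",
        "p_value", "fdr")]
}

#' @exportS3Method
glance.go_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms_tested = nrow(x$all_terms),
    n_enriched = sum(x$all_terms$fdr <= x$fdr_cut),
    fdr_cut = x$fdr_cut,
    method = x$method,
    n_input = x$n_input
  )
}

#' Bar plot of enriched GO terms
#'
#' @param object A `go_enrichment` object.
#' @param ... Unused.
#' @return A ggplot of -log10 FDR for the enriched terms, by namespace.
#' @exportS3Method
autoplot.go_enrichment <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) abort("no enriched terms to plot")
  d$description <- factor(d$description, levels = rev(unique(d$description)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$fdr), y = .data$description,
                                  fill = .data$namespace)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10]~FDR), y = NULL) +
    ggplot2::theme_minimal()
}
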