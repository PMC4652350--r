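#' Natural-log transform of an NSpC table
#'
#' @param nspc Wide NSpC tibble with all entries > 0 (pseudocount first).
#' @return Wide tibble of ln(NSpC).
#' @export
ln_transform <- function(nspc) {
  m <- counts_to_matrix(nspc)
  if (any(m <= 0))
    abort("nonpositive NSpC entry; apply add_pseudocount() before normalizing")
  matrix_to_counts(log(m))
}

#' Two-sample t-test on ln-transformed NSpC values
#'
#' Two-sided Student's t with pooled variance by default (df = 4 for 3 + 3
#' replicates), the classical choice for tiny balanced groups; set
#' `var_equal = FALSE` for Welch. Zero-variance degeneracies are resolved
#' deterministically instead of erroring: both groups constant and equal
#' gives p = 1, constant and unequal gives p = 0 (flagged via the
#' `"degenerate"` attribute) so batch runs never abort.
#'
#' @param group_a,group_b Numeric vectors of ln(NSpC), length >= 2 each.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch.
#' @return Two-sided p-value. Attribute `degenerate` is `TRUE` when both
#'   groups had zero variance.
#' @export
ttest_ln <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    abort("each group needs at least 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    p <- if (mean(group_a) == mean(group_b)) 1 else 0
    return(structure(p, degenerate = TRUE))
  }
  p <- t.test(group_a, group_b, var.equal = var_equal)$p.value
  structure(unname(p), degenerate = FALSE)
}

#' Cold/control expression ratio
#'
#' Ratio of arithmetic group means of NSpC (cold over control); with the
#' pseudocount in place both means are positive, so near on/off proteins
#' produce large finite ratios rather than infinities.
#'
#' @param mean_cold,mean_control Positive group means of NSpC.
#' @return The ratio cold/control.
#' @export
fold_change <- function(mean_cold, mean_control) {
  if (any(mean_cold <= 0) || any(mean_control <= 0))
    abort("group means must be > 0")
  mean_cold / mean_control
}

#' Classify proteins as up, down, or not significant
#'
#' A protein is `up` when p < `alpha` and ratio >= `fold`, `down` when
#' p < `alpha` and ratio <= 1/`fold`, otherwise `ns`. "Greater than
#' 2-fold" is implemented inclusively: a ratio of exactly 2 (or 0.5) is
#' declared differentially expressed.
#'
#' @param records Tibble with columns `ratio` and `p_value`.
#' @param alpha Significance level (default 0.05). No multiple-testing
#'   correction is applied by default; see [differential_expression()].
#' @param fold Fold-change threshold > 1 (default 2).
#' @return `records` with a `class` factor column added.
#' @export
classify <- function(records, alpha = 0.05, fold = 2.0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!is.numeric(fold) || fold <= 1) abort("fold must be > 1")
  dplyr::mutate(records, class = factor(dplyr::case_when(
    .data$p_value < alpha & .data$ratio >= fold ~ "up",
    .data$p_value < alpha & .data$ratio <= 1 / fold ~ "down",
    TRUE ~ "ns"
  ), levels = c("up", "down", "ns")))
}

#' Per-variety cold-vs-control differential expression
#'
#' For one variety, runs [ttest_ln()] on the ln(NSpC) of cold vs control
#' replicates of every protein, computes the arithmetic-mean NSpC ratio
#' (cold/control), and classifies each protein with [classify()].
#'
#' @param nspc Wide NSpC tibble (pseudocounted and normalized).
#' @param design Design tibble.
#' @param variety `"resistant"` or `"susceptible"`.
#' @param alpha,fold Thresholds passed to [classify()].
#' @param var_equal Pooled (default) or Welch t-test.
#' @param adjust Multiple-testing adjustment applied to p-values before
#'   classification: `"none"` (default, mirroring raw per-protein testing at
#'   alpha) or `"BH"`.
#' @return An object of class `rice_de`; `tidy()` gives the per-protein
#'   tibble (`protein_id`, `variety`, `mean_cold`, `mean_control`, `ratio`,
#'   `p_value`, `class`, `degenerate`), `glance()` one-row counts.
#' @export
differential_expression <- function(nspc, design, variety,
                                    alpha = 0.05, fold = 2.0,
                                    var_equal = TRUE,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  variety <- match.arg(variety, .varieties)
  m <- counts_to_matrix(nspc)
  cold_s <- design$sample_id[design$variety == variety & design$condition == "cold"]
  ctrl_s <- design$sample_id[design$variety == variety & design$condition == "control"]
  if (length(cold_s) < 2 || length(ctrl_s) < 2)
    abort(paste0("variety '", variety, "' needs >= 2 replicates per condition"))
  lnm <- log(m)
  if (any(!is.finite(lnm)))
    abort("nonpositive NSpC entry; apply add_pseudocount() before normalizing")
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    p <- ttest_ln(lnm[i, cold_s], lnm[i, ctrl_s], var_equal = var_equal)
    tibble::tibble(
      protein_id = rownames(m)[i],
      variety = variety,
      mean_cold = mean(m[i, cold_s]),
      mean_control = mean(m[i, ctrl_s]),
      p_value = as.numeric(p),
      degenerate = attr(p, "degenerate")
    )
  })
  res$ratio <- fold_change(res$mean_cold, res$mean_control)
  if (adjust == "BH") res$p_value <- p.adjust(res$p_value, method = "BH")
  res <- classify(res, alpha = alpha, fold = fold)
  res <- res[c("protein_id", "variety", "mean_cold", "mean_control",
               "ratio", "p_value", "class", "degenerate")]
  structure(list(records = res, alpha = alpha, fold = fold,
                 var_equal = var_equal, adjust = adjust),
            class = "rice_de")
}

#' @export
print.rice_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("differential expression, %s: %d proteins tested, %d up, %d down (alpha %.3g, fold %.3g, %s t-test)\n",
              x$records$variety[1] %||% "?", g$n_tested, g$n_up, g$n_down,
              x$alpha, x$fold, if (x$var_equal) "pooled" else "Welch"))
  invisible(x)
}

#' @exportS3Method
tidy.rice_de <- function(x, ...) x$records

#' @exportS3Method
glance.rice_de <- function(x, ...) {
  tibble::tibble(
    variety = x$records$variety[1] %||% NA_character_,
    n_tested = nrow(x$records),
    n_up = sum(x$records$class == "up"),
    n_down = sum(x$records$class == "down"),
    n_de = sum(x$records$class != "ns"),
    alpha = x$alpha, fold = x$fold,
    test = if (x$var_equal) "pooled" else "welch",
    adjust = x$adjust
  )
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `rice_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.rice_de <- function(object, ...) {
  d <- object$records
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$ratio),
                                  y = -log10(.data$p_value),
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log(object$fold), log(object$fold)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#d1495b", down = "#30638e",
                                            ns = "grey70")) +
    ggplot2::labs(x = "ln expression ratio (cold/control)",
                  y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}

#' Cross-variety categorization of differentially expressed proteins
#'
#' Splits the union of DE proteins (class up or down) into three disjoint
#' sets: responding only in the resistant variety, only in the susceptible
#' variety, or in both; tallies up/down per set; and flags overlap proteins
#' whose direction disagrees between varieties (e.g. up in the resistant
#' response but down in the susceptible one).
#'
#' @param resistant,susceptible `rice_de` objects (or their `tidy()`
#'   tibbles) for the two varieties.
#' @return An object of class `response_categories`; `tidy()` gives one row
#'   per DE protein with its category and per-variety direction, `glance()`
#'   the category tallies.
#' @export
categorize_responses <- function(resistant, susceptible) {
  get_rec <- function(x) if (inherits(x, "rice_de")) x$records else tibble::as_tibble(x)
  r <- get_rec(resistant); s <- get_rec(susceptible)
  r_de <- r[r$class != "ns", c("protein_id", "class")]
  s_de <- s[s$class != "ns", c("protein_id", "class")]
  overlap_ids <- intersect(r_de$protein_id, s_de$protein_id)
  res_only <- setdiff(r_de$protein_id, overlap_ids)
  sus_only <- setdiff(s_de$protein_id, overlap_ids)
  rows <- dplyr::bind_rows(
    tibble::tibble(protein_id = res_only, category = "resistant_only",
                   class_resistant = as.character(r_de$class[match(res_only, r_de$protein_id)]),
                   class_susceptible = NA_character_),
    tibble::tibble(protein_id = sus_only, category = "susceptible_only",
                   class_resistant = NA_character_,
                   class_susceptible = as.character(s_de$class[match(sus_only, s_de$protein_id)])),
    tibble::tibble(protein_id = overlap_ids, category = "overlap",
                   class_resistant = as.character(r_de$class[match(overlap_ids, r_de$protein_id)]),
                   class_susceptible = as.character(s_de$class[match(overlap_ids, s_de$protein_id)]))
  )
  rows$discordant <- rows$category == "overlap" &
    rows$class_resistant != rows$class_susceptible
  structure(list(
    resistant_only = res_only,
    susceptible_only = sus_only,
    overlap = overlap_ids,
    records = tibble::as_tibble(rows)
  ), class = "response_categories")
}

#' @export
print.response_categories <- function(x, ...) {
  cat(sprintf("DE response categories: %d resistant-only, %d susceptible-only, %d overlap (%d discordant)\n",
              length(x$resistant_only), length(x$susceptible_only),
              length(x$overlap), sum(x$records$discordant)))
  invisible(x)
}

#' @exportS3Method
tidy.response_categories <- function(x, ...) x$records

#' @exportS3Method
glance.response_categories <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    resistant_only = length(x$resistant_only),
    resistant_only_up = sum(r$category == "resistant_only" & r$class_resistant == "up"),
    resistant_only_down = sum(r$category == "resistant_only" & r$class_resistant == "down"),
    susceptible_only = length(x$susceptible_only),
    susceptible_only_up = sum(r$category == "susceptible_only" & r$class_susceptible == "up"),
    susceptible_only_down = sum(r$category == "susceptible_only" & r$class_susceptible == "down"),
    overlap = length(x$overlap),
    overlap_discordant = sum(r$discordant)
  )
}

#' Three-set summary plot of response categories
#'
#' @param object A `response_categories` object.
#' @param ... Unused.
#' @return A ggplot bar chart of the category tallies split by direction.
#' @exportS3Method
autoplot.response_categories <- function(object, ...) {
  r <- object$records
  r$direction <- ifelse(r$category == "susceptible_only",
                        r$class_susceptible, r$class_resistant)
  r$category <- factor(r$category,
                       levels = c("resistant_only", "overlap", "susceptible_only"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$category, fill = .data$direction)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(up = "#d1495b", down = "#30638e")) +
    ggplot2::labs(x = NULL, y = "differentially expressed proteins") +
    ggplot2::theme_minimal()
}
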