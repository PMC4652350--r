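#' Run the full spectral-count analysis pipeline
#'
#' Orchestrates read/validate -> replicate filter -> pseudocount -> NSAF
#' normalization -> replicate R^2 QC -> per-variety differential expression
#' -> cross-variety categorization -> GO enrichment (skipped with a message
#' when no annotation file is given) -> optional pI/MW profiling. Stages
#' communicate through files under `out_dir` so any stage can be inspected
#' or re-run in isolation, and a machine-readable run summary records the
#' parameter snapshot and per-stage tallies. Reruns on identical inputs are
#' byte-identical.
#'
#' @param config Path to a YAML file, or a named list, with entries:
#'   `counts`, `design`, `fasta` (paths, required), `go` (path, optional),
#'   `out_dir` (required), and optional parameters `min_spc` (2),
#'   `filter_scope` ("any-group"), `pseudocount` (0.1), `alpha` (0.05),
#'   `fold` (2), `var_equal` (TRUE), `adjust` ("none"), `fdr_cut` (0.05),
#'   `physico` (FALSE), `seed` (1).
#' @param quiet Suppress per-stage messages.
#' @return The run summary, invisibly (a named list mirroring
#'   `run_summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("counts", "design", "fasta", "out_dir"))
    if (is.null(config[[need]])) abort(paste0("config lacks '", need, "'"))
  p <- list(min_spc = config$min_spc %||% 2,
            filter_scope = config$filter_scope %||% "any-group",
            pseudocount = config$pseudocount %||% 0.1,
            alpha = config$alpha %||% 0.05,
            fold = config$fold %||% 2,
            var_equal = config$var_equal %||% TRUE,
            adjust = config$adjust %||% "none",
            fdr_cut = config$fdr_cut %||% 0.05,
            seed = config$seed %||% 1)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e))))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- stage("io", read_count_table(config$counts))
  design <- stage("io", read_design(config$design))
  proteins <- stage("io", read_fasta(config$fasta))
  say("io: %d proteins x %d samples read", nrow(counts), ncol(counts) - 1)

  filt <- stage("filter", apply_replicate_filter(counts, design,
                                                 min_spc = p$min_spc,
                                                 scope = p$filter_scope))
  say("filter: %d of %d proteins retained", length(filt$retained_ids), nrow(counts))
  adj <- stage("pseudocount", add_pseudocount(counts, filt, epsilon = p$pseudocount))
  nspc <- stage("normalize", nsaf_normalize(adj, proteins))
  write_count_table(nspc, file.path(out_dir, "nspc.tsv"))
  r2 <- stage("qc", replicate_r2(nspc, design))
  readr::write_tsv(r2, file.path(out_dir, "replicate_r2.tsv"), progress = FALSE)
  gm <- attr(r2, "group_means")
  say("qc: replicate R^2 group means %s", paste(sprintf("%.2f", gm$mean_r2), collapse = ", "))

  de <- purrr::map(setNames(.varieties, .varieties), function(v)
    stage("diffexpr", differential_expression(
      nspc, design, v, alpha = p$alpha, fold = p$fold,
      var_equal = p$var_equal, adjust = p$adjust)))
  for (v in .varieties)
    say("diffexpr (%s): %d DE of %d tested", v,
        glance(de[[v]])$n_de, glance(de[[v]])$n_tested)
  cats <- stage("categorize", categorize_responses(de$resistant, de$susceptible))
  say("categorize: %d resistant-only, %d susceptible-only, %d overlap",
      length(cats$resistant_only), length(cats$susceptible_only), length(cats$overlap))
  readr::write_tsv(tidy(cats), file.path(out_dir, "categories.tsv"), progress = FALSE)
  fig5 <- report_fig5_summary(cats)
  jsonlite::write_json(fig5, file.path(out_dir, "category_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  enr <- NULL
  de_tbl <- dplyr::bind_rows(tidy(de$resistant), tidy(de$susceptible))
  if (!is.null(config$go)) {
    ann <- stage("io", read_go_annotations(config$go, proteins))
    de_ids <- unique(de_tbl$protein_id[de_tbl$class != "ns"])
    enr <- stage("enrichment", go_enrichment(
      de_ids, ann, background_ids = proteins$protein_id, fdr_cut = p$fdr_cut))
    say("enrichment: %d terms at FDR <= %.3g", nrow(tidy(enr)), p$fdr_cut)
  } else {
    say("enrichment: no GO file configured, stage skipped")
  }

  if (isTRUE(config$physico)) {
    prof <- stage("physico", physico_profile(proteins))
    readr::write_tsv(prof, file.path(out_dir, "physico_profile.tsv"), progress = FALSE)
    say("physico: %d proteins profiled", nrow(prof))
  }

  paths <- write_results(de_tbl, if (is.null(enr)) NULL else tidy(enr),
                         out_dir, params = p)
  summary <- jsonlite::read_json(paths[["run_summary"]])
  summary$stage_tallies <- list(
    proteins_read = nrow(counts),
    proteins_retained = length(filt$retained_ids),
    de_resistant = glance(de$resistant)$n_de,
    de_susceptible = glance(de$susceptible)$n_de,
    categories = fig5,
    enriched_terms = if (is.null(enr)) NULL else nrow(tidy(enr)),
    enrichment_skipped = is.null(enr)
  )
  # tallies must reconcile with the written tables
  stopifnot(summary$stage_tallies$de_resistant + summary$stage_tallies$de_susceptible ==
              sum(de_tbl$class != "ns"))
  jsonlite::write_json(summary, paths[["run_summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(summary)
}

#' Three-group summary of differentially expressed proteins
#'
#' Renders a `response_categories` object as the fixed-key-order summary
#' used for cross-variety reporting: counts of up/down proteins specific to
#' each variety plus the overlap (with its discordant-direction count).
#'
#' @param categories A `response_categories` object.
#' @return A named list
#'   `list(resistant_only = list(up, down), overlap = list(total,
#'   discordant), susceptible_only = list(up, down))`.
#' @export
report_fig5_summary <- function(categories) {
  g <- glance(categories)
  list(
    resistant_only = list(up = g$resistant_only_up, down = g$resistant_only_down),
    overlap = list(total = g$overlap, discordant = g$overlap_discordant),
    susceptible_only = list(up = g$susceptible_only_up, down = g$susceptible_only_down)
  )
}
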