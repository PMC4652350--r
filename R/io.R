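#' Read a protein-level spectral-count table
#'
#' Reads a TSV whose first column holds protein identifiers and whose
#' remaining columns hold one sample each, with nonnegative integer spectral
#' counts (SpC). Empty cells mean the protein was not identified in that run
#' (shotgun runs sample only a fraction of the peptides present) and are
#' recorded as zero; one message reports how many cells were filled this way.
#'
#' @param path Path to a tab-separated file. The header row names the
#'   samples; the first column (any name) holds protein ids.
#' @return A tibble with a `protein_id` character column followed by one
#'   integer column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\ts1\ts2", "p1\t4\t0", "p2\t2\t1"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs a protein id column plus at least one sample column")
  names(raw)[1] <- "protein_id"
  if (anyDuplicated(raw$protein_id)) {
    dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
    abort(paste0("duplicate protein_id in count table: ", paste(head(dup, 5), collapse = ", ")))
  }
  n_missing <- 0L
  for (j in seq(2L, ncol(raw))) {
    cell <- raw[[j]]
    miss <- is.na(cell) | cell == ""
    n_missing <- n_missing + sum(miss)
    cell[miss] <- "0"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
      what <- if (!is.na(num[bad[1]]) && num[bad[1]] < 0) "negative count" else "non-integer count"
      abort(sprintf("%s '%s' at row '%s', column '%s'",
                    what, cell[bad[1]], raw$protein_id[bad[1]], names(raw)[j]))
    }
    raw[[j]] <- as.integer(num)
  }
  if (n_missing > 0)
    inform(sprintf("%d missing cells treated as SpC = 0 (not identified in that run)", n_missing))
  raw
}

#' Write a spectral-count (or NSpC) table
#'
#' @param counts Wide tibble as returned by [read_count_table()] or
#'   [nsaf_normalize()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

.varieties <- c("resistant", "susceptible")
.conditions <- c("cold", "control")

#' Read and validate an experimental design table
#'
#' The design maps each LC-MS/MS run (sample) to a variety
#' (`resistant` = cold-germination tolerant, `susceptible`), a condition
#' (`cold` treatment or `control`), and a biological replicate number.
#' The study design this package targets is 2 varieties x 2 conditions x
#' 3 biological replicates; groups with only 2 replicates are accepted with
#' a warning since the t-test needs at least two values per group.
#'
#' @param path Path to a TSV with columns `sample_id`, `variety`,
#'   `condition`, `replicate`.
#' @return A validated tibble with those four columns (`replicate` integer).
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  validate_design(d)
}

#' Validate a design tibble
#'
#' @param design Data frame with columns `sample_id`, `variety`,
#'   `condition`, `replicate`.
#' @return The design as a tibble, checked and with `replicate` as integer.
#' @export
validate_design <- function(design) {
  needed <- c("sample_id", "variety", "condition", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    abort(paste0("design lacks column(s): ", paste(missing_cols, collapse = ", ")))
  d <- tibble::as_tibble(design)[needed]
  d$replicate <- suppressWarnings(as.integer(d$replicate))
  if (anyDuplicated(d$sample_id))
    abort("duplicate sample_id in design")
  bad_var <- setdiff(unique(d$variety), .varieties)
  if (length(bad_var))
    abort(paste0("unknown variety label(s): ", paste(bad_var, collapse = ", "),
                 " (expected resistant/susceptible)"))
  bad_cond <- setdiff(unique(d$condition), .conditions)
  if (length(bad_cond))
    abort(paste0("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
                 " (expected cold/control)"))
  if (any(is.na(d$replicate)) || any(d$replicate < 1))
    abort("replicate must be a positive integer")
  key <- paste(d$variety, d$condition, d$replicate)
  if (anyDuplicated(key))
    abort(paste0("duplicate (variety, condition, replicate) triple: ",
                 key[duplicated(key)][1]))
  sizes <- dplyr::count(d, .data$variety, .data$condition)
  if (any(sizes$n < 2))
    abort("every (variety, condition) group needs at least 2 replicates")
  if (any(sizes$n == 2))
    warn("some groups have only 2 replicates; 3 are recommended")
  d
}

#' Write a design table
#'
#' @param design Design tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

# IUPAC one-letter amino acids plus ambiguity codes and selenocysteine
.aa_allowed <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","X","B","Z","U")

#' Read protein sequences from FASTA
#'
#' Record id is the first whitespace-delimited token of the header.
#' Sequences are upper-cased and a trailing `*` stop codon is stripped
#' before length (and downstream MW/pI) computation.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `protein_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  # read without alphabet restriction so invalid residues can be reported
  # with the offending record's id rather than a low-level parser error
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      abort(paste0("empty sequence for record '", ids[i], "'"))
    chars <- unique(strsplit(seqs[i], "")[[1]])
    bad <- setdiff(chars, c(.aa_allowed, "*"))
    if (length(bad))
      abort(paste0("invalid residue(s) ", paste(bad, collapse = ""),
                   " in record '", ids[i], "'"))
    if (grepl("\\*", seqs[i]))
      abort(paste0("internal stop codon '*' in record '", ids[i], "'"))
  }
  tibble::tibble(protein_id = ids, sequence = unname(seqs),
                 length = nchar(unname(seqs)))
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a flat GO annotation map
#'
#' Reads a TSV of `(protein_id, go_id[, namespace])` rows, as exported from
#' flat genome-annotation files. Annotations for proteins absent from
#' `proteins` are kept (with a warning) so the genome-wide background used
#' by enrichment stays annotation-wide, not experiment-wide.
#'
#' @param path Path to the TSV. A header row is detected by a `GO:`-less
#'   second field in row one.
#' @param proteins Optional tibble with a `protein_id` column (e.g. from
#'   [read_fasta()]) used only to warn about orphan annotations.
#' @return A tibble with columns `protein_id`, `go_id`, `namespace`
#'   (namespace is `NA` when the file has two columns).
#' @export
read_go_annotations <- function(path, proteins = NULL) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  has_header <- length(first) == 1 && !grepl("GO:", first)
  ann <- readr::read_tsv(path, col_names = has_header,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(ann) == 0) {
    return(tibble::tibble(protein_id = character(), go_id = character(),
                          namespace = character()))
  }
  if (ncol(ann) < 2) abort("GO annotation file needs at least 2 columns")
  names(ann)[1:2] <- c("protein_id", "go_id")
  if (ncol(ann) >= 3) names(ann)[3] <- "namespace" else ann$namespace <- NA_character_
  ann <- ann[c("protein_id", "go_id", "namespace")]
  bad <- !grepl("^GO:\\d{7}$", ann$go_id)
  if (any(bad))
    abort(paste0("malformed GO id '", ann$go_id[which(bad)[1]], "'"))
  if (!is.null(proteins)) {
    orphans <- setdiff(unique(ann$protein_id), proteins$protein_id)
    if (length(orphans))
      warn(sprintf("%d annotated proteins absent from the sequence set; kept in the genome background",
                   length(orphans)))
  }
  ann
}

#' Write differential-expression and enrichment results
#'
#' Writes deterministic TSV tables plus one JSON run summary whose tallies
#' equal the row counts of the tables, so reruns on the same inputs are
#' byte-identical.
#'
#' @param de Differential-record tibble (both varieties stacked), e.g.
#'   `dplyr::bind_rows(tidy(de_res), tidy(de_sus))`; may have zero rows.
#' @param enrichment Enrichment tibble (see [go_enrichment()]) or `NULL`.
#' @param out_dir Output directory, created if needed.
#' @param params Named list of parameters to embed in the summary.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(de, enrichment = NULL, out_dir, params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  de_cols <- c("protein_id", "variety", "mean_cold", "mean_control",
               "ratio", "p_value", "class")
  de <- tibble::as_tibble(de)
  for (cc in setdiff(de_cols, names(de))) de[[cc]] <- logical(0)
  de_path <- file.path(out_dir, "differential_expression.tsv")
  readr::write_tsv(de[de_cols], de_path, progress = FALSE)
  paths <- c(differential_expression = de_path)
  if (!is.null(enrichment)) {
    en_cols <- c("go_id", "description", "namespace", "k_input", "K_genome",
                 "p_value", "fdr")
    enrichment <- tibble::as_tibble(enrichment)
    for (cc in setdiff(en_cols, names(enrichment))) enrichment[[cc]] <- logical(0)
    en_path <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(enrichment[en_cols], en_path, progress = FALSE)
    paths <- c(paths, enrichment = en_path)
  }
  tally <- as.list(table(factor(de$class, levels = c("up", "down", "ns"))))
  summary <- list(
    parameters = params,
    n_differential_rows = nrow(de),
    class_counts = tally,
    n_enriched_terms = if (is.null(enrichment)) NA else nrow(enrichment)
  )
  js_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, js_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  paths <- c(paths, run_summary = js_path)
  invisible(paths)
}

# wide count/NSpC tibble -> numeric matrix (proteins x samples)
counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[-1])
  storage.mode(m) <- "double"
  rownames(m) <- counts$protein_id
  m
}

matrix_to_counts <- function(m) {
  tibble::as_tibble(m, rownames = "protein_id")
}
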