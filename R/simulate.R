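# Approximate amino-acid frequencies of a plant proteome, used when drawing
# random sequences; kept rich in D/E/K/R/H so pI computation is exercised.
.aa_freq <- c(A = .079, R = .052, N = .041, D = .053, C = .016, Q = .036,
              E = .062, G = .071, H = .023, I = .047, L = .089, K = .056,
              M = .024, F = .040, P = .048, S = .069, T = .052, W = .012,
              Y = .030, V = .066)

#' Simulation configuration for synthetic spectral-count experiments
#'
#' Defaults describe the study conditions the analysis targets: a
#' 2-variety x 2-condition x 3-replicate shotgun experiment on a few
#' thousand proteins, with run-to-run detection dropout ("analytical
#' incompleteness"), counts proportional to abundance x length under a
#' fixed per-run spectral budget, and planted cold/control fold changes in
#' a subset of proteins per variety.
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param length_law Log-normal parameters for residue length
#'   (`meanlog`, `sdlog`); defaults give a median around 320 residues.
#' @param abundance_law Log-normal parameters for relative abundance
#'   (`meanlog`, `sdlog`, and `cap_quantile`); the default `sdlog = 2`
#'   spans roughly 3-4 orders of magnitude, and abundances above the
#'   `cap_quantile` quantile are winsorized to it so the top of the
#'   proteome is a handful of comparably abundant proteins (as in a seed
#'   embryo, where storage and housekeeping proteins share the top ranks)
#'   rather than a single runaway species.
#' @param spectra_budget Total MS/MS spectra assigned per run (multinomial
#'   total), mimicking fixed sampling depth.
#' @param de_fraction Proportion of proteins with a planted cold-response
#'   fold change, per variety.
#' @param fold_law Planted fold magnitudes are log-uniform over
#'   `[min, max]`; direction (up/down) is symmetric.
#' @param overlap_fraction Share of each variety's planted-DE proteins
#'   also planted in the other variety (with an independently drawn fold,
#'   so discordant directions arise naturally).
#' @param dropout_tau Detection scale: a protein with expected count `mu`
#'   in a run is detected with probability `1 - exp(-mu / dropout_tau)`;
#'   larger values mean more dropout.
#' @param replicate_noise Log-normal `sdlog` of per-(protein, run)
#'   biological/technical abundance noise.
#' @param seed Single global seed; every stream in the generator derives
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       length_law = list(meanlog = log(320), sdlog = 0.5),
                       abundance_law = list(meanlog = 0, sdlog = 2,
                                            cap_quantile = 0.995),
                       spectra_budget = 50000,
                       de_fraction = 0.05,
                       fold_law = list(min = 2, max = 64),
                       overlap_fraction = 0.1,
                       dropout_tau = 1,
                       replicate_noise = 0.2,
                       seed = 1L) {
  if (n_proteins <= 0) abort("n_proteins must be > 0")
  if (spectra_budget <= 0) abort("spectra_budget must be > 0")
  for (p in c(de_fraction, overlap_fraction))
    if (p < 0 || p > 1) abort("proportions must lie in [0, 1]")
  if (length_law$sdlog < 0 || abundance_law$sdlog < 0 || replicate_noise < 0)
    abort("dispersion parameters must be >= 0")
  if (fold_law$min < 1 || fold_law$max < fold_law$min)
    abort("fold_law needs 1 <= min <= max")
  structure(list(n_proteins = as.integer(n_proteins), length_law = length_law,
                 abundance_law = abundance_law,
                 spectra_budget = as.integer(spectra_budget),
                 de_fraction = de_fraction, fold_law = fold_law,
                 overlap_fraction = overlap_fraction, dropout_tau = dropout_tau,
                 replicate_noise = replicate_noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default 2 x 2 x 3 experimental design
#'
#' @param n_replicates Replicates per (variety, condition) group.
#' @return A design tibble with `sample_id`, `variety`, `condition`,
#'   `replicate`.
#' @export
default_design <- function(n_replicates = 3) {
  d <- tidyr::expand_grid(variety = .varieties, condition = .conditions,
                          replicate = seq_len(n_replicates))
  d$sample_id <- sprintf("%s_%s_%d", substr(d$variety, 1, 3), d$condition,
                         d$replicate)
  d[c("sample_id", "variety", "condition", "replicate")]
}

#' Simulate a synthetic proteome with ground truth
#'
#' Draws protein lengths and baseline relative abundances from the
#' configured log-normal laws, plants per-variety fold changes, and
#' (optionally) generates random amino-acid sequences consistent with the
#' lengths for the physicochemical module.
#'
#' @param config A [sim_config()].
#' @param sequences Generate random sequences (default `TRUE`).
#' @return A list with `proteins` (tibble: `protein_id`, `sequence`,
#'   `length`) and `truth` (tibble: `protein_id`, `length`, `abundance`,
#'   `fold_resistant`, `fold_susceptible`; folds are 1 for unaffected
#'   proteins).
#' @export
simulate_proteome <- function(config = sim_config(), sequences = TRUE) {
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SYN_P%05d", seq_len(n))
  lens <- pmax(50L, as.integer(round(rlnorm(n, config$length_law$meanlog,
                                            config$length_law$sdlog))))
  abund <- rlnorm(n, config$abundance_law$meanlog, config$abundance_law$sdlog)
  capq <- config$abundance_law$cap_quantile %||% 1
  if (capq < 1) abund <- pmin(abund, stats::quantile(abund, capq))
  draw_fold <- function(m) {
    mag <- exp(runif(m, log(config$fold_law$min), log(config$fold_law$max)))
    dir <- sample(c(1, -1), m, replace = TRUE)
    ifelse(dir > 0, mag, 1 / mag)
  }
  n_de <- round(config$de_fraction * n)
  n_ov <- round(config$overlap_fraction * n_de)
  pool <- sample(n)
  ov_idx <- pool[seq_len(n_ov)]
  res_idx <- c(ov_idx, pool[seq(n_ov + 1, length.out = n_de - n_ov)])
  sus_idx <- c(ov_idx, pool[seq(n_de + 1, length.out = n_de - n_ov)])
  fold_res <- rep(1, n); fold_sus <- rep(1, n)
  fold_res[res_idx] <- draw_fold(length(res_idx))
  fold_sus[sus_idx] <- draw_fold(length(sus_idx))
  if (capq < 1) {
    # a protein cannot exceed the ceiling share of sampled spectra, so
    # fold-ups saturate at the cap; the realized fold is the ground truth
    cap <- max(abund)
    fold_res <- pmin(fold_res, cap / abund)
    fold_sus <- pmin(fold_sus, cap / abund)
  }
  seqs <- if (sequences) {
    letters_drawn <- sample(names(.aa_freq), sum(lens), replace = TRUE,
                            prob = .aa_freq)
    vapply(split(letters_drawn, rep(seq_len(n), lens)), paste0,
           character(1), collapse = "")
  } else rep(NA_character_, n)
  list(
    proteins = tibble::tibble(protein_id = ids, sequence = unname(seqs),
                              length = lens),
    truth = tibble::tibble(protein_id = ids, length = lens, abundance = abund,
                           fold_resistant = fold_res,
                           fold_susceptible = fold_sus)
  )
}

#' Simulate a spectral-count experiment from a proteome and design
#'
#' For each run, effective abundance is baseline x planted fold (cold runs
#' of an affected variety only) x per-protein log-normal replicate noise;
#' spectra are assigned multinomially with sampling weight proportional to
#' abundance x length and a fixed total of `spectra_budget`; finally,
#' per-protein detection dropout zeroes proteins the run failed to sample,
#' with detection probability `1 - exp(-expected_count / dropout_tau)`.
#'
#' @param proteome Output of [simulate_proteome()] (list with `truth`).
#' @param design Design tibble covering 2 varieties x 2 conditions.
#' @param config The same [sim_config()].
#' @return A wide count tibble (`protein_id` + one integer column per
#'   sample), ids aligned with the truth table.
#' @export
simulate_experiment <- function(proteome, design, config = sim_config()) {
  truth <- proteome$truth
  design <- validate_design(design)
  if (nrow(truth) != config$n_proteins)
    abort("proteome and config disagree on n_proteins")
  # independent stream, still derived from the single global seed
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  m <- matrix(0L, n, nrow(design),
              dimnames = list(truth$protein_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    fold <- if (design$condition[j] == "cold") {
      if (design$variety[j] == "resistant") truth$fold_resistant else truth$fold_susceptible
    } else rep(1, n)
    eff <- truth$abundance * fold *
      rlnorm(n, -config$replicate_noise^2 / 2, config$replicate_noise)
    w <- eff * truth$length
    prob <- w / sum(w)
    counts <- rmultinom(1, config$spectra_budget, prob)[, 1]
    expected <- config$spectra_budget * prob
    detected <- rbinom(n, 1L, 1 - exp(-expected / config$dropout_tau))
    m[, j] <- as.integer(counts * detected)
  }
  matrix_to_counts(m)
}

#' Simulate a complete study (proteome + experiment) in one call
#'
#' @inheritParams simulate_experiment
#' @param design Design tibble; defaults to [default_design()].
#' @param sequences Generate random sequences (default `FALSE`; the counts
#'   pipeline only needs lengths).
#' @return List with `proteins`, `truth`, `counts`, `design`.
#' @export
simulate_study <- function(config = sim_config(), design = default_design(),
                           sequences = FALSE) {
  prot <- simulate_proteome(config, sequences = sequences)
  counts <- simulate_experiment(prot, design, config)
  c(prot, list(counts = counts, design = design))
}

#' Export a simulated study as an on-disk toy dataset
#'
#' Writes `counts.tsv`, `design.tsv`, `proteins.fasta`, `go_annotations.tsv`
#' and `truth.tsv` into a directory, forming a self-contained fixture the
#' reading functions accept. The GO map assigns each protein a handful of
#' random terms and deliberately annotates every planted-DE protein (plus a
#' small background fraction) with one "stress response" term, so that term
#' is maximally enriched in the true DE set.
#'
#' @param study Output of [simulate_study()] (needs sequences for FASTA).
#' @param out_dir Output directory, created if needed.
#' @param config The same [sim_config()] (drives the GO-map stream).
#' @param n_go_terms Size of the random background term pool.
#' @return Named character vector of written paths, invisibly.
#' @export
export_fixture <- function(study, out_dir, config = sim_config(),
                           n_go_terms = 40) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (any(is.na(study$proteins$sequence)))
    abort("fixture export needs sequences; rerun with sequences = TRUE")
  set.seed(config$seed + 2L)
  truth <- study$truth
  n <- nrow(truth)
  pool <- sprintf("GO:%07d", seq_len(n_go_terms) * 10L)
  ns_pool <- rep(c("biological_process", "molecular_function",
                   "cellular_component"), length.out = n_go_terms)
  per_protein <- pmin(stats::rpois(n, 2), n_go_terms)
  ann <- purrr::map_dfr(seq_len(n), function(i) {
    k <- per_protein[i]
    if (k == 0) return(tibble::tibble())
    idx <- sample(n_go_terms, k)
    tibble::tibble(protein_id = truth$protein_id[i], go_id = pool[idx],
                   namespace = ns_pool[idx])
  })
  planted <- truth$protein_id[truth$fold_resistant != 1 | truth$fold_susceptible != 1]
  extra <- sample(setdiff(truth$protein_id, planted),
                  max(1, round(0.05 * (n - length(planted)))))
  stress_term <- "GO:0006950"  # response to stress
  ann <- dplyr::bind_rows(ann, tibble::tibble(
    protein_id = c(planted, extra), go_id = stress_term,
    namespace = "biological_process"))
  ann <- dplyr::arrange(ann, .data$protein_id, .data$go_id)
  paths <- c(
    counts = write_count_table(study$counts, file.path(out_dir, "counts.tsv")),
    design = write_design(study$design, file.path(out_dir, "design.tsv")),
    fasta = write_fasta(study$proteins, file.path(out_dir, "proteins.fasta")),
    go = {
      p <- file.path(out_dir, "go_annotations.tsv")
      readr::write_tsv(ann, p, progress = FALSE)
      p
    },
    truth = {
      p <- file.path(out_dir, "truth.tsv")
      readr::write_tsv(truth, p, progress = FALSE)
      p
    }
  )
  invisible(paths)
}

#' Configuration of the packaged toy dataset
#'
#' A scaled-down study (150 proteins, 3000 spectra per run) with the same
#' statistical structure as the full defaults, small enough to ship as
#' plain-text files under `inst/extdata/fixture/` and to re-generate
#' byte-identically in tests.
#'
#' @return A [sim_config()].
#' @export
fixture_config <- function() {
  sim_config(n_proteins = 150,
             length_law = list(meanlog = log(250), sdlog = 0.5),
             spectra_budget = 3000, seed = 42L)
}
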