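# Independent oracles and small in-code fixtures shared across tests.

# hypergeometric upper tail by direct ratio-of-binomials arithmetic
# (plain choose(), no logs) -- independent of the log-space implementation
oracle_hyper_direct <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hypergeometric upper tail by exhaustive enumeration of every n-subset of
# a background with K marked items; only sane for tiny N
oracle_hyper_enum <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# textbook pooled-variance two-sample t, evaluated from the closed form
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tt), df = na + nb - 2)
}

# small wide count tibble from a named list of per-protein count vectors
make_counts <- function(rows, sample_ids) {
  m <- do.call(rbind, rows)
  colnames(m) <- sample_ids
  tibble::as_tibble(m) |>
    dplyr::mutate(protein_id = names(rows), .before = 1)
}

mini_design <- function(n_rep = 3) riceprot::default_design(n_rep)

fixture_dir <- function() {
  d <- system.file("extdata", "fixture", package = "riceprot")
  if (!nzchar(d)) stop("packaged fixture not found")
  d
}

write_tsv_tmp <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
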