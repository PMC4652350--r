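test_that("hypergeometric upper tail matches direct arithmetic and enumeration", {
  # P(X >= 3) with K = 5 marked of N = 20, drawing n = 5:
  # sum_{j=3..5} C(5,j) C(15,5-j) / C(20,5) = 1126/15504
  expect_equal(hypergeom_upper_tail(3, 5, 5, 20), 1126 / 15504, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 5, 5, 20), oracle_hyper_enum(3, 5, 5, 20),
               tolerance = 1e-12)

  expect_equal(hypergeom_upper_tail(0, 5, 5, 20), 1)
  # K = N: every draw is fully marked
  expect_equal(hypergeom_upper_tail(4, 10, 4, 10), 1)
  expect_error(hypergeom_upper_tail(6, 5, 5, 20), "k <= min")

  # random small instances against full subset enumeration
  set.seed(17)
  for (i in 1:25) {
    N <- sample(4:12, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N), oracle_hyper_enum(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up closed form and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # nondecreasing when sorted by p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("go_enrichment computes exact toy probabilities and ranks planted terms", {
  # 6 annotated proteins, 4 in the input list; term A annotates 3, all in
  # the list: p = C(3,3) C(3,1) / C(6,4) = 3/15 = 0.2
  ann <- tibble::tibble(
    protein_id = c(paste0("p", 1:3), paste0("p", 1:6)),
    go_id = c(rep("GO:0000001", 3), rep("GO:0000002", 6)),
    namespace = "biological_process")
  enr <- go_enrichment(paste0("p", 1:4), ann, paste0("p", 1:6), fdr_cut = 1)
  terms <- enr$all_terms
  expect_equal(terms$p_value[terms$go_id == "GO:0000001"], 0.2, tolerance = 1e-12)
  # term covering the whole universe: n = k, p = 1
  expect_equal(terms$p_value[terms$go_id == "GO:0000002"], 1)
  expect_equal(terms$k_input[terms$go_id == "GO:0000001"], 3)
  expect_equal(terms$K_genome[terms$go_id == "GO:0000001"], 3)
  expect_true(all(terms$fdr >= terms$p_value))

  # input = all annotated proteins: every term has p = 1
  enr_all <- go_enrichment(paste0("p", 1:6), ann, paste0("p", 1:6), fdr_cut = 1)
  expect_true(all(enr_all$all_terms$p_value == 1))

  # orphan input proteins are warned about and excluded
  expect_warning(go_enrichment(c("p1", "p2", "p3", "zz"), ann, paste0("p", 1:6),
                               fdr_cut = 1), "absent from the background")
  expect_error(go_enrichment(character(0), ann, paste0("p", 1:6)), "empty")
})

test_that("adding an annotated protein to the input never raises the term's p", {
  set.seed(23)
  prots <- paste0("p", 1:30)
  ann <- tibble::tibble(
    protein_id = c(sample(prots, 8), prots),
    go_id = c(rep("GO:0000010", 8), rep("GO:0000099", 30)),
    namespace = "biological_process")
  in_term <- unique(ann$protein_id[ann$go_id == "GO:0000010"])
  de <- sample(setdiff(prots, in_term), 5)
  p_before <- go_enrichment(de, ann, prots, fdr_cut = 1)$all_terms
  p_before <- p_before$p_value[p_before$go_id == "GO:0000010"]
  de2 <- c(de, in_term[1])
  p_after <- go_enrichment(de2, ann, prots, fdr_cut = 1)$all_terms
  p_after <- p_after$p_value[p_after$go_id == "GO:0000010"]
  expect_lte(p_after, p_before)
})

test_that("enrichment output carries the report columns in order", {
  ann <- tibble::tibble(protein_id = paste0("p", 1:10),
                        go_id = rep(c("GO:0000001", "GO:0000002"), 5),
                        namespace = rep(c("biological_process", "molecular_function"), 5))
  enr <- go_enrichment(paste0("p", 1:4), ann, paste0("p", 1:10), fdr_cut = 1)
  expect_equal(names(tidy(enr)),
               c("go_id", "description", "namespace", "k_input", "K_genome",
                 "p_value", "fdr"))
  expect_equal(glance(enr)$n_terms_tested, nrow(enr$all_terms))
})
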