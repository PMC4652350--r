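test_that("ln transform is the elementwise natural log and refuses nonpositives", {
  d <- mini_design(1)
  nspc <- make_counts(list(a = c(1, exp(-1), exp(2), 1)), d$sample_id)
  ln <- ln_transform(nspc)
  expect_equal(unlist(ln[-1], use.names = FALSE), c(0, -1, 2, 0))
  bad <- nspc; bad[[2]][1] <- 0
  expect_error(ln_transform(bad), "nonpositive")
})

test_that("ttest_ln agrees with the closed-form pooled t to 1e-10", {
  # worked example with known group means/variances
  a <- c(0.1, 0.2, 0.3); b <- c(1.1, 1.2, 1.3)
  expect_equal(as.numeric(ttest_ln(a, b)), oracle_t_pooled(a, b), tolerance = 1e-10)

  set.seed(13)
  for (i in 1:200) {
    a <- rnorm(3); b <- rnorm(3, mean = sample(c(0, 2), 1))
    p <- as.numeric(ttest_ln(a, b))
    expect_equal(p, oracle_t_pooled(a, b), tolerance = 1e-10)
    # symmetry in the group order
    expect_equal(as.numeric(ttest_ln(b, a)), p, tolerance = 1e-12)
  }
})

test_that("ttest_ln handles degenerate zero-variance groups deterministically", {
  same <- c(1, 1, 1)
  expect_equal(as.numeric(ttest_ln(same, same)), 1)
  expect_true(attr(ttest_ln(same, same), "degenerate"))
  expect_equal(as.numeric(ttest_ln(same, c(2, 2, 2))), 0)
  expect_error(ttest_ln(1, c(1, 2)), "at least 2")
})

test_that("fold change is the mean ratio with reciprocity", {
  expect_equal(fold_change(2, 1), 2)
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(0.4, 0.8) * fold_change(0.8, 0.4), 1)
  expect_error(fold_change(0, 1), "> 0")
})

test_that("classification applies the alpha and inclusive 2-fold rules", {
  rec <- tibble::tibble(ratio = c(3, 0.4, 3, 2, 0.5, 1.9),
                        p_value = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01))
  cl <- classify(rec)$class
  expect_equal(as.character(cl), c("up", "down", "ns", "up", "down", "ns"))
  expect_error(classify(rec, alpha = 1.2), "alpha")
  expect_error(classify(rec, fold = 1), "fold")

  # threshold monotonicity: raising fold never adds DE calls
  set.seed(3)
  rec2 <- tibble::tibble(ratio = exp(rnorm(100)), p_value = runif(100))
  de2 <- classify(rec2, fold = 2)$class != "ns"
  de4 <- classify(rec2, fold = 4)$class != "ns"
  expect_true(all(which(de4) %in% which(de2)))
  # idempotence
  expect_equal(classify(classify(rec2))$class, classify(rec2)$class)
})

test_that("differential_expression ties the pieces together per variety", {
  d <- mini_design()
  set.seed(42)
  # protein 'up8' planted 8-fold up in resistant cold; 'null' flat
  rows <- list(
    up8 = c(80, 82, 78, 10, 11, 9, 10, 10, 11, 10, 9, 10),
    null = c(50, 52, 49, 50, 51, 50, 49, 50, 52, 50, 51, 50),
    filler = c(20, 24, 18, 21, 19, 23, 22, 20, 19, 21, 23, 20)
  )
  counts <- make_counts(rows, d$sample_id)
  nspc <- nsaf_normalize(add_pseudocount(counts), setNames(c(300, 300, 300), names(rows)))
  de <- differential_expression(nspc, d, "resistant")
  rec <- tidy(de)
  expect_equal(as.character(rec$class[rec$protein_id == "up8"]), "up")
  expect_equal(as.character(rec$class[rec$protein_id == "null"]), "ns")
  expect_gt(rec$ratio[rec$protein_id == "up8"], 2)
  g <- glance(de)
  expect_equal(g$n_tested, 3)
  expect_equal(g$n_up, sum(rec$class == "up"))
  expect_s3_class(ggplot2::autoplot(de), "ggplot")
})

test_that("response categorization partitions DE sets and flags discordance", {
  mk <- function(ids, classes, variety) tibble::tibble(
    protein_id = ids, variety = variety, mean_cold = 1, mean_control = 1,
    ratio = ifelse(classes == "up", 3, ifelse(classes == "down", 0.3, 1)),
    p_value = ifelse(classes == "ns", 0.9, 0.01), class = classes)
  r <- mk(c("a", "b", "c", "x"), c("up", "down", "up", "ns"), "resistant")
  s <- mk(c("c", "d", "x"), c("down", "down", "ns"), "susceptible")
  cats <- categorize_responses(r, s)
  expect_setequal(cats$resistant_only, c("a", "b"))
  expect_setequal(cats$susceptible_only, "d")
  expect_equal(cats$overlap, "c")
  # three sets pairwise disjoint
  expect_equal(length(intersect(cats$resistant_only, cats$susceptible_only)), 0)
  expect_equal(length(intersect(cats$overlap, c(cats$resistant_only, cats$susceptible_only))), 0)
  # c is up in resistant, down in susceptible: discordant
  expect_true(cats$records$discordant[cats$records$protein_id == "c"])
  g <- glance(cats)
  expect_equal(g$resistant_only_up + g$resistant_only_down, g$resistant_only)
  expect_equal(g$overlap_discordant, 1)

  # disjoint DE sets: empty overlap
  cats2 <- categorize_responses(mk("a", "up", "resistant"), mk("b", "up", "susceptible"))
  expect_equal(length(cats2$overlap), 0)
  expect_s3_class(ggplot2::autoplot(cats), "ggplot")
})

test_that("fig-5 style summary preserves tallies in fixed key order", {
  mk <- function(ids, classes, variety) tibble::tibble(
    protein_id = ids, variety = variety, mean_cold = 1, mean_control = 1,
    ratio = ifelse(classes == "up", 3, 0.3),
    p_value = 0.01, class = classes)
  cats <- categorize_responses(mk(c("a", "b"), c("up", "down"), "resistant"),
                               mk(c("c"), "up", "susceptible"))
  s <- report_fig5_summary(cats)
  expect_equal(names(s), c("resistant_only", "overlap", "susceptible_only"))
  expect_equal(s$resistant_only, list(up = 1L, down = 1L))
  expect_equal(s$susceptible_only$up, 1L)

  empty <- categorize_responses(mk("a", "up", "resistant")[0, ],
                                mk("c", "up", "susceptible")[0, ])
  s0 <- report_fig5_summary(empty)
  expect_equal(s0$overlap$total, 0L)
  expect_equal(s0$resistant_only$up + s0$resistant_only$down, 0L)
})
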