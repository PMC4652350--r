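test_that("replicate filter retains a protein iff some group passes in all replicates", {
  d <- mini_design()
  # order groups as in design: resistant cold, resistant control, susceptible cold, susceptible control
  counts <- make_counts(list(
    keep_one_group = c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    drop_everywhere = c(1, 5, 5, 1, 5, 5, 1, 5, 5, 1, 5, 5),
    keep_all = rep(3, 12)
  ), d$sample_id)
  rep_ <- apply_replicate_filter(counts, d, min_spc = 2)
  expect_setequal(rep_$retained_ids, c("keep_one_group", "keep_all"))
  expect_equal(rep_$dropped$protein_id, "drop_everywhere")
  # retained and dropped partition the input
  expect_setequal(c(rep_$retained_ids, rep_$dropped$protein_id), counts$protein_id)

  # vacuous filter
  expect_equal(length(apply_replicate_filter(counts, d, min_spc = 0)$retained_ids), 3)
  expect_error(apply_replicate_filter(counts, d, min_spc = -1), "nonnegative")

  # stricter scopes
  expect_equal(apply_replicate_filter(counts, d, scope = "all-groups")$retained_ids,
               "keep_all")
  expect_setequal(apply_replicate_filter(counts, d, scope = "per-comparison")$retained_ids,
                  "keep_all")
})

test_that("raising min_spc never grows the retained set (monotonicity)", {
  set.seed(5)
  d <- mini_design()
  counts <- make_counts(setNames(lapply(1:50, function(i)
    rpois(12, sample(0:6, 1))), paste0("p", 1:50)), d$sample_id)
  prev <- apply_replicate_filter(counts, d, min_spc = 0)$retained_ids
  for (ms in 1:5) {
    cur <- apply_replicate_filter(counts, d, min_spc = ms)$retained_ids
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pseudocount replaces only zeros, only over retained proteins", {
  d <- mini_design(1)
  counts <- make_counts(list(a = c(0, 3, 0, 2), b = c(1, 1, 1, 1)), d$sample_id)
  adj <- add_pseudocount(counts, c("a", "b"), epsilon = 0.1)
  expect_equal(unlist(adj[adj$protein_id == "a", -1], use.names = FALSE),
               c(0.1, 3, 0.1, 2))
  expect_equal(unlist(adj[adj$protein_id == "b", -1], use.names = FALSE),
               rep(1, 4))
  adj5 <- add_pseudocount(counts, "a", epsilon = 0.5)
  expect_equal(adj5[[2]][1], 0.5)
  expect_equal(nrow(adj5), 1)
  expect_error(add_pseudocount(counts, "a", epsilon = 0), "> 0")
  expect_error(add_pseudocount(counts, character(0)), "empty")
})

test_that("NSAF normalization is exact on hand-computed cases", {
  d <- mini_design(1)[1, ]
  counts <- tibble::tibble(protein_id = c("A", "B"), s1 = c(4, 2))
  names(counts)[2] <- d$sample_id[1]
  nspc <- nsaf_normalize(counts, c(A = 100, B = 200))
  # SAF: 0.04 and 0.01; total 0.05
  expect_equal(nspc[[2]], c(0.8, 0.2))

  # single protein normalizes to 1
  one <- nsaf_normalize(counts[1, ], c(A = 123))
  expect_equal(one[[2]], 1)

  # scale invariance: doubling all SpC in a sample leaves NSpC unchanged
  doubled <- counts; doubled[[2]] <- doubled[[2]] * 2
  expect_equal(nsaf_normalize(doubled, c(A = 100, B = 200))[[2]], nspc[[2]])

  expect_error(nsaf_normalize(counts, c(A = 100)), "no length for")
})

test_that("NSAF columns sum to one and are row-order equivariant", {
  set.seed(9)
  d <- mini_design()
  counts <- make_counts(setNames(lapply(1:30, function(i)
    rpois(12, 5) + 1), paste0("p", 1:30)), d$sample_id)
  lens <- setNames(sample(100:500, 30), paste0("p", 1:30))
  nspc <- nsaf_normalize(counts, lens)
  expect_true(all(abs(colSums(nspc[-1]) - 1) < 1e-9))

  perm <- counts[sample(30), ]
  nspc_p <- nsaf_normalize(perm, lens)
  reord <- nspc_p[match(nspc$protein_id, nspc_p$protein_id), ]
  expect_equal(as.data.frame(reord), as.data.frame(nspc))
})

test_that("replicate R^2 is squared Pearson correlation within groups", {
  d <- mini_design()
  base <- c(5, 10, 20, 40)
  rows <- lapply(seq_along(base), function(i) rep(base[i], 12))
  counts <- make_counts(setNames(rows, paste0("p", 1:4)), d$sample_id)
  nspc <- nsaf_normalize(counts, setNames(rep(100, 4), paste0("p", 1:4)))
  r2 <- replicate_r2(nspc, d)
  # identical replicate columns: R^2 = 1 everywhere
  expect_true(all(abs(r2$r2 - 1) < 1e-12))
  expect_equal(nrow(r2), 4 * choose(3, 2))

  # anti-proportional vectors still give R^2 = 1 (sign is squared away)
  m <- tibble::tibble(protein_id = c("x", "y", "z"))
  for (s in d$sample_id) m[[s]] <- c(1, 2, 3)
  m[[d$sample_id[1]]] <- c(-1, -2, -3) + 4  # = (3,2,1), perfectly anticorrelated
  r2b <- replicate_r2(m, d)
  expect_true(all(abs(r2b$r2 - 1) < 1e-12))

  # constant vector: missing with warning (one per affected pair)
  cm <- m; cm[[d$sample_id[2]]] <- c(2, 2, 2)
  w <- testthat::capture_warnings(r2c <- replicate_r2(cm, d))
  expect_match(w, "undefined", all = TRUE)
  expect_equal(sum(is.na(r2c$r2)), 2)
})
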