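test_that("vocabularies have the documented node sets", {
  si <- node_vocabulary("si")
  expect_equal(nrow(si), 23)
  expect_equal(sum(si$kind == "ordinal"), 19)
  expect_setequal(si$name[si$kind == "binary"],
                  c("lifetime_SA", "MaDE", "gender_female",
                    "institution_hospital"))
  made <- node_vocabulary("made")
  expect_equal(nrow(made), 21)
  expect_false("MaDE" %in% made$name)
  expect_false("lifetime_SA" %in% made$name)
})

test_that("restrict_vocabulary drops nodes and rejects non-members", {
  si <- node_vocabulary("si")
  ab <- restrict_vocabulary(si, "PHQ_9")
  expect_equal(nrow(ab), 22)
  expect_false("PHQ_9" %in% ab$name)
  expect_equal(restrict_vocabulary(si, character()), si)
  expect_error(restrict_vocabulary(si, "PHQ_99"),
               class = "ginscreen_vocab_error")
  expect_error(restrict_vocabulary(si, si$name),
               class = "ginscreen_vocab_error")
})

test_that("edge matrix retains duplicated columns and honours threshold 0", {
  v <- toy_vocab(3, 0)
  tab <- data.frame(o1 = c(1, 2, 3, 4, 4, 3), o2 = c(1, 2, 3, 4, 4, 3),
                    o3 = c(4, 3, 1, 2, 1, 2))
  e <- fit_edge_matrix(tab, v, threshold = 0.99)
  expect_equal(e["o1", "o2"], 1.0)
  e0 <- fit_edge_matrix(tab, v, threshold = 0)
  expect_true(all(diag(e0) == 0))
  expect_true(all(e0[upper.tri(e0)] != 0))
  expect_equal(unclass(e0), t(unclass(e0)), ignore_attr = TRUE)
})

test_that("Spearman edge weights match the hand rank formula", {
  x <- c(1, 2, 3, 4, 4, 3); y <- c(1, 2, 3, 4, 3, 4)
  v <- toy_vocab(2, 0)
  tab <- data.frame(o1 = x, o2 = y)
  e <- fit_edge_matrix(tab, v, threshold = 0)
  rho_hand <- cor(rank(x), rank(y))   # Pearson on midranks
  expect_equal(e["o1", "o2"], rho_hand, tolerance = 1e-12)
  e6 <- fit_edge_matrix(tab, v, threshold = 0.6)
  expect_equal(e6["o1", "o2"] != 0, abs(rho_hand) >= 0.6)
})

test_that("constant columns zero out with a warning", {
  v <- toy_vocab(2, 0)
  tab <- data.frame(o1 = rep(2, 8), o2 = c(1:4, 1:4))
  expect_warning(e <- fit_edge_matrix(tab, v, threshold = 0),
                 "constant")
  expect_equal(e["o1", "o2"], 0)
})

test_that("edge invariants hold on random tables; sparsity is threshold-monotone", {
  set.seed(31)
  for (i in 1:5) {
    v <- toy_vocab(5, 0)
    tab <- as.data.frame(matrix(sample(1:4, 200, TRUE), 40, 5))
    names(tab) <- v$name
    prev <- Inf
    for (thr in c(0, 0.2, 0.5, 0.9)) {
      e <- fit_edge_matrix(tab, v, threshold = thr)
      expect_equal(unclass(e), t(unclass(e)), ignore_attr = TRUE)
      expect_true(all(diag(e) == 0))
      nz <- abs(e[e != 0])
      if (length(nz)) expect_true(all(nz >= thr))
      n_edges <- sum(e != 0)
      expect_lte(n_edges, prev)
      prev <- n_edges
    }
  }
})

test_that("one-hot encoding follows the slot conventions", {
  v <- toy_vocab(2, 2)
  e <- toy_edges(v)
  row <- data.frame(o1 = 4L, o2 = 1L, b1 = 1L, b2 = 0L, acute_SI = 1L)
  g <- encode_subject(row, v, e)
  expect_equal(g$features["o1", ], c(0, 0, 0, 1, 0, 0))
  expect_equal(g$features["b1", ], c(0, 0, 0, 0, 0, 1))
  expect_equal(g$features["b2", ], c(0, 0, 0, 0, 1, 0))
  expect_equal(rowSums(g$features), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sum(g$features), 4)   # one 1 per active node
  expect_equal(g$label, 1L)
})

test_that("encoding demands MaDE (directing to pseudo-labeling) and a matching edge hash", {
  v <- node_vocabulary("si")
  co <- toy_cohort(20)
  coder <- fit_quartile_coder(co)
  cq <- apply_quartile_coder(coder, co)
  err <- expect_error(ginscreen:::node_codes(cq, v),
                      class = "ginscreen_missing_made")
  expect_match(conditionMessage(err), "pseudo")
  cq$MaDE <- 0L
  e_other <- toy_edges(toy_vocab(2, 1))
  expect_error(encode_subjects(cq, v, e_other),
               class = "ginscreen_vocab_error")
})

test_that("subjects encoded against one edge matrix share adjacency exactly", {
  v <- node_vocabulary("si")
  co <- toy_cohort(30)
  coder <- fit_quartile_coder(co)
  cq <- apply_quartile_coder(coder, co)
  cq$MaDE <- rbinom(30, 1, 0.5)
  e <- suppressWarnings(fit_edge_matrix(cq, v, threshold = 0.3))
  g1 <- encode_subject(cq[1, ], v, e)
  g2 <- encode_subject(cq[2, ], v, e)
  expect_identical(g1$edges, g2$edges)
})

test_that("edge matrices round-trip through TSV + sidecar", {
  v <- toy_vocab(3, 1)
  set.seed(8)
  tab <- as.data.frame(matrix(sample(1:4, 120, TRUE), 30, 4))
  names(tab) <- v$name
  tab$b1 <- rbinom(30, 1, 0.5)
  e <- fit_edge_matrix(tab, v, threshold = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_matrix(e, path)
  back <- read_edge_matrix(path)
  expect_equal(unclass(back), unclass(e), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "threshold"), attr(e, "threshold"))
  expect_equal(attr(back, "vocab_hash"), attr(e, "vocab_hash"))
})
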