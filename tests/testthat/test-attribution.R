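raw_attention <- function(m, vocab) {
  rownames(m) <- c(paste0("level_", 1:4), "binary_0", "binary_1")
  colnames(m) <- vocab$name
  structure(m, class = c("attention_matrix", "matrix"),
            normalization = "raw", vocab = vocab)
}

test_that("row-wise normalization rescales level rows by their max over ordinal nodes", {
  v <- toy_vocab(3, 1)
  m <- matrix(0, 6, 4)
  m[1, 1:3] <- c(2, -4, 1)
  m[2, 1:3] <- c(1, 0.5, -0.25)
  m[3, 1:3] <- c(3, 1, 2); m[4, 1:3] <- c(-1, -2, 0.5)
  att <- raw_attention(m, v)
  rw <- normalize_attention(att, "row-wise")
  expect_equal(unname(rw[1, 1:3]), c(0.5, -1, 0.25))
  expect_true(all(vapply(1:4, function(r) max(abs(rw[r, 1:3])), 0) == 1))
  # signs never change
  expect_true(all(sign(rw[, 1:3]) == sign(m[1:4, 1:3])))
  # idempotent in its own mode
  expect_identical(normalize_attention(rw, "row-wise"), rw)
})

test_that("L1-column normalization tops out at exactly 1 and preserves order", {
  v <- toy_vocab(3, 1)
  m <- matrix(0, 6, 4)
  m[1:4, 1] <- c(1, 1, 0.5, 0.5)     # L1 = 3
  m[1:4, 2] <- c(2, 2, 1, 1)         # L1 = 6
  m[1:4, 3] <- c(0.5, 0.5, 0.5, 0.5) # L1 = 2
  att <- raw_attention(m, v)
  l1 <- normalize_attention(att, "l1-column")
  expect_equal(unname(l1[1, ]), c(0.5, 1, 1 / 3), tolerance = 1e-12)
  expect_equal(names(which.max(l1[1, ])), "o2")
  raw_l1 <- colSums(abs(m[1:4, 1:3]))
  expect_equal(order(l1[1, ]), order(raw_l1))
})

test_that("column-wise normalization min-max scales binary columns", {
  v <- toy_vocab(2, 2)
  m <- matrix(0, 6, 4)
  m[5:6, 3] <- c(-1, 3)
  m[5:6, 4] <- c(2, 2)    # constant -> warning, left alone
  att <- raw_attention(m, v)
  expect_warning(cw <- normalize_attention(att, "column-wise"), "constant")
  expect_equal(unname(cw[, 3]), c(0, 1))
})

test_that("population attention of a linear model recovers the classifier weights", {
  v <- toy_vocab(2, 1)
  e <- toy_edges(v)
  w <- rnorm(6)
  cfg <- gin_config(n_layers = 1, identity_mlp = TRUE, epochs = 1)
  m <- gin_init(cfg, v, e, seed = 1)
  m$w <- w; m$b <- 0
  set.seed(2)
  slots <- random_slots(40, v)
  labels <- rep(c(0L, 1L), 20)
  g <- toy_graphs(slots, v, e, labels)
  att <- population_attention(m, g)
  for (node in 1:3) expect_equal(unname(att[, node]), w, tolerance = 1e-10)
  # duplicating the subject set leaves the mean unchanged
  g2 <- toy_graphs(rbind(slots, slots), v, e, rep(labels, 2))
  expect_equal(unclass(population_attention(m, g2)), unclass(att),
               tolerance = 1e-12, ignore_attr = TRUE)
  # the linear model's gradient is subject-independent, so subject-set
  # choices agree on the values
  att_all <- population_attention(m, g, subjects = "all")
  expect_equal(unclass(att_all), unclass(att), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(population_attention(m, toy_graphs(slots, v, e, rep(0L, 40))),
               class = "ginscreen_invalid_spec")
})

test_that("ensemble attention is the mean of member attentions", {
  v <- toy_vocab(2, 1)
  e <- toy_edges(v)
  cfg <- gin_config(n_layers = 1, identity_mlp = TRUE, epochs = 1)
  m1 <- gin_init(cfg, v, e, seed = 1); m1$w <- rep(1, 6)
  m2 <- gin_init(cfg, v, e, seed = 2); m2$w <- rep(3, 6)
  ens <- gin_ensemble(list(m1, m2))
  set.seed(3)
  g <- toy_graphs(random_slots(10, v), v, e, rep(c(0L, 1L), 5))
  att <- population_attention(ens, g)
  expect_equal(unname(att[1, 1]), 2, tolerance = 1e-10)
})

test_that("odds ratios follow the 2x2 arithmetic with Haldane correction", {
  df <- data.frame(
    item = c(rep(1, 20), rep(1, 5), rep(0, 10), rep(0, 40)),
    acute_SI = c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 40)))
  or <- binary_odds_ratios(df, "item")
  expect_equal(or$odds_ratio, 16)
  expect_false(or$corrected)

  df2 <- data.frame(item = rep(c(1, 0), each = 20),
                    acute_SI = c(rep(c(1, 0), 10), rep(0, 20)))
  or2 <- binary_odds_ratios(df2, "item")
  a <- sum(df2$item == 1 & df2$acute_SI == 1)
  b <- sum(df2$item == 1 & df2$acute_SI == 0)
  cc <- sum(df2$item == 0 & df2$acute_SI == 1)
  d <- sum(df2$item == 0 & df2$acute_SI == 0)
  expect_equal(cc, 0)
  expect_true(or2$corrected)
  expect_equal(or2$odds_ratio,
               ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5)))

  bal <- data.frame(item = rep(c(1, 1, 0, 0), 10),
                    acute_SI = rep(c(1, 0, 1, 0), 10))
  expect_equal(binary_odds_ratios(bal, "item")$odds_ratio, 1)
  expect_error(binary_odds_ratios(bal, "missing_item"),
               class = "ginscreen_schema_error")
})
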