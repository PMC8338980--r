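# Closed-form, oracle and property checks for the GIN itself.

identity_model <- function(vocab, edges, K = 1, w = NULL, b = 0,
                           eps = rep(0, K)) {
  cfg <- gin_config(n_layers = K, identity_mlp = TRUE, epochs = 1)
  m <- gin_init(cfg, vocab, edges, seed = 1)
  for (k in seq_len(K)) m$layers[[k]]$eps <- eps[k]
  m$w <- w %||% rep(1, 6 * K)
  m$b <- b
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single node, no edges, identity MLPs, sum classifier gives y = K", {
  v <- toy_vocab(1, 0)
  e <- toy_edges(v)
  for (K in c(1, 3, 5)) {
    m <- identity_model(v, e, K = K)
    g <- toy_graph(2L, v, e)
    fw <- gin_forward(m, g)
    expect_equal(fw$y, K)
    expect_equal(fw$sigmoid, plogis(K))
    # embedding invariants: per-layer pooled feature is the node feature
    expect_equal(fw$embedding$layer_1, g$features[1, ], ignore_attr = TRUE)
    expect_equal(length(fw$concatenated), 6 * K)
  }
})

test_that("forward is invariant to consistent node permutation", {
  set.seed(21)
  v <- toy_vocab(4, 2)
  A <- matrix(rnorm(36) * 0.4, 6, 6); A <- (A + t(A)) / 2; diag(A) <- 0
  e <- toy_edges(v, A)
  cfg <- gin_config(n_layers = 3, width = 8, epochs = 1)
  m <- gin_init(cfg, v, e, seed = 4)
  slots <- matrix(c(1L, 3L, 2L, 4L, 5L, 6L), 1)
  y0 <- gin_forward_batch(m, slots)$y
  for (i in 1:5) {
    perm <- sample(6)
    m2 <- m
    m2$A <- m$A[perm, perm]
    y1 <- gin_forward_batch(m2, slots[, perm, drop = FALSE])$y
    expect_equal(y1, y0, tolerance = 1e-6)
  }
})

test_that("weighted aggregation matches a dense-matrix oracle", {
  v <- toy_vocab(3, 0)
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.8
  A[2, 3] <- A[3, 2] <- -0.7
  e <- toy_edges(v, A)
  set.seed(9)
  w <- rnorm(6 * 2)
  m <- identity_model(v, e, K = 2, w = w, b = 0.3, eps = c(0.2, -0.1))
  slots <- c(2L, 4L, 1L)
  fw <- gin_forward(m, toy_graph(slots, v, e))
  H0 <- matrix(0, 3, 6); H0[cbind(1:3, slots)] <- 1
  y_oracle <- dense_identity_forward(A, c(0.2, -0.1), H0, w, 0.3, K = 2)
  expect_equal(fw$y, y_oracle, tolerance = 1e-10)
  # hand-computed layer-1 node features for the path graph
  M <- A + 1.2 * diag(3)
  expect_equal(fw$embedding$layer_1, colSums(M %*% H0), ignore_attr = TRUE)
})

test_that("bce_loss matches arithmetic and contracts", {
  expect_equal(bce_loss(rep(0.5, 7), c(1, 0, 1, 1, 0, 0, 1)), log(2))
  expect_lt(bce_loss(c(1 - 1e-7, 1e-7), c(1, 0)), 1e-6)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2)
  expect_error(bce_loss(numeric(0), integer(0)),
               class = "ginscreen_invalid_spec")
})

test_that("a linear GIN exposes its classifier weights as input gradients", {
  v <- toy_vocab(2, 1)
  e <- toy_edges(v)           # zero adjacency
  w <- c(rnorm(6))
  m <- identity_model(v, e, K = 1, w = w)
  g <- toy_graph(c(2L, 3L, 6L), v, e)
  grad <- input_gradient(m, g)
  for (node in 1:3) expect_equal(grad[node, ], w, ignore_attr = TRUE)
  # doubling the classifier weights doubles every gradient entry
  m2 <- m; m2$w <- 2 * w
  expect_equal(input_gradient(m2, g), 2 * grad)
})

test_that("input gradients match central finite differences", {
  set.seed(77)
  v <- toy_vocab(3, 2)
  A <- matrix(rnorm(25) * 0.3, 5, 5); A <- (A + t(A)) / 2; diag(A) <- 0
  e <- toy_edges(v, A)
  for (bn in c(FALSE, TRUE)) {
    cfg <- gin_config(n_layers = 2, width = 5, epochs = 1, batch_norm = bn)
    m <- gin_init(cfg, v, e, seed = 3)
    if (bn) for (k in 1:2) {          # non-trivial running stats
      m$layers[[k]]$rm1 <- rnorm(5) * .2; m$layers[[k]]$rv1 <- runif(5, .5, 2)
      m$layers[[k]]$rm2 <- rnorm(5) * .2; m$layers[[k]]$rv2 <- runif(5, .5, 2)
    }
    slots <- c(2L, 4L, 1L, 5L, 6L)
    g <- toy_graph(slots, v, e)
    grad <- input_gradient(m, g)
    H0 <- g$features
    f_at <- function(H) {
      Hc <- H
      G <- c()
      for (k in 1:2) {
        ly <- m$layers[[k]]
        X <- (A + (1 + ly$eps) * diag(5)) %*% Hc
        Z1 <- sweep(X %*% ly$W1, 2, ly$b1, "+")
        if (bn) Z1 <- sweep(sweep(sweep(sweep(Z1, 2, ly$rm1), 2,
                                        sqrt(ly$rv1 + 1e-5), "/"),
                                  2, ly$g1, "*"), 2, ly$be1, "+")
        R <- pmax(Z1, 0)
        Z2 <- sweep(R %*% ly$W2, 2, ly$b2, "+")
        if (bn) Z2 <- sweep(sweep(sweep(sweep(Z2, 2, ly$rm2), 2,
                                        sqrt(ly$rv2 + 1e-5), "/"),
                                  2, ly$g2, "*"), 2, ly$be2, "+")
        Hc <- Z2
        G <- c(G, colSums(Hc))
      }
      sum(G * m$w) + m$b
    }
    num <- matrix(0, 5, 6)
    for (vv in 1:5) for (j in 1:6) {
      Hp <- H0; Hm <- H0
      Hp[vv, j] <- Hp[vv, j] + 1e-4; Hm[vv, j] <- Hm[vv, j] - 1e-4
      num[vv, j] <- (f_at(Hp) - f_at(Hm)) / 2e-4
    }
    expect_lt(max(abs(num - grad)) / max(1, max(abs(num))), 1e-4)
  }
})

test_that("zeroing a layer's classifier block removes exactly that layer's share", {
  set.seed(12)
  v <- toy_vocab(3, 1)
  A <- matrix(rnorm(16) * .3, 4, 4); A <- (A + t(A)) / 2; diag(A) <- 0
  e <- toy_edges(v, A)
  cfg <- gin_config(n_layers = 3, width = 4, epochs = 1)
  m <- gin_init(cfg, v, e, seed = 5)
  g <- toy_graph(c(1L, 4L, 2L, 6L), v, e)
  fw <- gin_forward(m, g)
  blocks <- split(seq_along(m$w), rep(1:3, each = 4))
  for (k in 1:3) {
    mk <- m
    mk$w[blocks[[k]]] <- 0
    contribution <- sum(fw$embedding[[k]] * m$w[blocks[[k]]])
    expect_equal(gin_forward(mk, g)$y, fw$y - contribution,
                 tolerance = 1e-10)
  }
})

test_that("with K=1, identity MLP, zero adjacency the GIN is logistic regression", {
  set.seed(42)
  v <- toy_vocab(3, 1)
  e <- toy_edges(v)
  n <- 400
  slots <- random_slots(n, v)
  true_w <- c(0.8, -0.4, 0.1, 0.9, 0, 0)   # per-slot effects, shared nodes
  X <- matrix(0, n, 6)
  for (i in 1:n) for (vv in 1:4) X[i, slots[i, vv]] <- X[i, slots[i, vv]] + 1
  pr <- plogis(X %*% true_w - 1)
  labels <- rbinom(n, 1, pr)
  graphs <- toy_graphs(slots, v, e, labels)
  cfg <- gin_config(n_layers = 1, identity_mlp = TRUE, epochs = 300,
                    learning_rate = 0.05, batch_size = n)
  m <- suppressWarnings(train_gin(graphs, graphs, cfg,
                                  checkpoint_rule(threshold = "youden"),
                                  seed = 2))
  # reference: plain logistic regression on the summed one-hot features
  ref <- glm(labels ~ X, family = binomial)
  p_gin <- gin_predict(m, graphs)
  p_glm <- fitted(ref)
  expect_gt(cor(qlogis(p_gin), qlogis(p_glm)), 0.98)
})

test_that("the Youden threshold maximises sensitivity + specificity", {
  set.seed(2)
  for (i in 1:10) {
    sc <- round(runif(150), 2)
    lb <- rbinom(150, 1, 0.3)
    yt <- youden_threshold(sc, lb)
    s <- sort(unique(sc))
    cand <- (s[-1] + s[-length(s)]) / 2
    j <- vapply(cand, function(th) {
      cm <- confusion_metrics(sc, lb, th)
      cm$sensitivity + cm$specificity
    }, 0)
    expect_equal(yt, cand[which.max(j)])
  }
})

test_that("training is deterministic in the seed", {
  set.seed(50)
  v <- toy_vocab(3, 1)
  A <- matrix(rnorm(16) * .2, 4, 4); A <- (A + t(A)) / 2; diag(A) <- 0
  e <- toy_edges(v, A)
  slots <- random_slots(120, v)
  labels <- rbinom(120, 1, 0.4)
  tr <- toy_graphs(slots[1:80, ], v, e, labels[1:80])
  va <- toy_graphs(slots[81:120, ], v, e, labels[81:120])
  cfg <- gin_config(n_layers = 2, width = 6, epochs = 4, batch_size = 32)
  m1 <- suppressWarnings(train_gin(tr, va, cfg, checkpoint_rule(), seed = 7))
  m2 <- suppressWarnings(train_gin(tr, va, cfg, checkpoint_rule(), seed = 7))
  expect_identical(m1$trace, m2$trace)
  expect_equal(gin_predict(m1, va), gin_predict(m2, va), tolerance = 0)
  m3 <- suppressWarnings(train_gin(tr, va, cfg, checkpoint_rule(), seed = 8))
  expect_false(identical(m1$trace$loss, m3$trace$loss))
})

test_that("forward cost grows about linearly with edge count", {
  set.seed(3)
  v <- structure(data.frame(name = paste0("n", 1:40),
                            kind = rep("ordinal", 40),
                            column = paste0("n", 1:40),
                            stringsAsFactors = FALSE),
                 class = c("node_vocabulary", "data.frame"))
  mk_e <- function(density) {
    A <- matrix(0, 40, 40)
    idx <- which(upper.tri(A))
    on <- sample(idx, round(density * length(idx)))
    A[on] <- 0.5; A <- A + t(A)
    toy_edges(v, A)
  }
  slots <- matrix(sample(1:4, 40 * 512, TRUE), 512, 40)
  time_for <- function(e) {
    m <- gin_init(gin_config(n_layers = 3, width = 16, epochs = 1), v, e,
                  seed = 1)
    gin_forward_batch(m, slots)   # warm-up
    t0 <- Sys.time()
    for (i in 1:5) gin_forward_batch(m, slots)
    as.numeric(Sys.time() - t0)
  }
  # sanity bound, not a benchmark: 10x the edges should stay well under
  # a quadratic blow-up
  t_sparse <- time_for(mk_e(0.05))
  t_dense <- time_for(mk_e(0.5))
  expect_lt(t_dense, t_sparse * 20)
})
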