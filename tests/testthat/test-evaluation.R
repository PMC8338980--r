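test_that("confusion metrics match hand counts and brute force", {
  cm <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 1)

  # majority-collapse case: every score below threshold, 1% positives
  cm2 <- confusion_metrics(rep(0.1, 100), c(1, rep(0, 99)), 0.5)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)
  expect_equal(cm2$accuracy, 0.99)

  set.seed(4)
  sc <- runif(50); lb <- rbinom(50, 1, 0.4); th <- 0.35
  cm3 <- confusion_metrics(sc, lb, th)
  tp <- sum(sc >= th & lb == 1); fn <- sum(sc < th & lb == 1)
  tn <- sum(sc < th & lb == 0); fp <- sum(sc >= th & lb == 0)
  expect_equal(cm3$sensitivity, tp / (tp + fn))
  expect_equal(cm3$specificity, tn / (tn + fp))
  expect_equal(cm3$accuracy, (tp + tn) / 50)

  cm4 <- confusion_metrics(c(0.2, 0.7), c(1, 1), 0.5)
  expect_true(is.na(cm4$specificity))
  expect_equal(cm4$sensitivity, 0.5)
})

test_that("metrics are threshold-monotone", {
  set.seed(10)
  sc <- runif(200); lb <- rbinom(200, 1, 0.3)
  ths <- seq(0, 1, by = 0.05)
  sens <- vapply(ths, function(t) confusion_metrics(sc, lb, t)$sensitivity, 0)
  spec <- vapply(ths, function(t) confusion_metrics(sc, lb, t)$specificity, 0)
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("AUC equals the Mann-Whitney pair count, including ties", {
  expect_equal(auc_delong(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, TRUE)   # force ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_delong(sc, lb)$auc, oracle_auc_paircount(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("null AUC sits within 3 SE of one half and CI tightens with n", {
  set.seed(23)
  sc <- runif(2000); lb <- rbinom(2000, 1, 0.5)
  a <- auc_delong(sc, lb)
  expect_lt(abs(a$auc - 0.5), 3 * sqrt(a$var))
  sc2 <- runif(100); lb2 <- rbinom(100, 1, 0.5)
  a2 <- auc_delong(sc2, lb2)
  expect_lt(diff(a$ci), diff(a2$ci))
  expect_error(auc_delong(runif(10), rep(1, 10)),
               class = "ginscreen_single_class")
})

test_that("DeLong AUC, variance and CI agree with pROC", {
  set.seed(91)
  sc <- c(rnorm(60, 1), rnorm(140, 0)); lb <- c(rep(1, 60), rep(0, 140))
  mine <- auc_delong(sc, lb)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(mine$var, as.numeric(pROC::var(ref)), tolerance = 1e-8)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("paired DeLong test is antisymmetric and null on identical scores", {
  set.seed(34)
  lb <- rbinom(80, 1, 0.4)
  a <- runif(80); b <- a + rnorm(80, sd = 0.2)
  same <- delong_paired_test(a, a, lb)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_paired_test(a, b, lb)
  ba <- delong_paired_test(b, a, lb)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  # cross-check with pROC's paired DeLong
  ref <- pROC::roc.test(pROC::roc(lb, a, quiet = TRUE, direction = "<"),
                        pROC::roc(lb, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ab$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("paired DeLong p agrees with a label-preserving bootstrap oracle", {
  set.seed(60)
  n <- 60
  lb <- c(rep(1, 20), rep(0, 40))
  truth <- rnorm(n)
  a <- truth + rnorm(n, sd = 1.2) + lb * 0.8
  b <- truth + rnorm(n, sd = 1.6) + lb * 0.6
  res <- delong_paired_test(a, b, lb)
  boots <- replicate(4000, {
    pos <- sample(which(lb == 1), replace = TRUE)
    neg <- sample(which(lb == 0), replace = TRUE)
    idx <- c(pos, neg)
    boot_auc(a[idx], lb[idx]) - boot_auc(b[idx], lb[idx])
  })
  p_boot <- 2 * pnorm(-abs(res$difference) / sd(boots))
  expect_lt(abs(res$p_value - p_boot), 0.1)
})

test_that("dependent-correlation test handles its edge and extreme cases", {
  set.seed(5)
  x <- rnorm(100); crit <- x + rnorm(100)
  same <- dependent_correlation_test(x, x, crit)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)

  alt <- rnorm(100)
  ext <- dependent_correlation_test(crit, alt, crit)
  expect_equal(ext$rho_pred, 1)
  expect_lt(ext$p_two_sided, 1e-6)

  ab <- dependent_correlation_test(x, alt, crit)
  ba <- dependent_correlation_test(alt, x, crit)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)

  expect_error(dependent_correlation_test(rep(1, 50), alt[1:50], crit[1:50]),
               class = "ginscreen_invalid_spec")
  expect_error(dependent_correlation_test(x[1:5], alt[1:5], crit[1:5]),
               class = "ginscreen_invalid_spec")
})

test_that("dependent-correlation p agrees with a subject-resampling bootstrap", {
  set.seed(41)
  n <- 40
  z <- rnorm(n)
  crit <- z + rnorm(n)
  pred <- z + rnorm(n, sd = 0.8)
  alt <- z + rnorm(n, sd = 1.4)
  res <- dependent_correlation_test(pred, alt, crit)
  boots <- replicate(4000, {
    idx <- sample(n, replace = TRUE)
    cor(pred[idx], crit[idx], method = "spearman") -
      cor(alt[idx], crit[idx], method = "spearman")
  })
  d_obs <- res$rho_pred - res$rho_alt
  p_boot <- 2 * pnorm(-abs(d_obs) / sd(boots))
  expect_lt(abs(res$p_two_sided - p_boot), 0.15)
})

test_that("listwise deletion drops incomplete triples", {
  set.seed(8)
  x <- rnorm(30); a <- rnorm(30); crit <- x + rnorm(30)
  crit[c(3, 7)] <- NA
  res <- dependent_correlation_test(x, a, crit)
  expect_equal(res$n, 28)
})

test_that("baselines separate noiseless linear data and obey the penalty limit", {
  set.seed(66)
  v <- toy_vocab(4, 0)
  e <- toy_edges(v)
  slots <- random_slots(240, v)
  labels <- as.integer(slots[, 1] >= 3)        # perfectly separable
  g <- toy_graphs(slots, v, e, labels)
  for (kind in c("lasso-logistic", "max-margin")) {
    fit <- baseline_fit(g, g, kind, seed = 2)
    expect_gte(mean(fit$predicted == labels), 0.99)
  }
  expect_error(baseline_fit(toy_graphs(slots, v, e, rep(0, 240)), g,
                            "lasso-logistic"),
               class = "ginscreen_single_class")
  # infinite penalty drives all coefficients to zero -> constant scores
  X <- ginscreen:::flatten_features(g)
  fit_inf <- glmnet::glmnet(X, labels, family = "binomial",
                            lambda = 1e6)
  expect_equal(max(abs(fit_inf$beta)), 0)
})
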