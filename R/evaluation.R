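# Classification metrics, DeLong ROC machinery, dependent-correlation
# tests, and the two conventional baselines ------------------------------

#' Confusion-matrix metrics at a threshold
#'
#' Scores at or above the threshold predict positive.  With single-class
#' labels the undefined rate (sensitivity without positives, specificity
#' without negatives) is reported as `NA`, never as 0.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `n`,
#'   `n_pos`, `threshold`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(labels),
       n = length(labels), n_pos = tp + fn, threshold = threshold)
}

# Mann-Whitney AUC with ties counted 1/2, via midranks.
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_ginscreen("AUC needs both classes", class = "ginscreen_single_class")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (one per positive), V01 (one per
# negative); mean of either is the AUC.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0)
    stop_ginscreen("AUC needs both classes", class = "ginscreen_single_class")
  # psi(x_i, y_j) = 1, 1/2, 0 as x > = < y; row/col means via midranks
  rall <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (rall[seq_len(m)] - rx) / n
  v01 <- 1 - (rall[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC equals the Mann-Whitney two-sample statistic (ties counted
#' 1/2); its variance comes from DeLong's structural-components
#' estimator, and the CI from a normal approximation clipped to
#' \[0, 1\].
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels, conf = 0.95) {
  cmp <- delong_components(scores, labels)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(cmp$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = cmp$auc, var = v, ci = ci, n_pos = cmp$m, n_neg = cmp$n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects,
#' accounting for their covariance through the structural components.
#' Identical score vectors give difference 0 and p = 1.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels binary labels.
#' @return list with `auc_a`, `auc_b`, `difference`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, difference = d, var_diff = var_diff,
       z = z, p_value = p)
}

spearman_rho <- function(x, y) cor(x, y, method = "spearman")

#' Compare two dependent, overlapping Spearman correlations
#'
#' Tests whether the rank correlation of `pred` with `criterion` exceeds
#' that of `alt` with the same `criterion`, on the same subjects, using
#' Steiger's z on Fisher-transformed rank correlations with the
#' inter-predictor correlation accounting for the dependence.  Rows with
#' a missing value in any of the three variables are dropped listwise.
#'
#' @param pred,alt two predictor vectors.
#' @param criterion the shared criterion vector.
#' @return list with `rho_pred`, `rho_alt`, `rho_inter`, `z`,
#'   `p_two_sided`, `p_one_sided` (for rho_pred > rho_alt), `n`.
#' @export
dependent_correlation_test <- function(pred, alt, criterion) {
  keep <- stats::complete.cases(pred, alt, criterion)
  pred <- pred[keep]; alt <- alt[keep]; criterion <- criterion[keep]
  n <- length(pred)
  if (n < 10)
    stop_ginscreen("need at least 10 complete triples",
                   class = "ginscreen_invalid_spec")
  if (sd(pred) == 0 || sd(alt) == 0 || sd(criterion) == 0)
    stop_ginscreen("constant column in correlation comparison",
                   class = "ginscreen_invalid_spec")
  r1 <- spearman_rho(pred, criterion)
  r2 <- spearman_rho(alt, criterion)
  r12 <- spearman_rho(pred, alt)
  z1 <- atanh(min(max(r1, -1 + 1e-12), 1 - 1e-12))
  z2 <- atanh(min(max(r2, -1 + 1e-12), 1 - 1e-12))
  rm2 <- (r1^2 + r2^2) / 2
  if (1 - r12 < .Machine$double.eps^0.5) {
    # perfectly dependent predictors: no evidence unless the
    # correlations themselves differ, which cannot happen at r12 = 1
    z <- 0
  } else {
    f <- min((1 - r12) / (2 * (1 - rm2)), 1)
    h <- (1 - f * rm2) / (1 - rm2)
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  list(rho_pred = r1, rho_alt = r2, rho_inter = r12, z = z,
       p_two_sided = 2 * pnorm(-abs(z)), p_one_sided = pnorm(-z), n = n)
}

# flattened one-hot design matrix (n x V*6) -- the same representation
# the GIN consumes, so baselines compare like-for-like
flatten_features <- function(graphs) {
  n <- n_graphs(graphs); V <- ncol(graphs$slots)
  X <- matrix(0, n, V * 6)
  col_idx <- (rep(seq_len(V), each = 1) - 1) * 6
  for (i in seq_len(n)) X[i, col_idx + graphs$slots[i, ]] <- 1
  colnames(X) <- paste0(rep(graphs$vocab$name, each = 6), "_s", 1:6)
  X
}

#' Conventional baselines on the flattened one-hot features
#'
#' `"lasso-logistic"`: penalized logistic regression with the penalty
#' chosen by stratified cross-validation on the training graphs.
#' `"max-margin"`: a support-vector machine; its signed decision values
#' are mapped through the logistic link so that scores are comparable to
#' sigmoid outputs, and class predictions use the SVM's own decision
#' rule.
#'
#' @param train,test `subject_graphs` for training and scoring.
#' @param kind `"lasso-logistic"` or `"max-margin"`.
#' @param seed integer seed (cross-validation folds).
#' @return list with `scores` (on `test`), `predicted` (0/1), `kind`.
#' @export
baseline_fit <- function(train, test, kind = c("lasso-logistic", "max-margin"),
                         seed = 1) {
  kind <- match.arg(kind)
  y <- train$labels
  if (length(unique(y)) < 2)
    stop_ginscreen("single-class training data",
                   class = "ginscreen_single_class")
  Xtr <- flatten_features(train)
  Xte <- flatten_features(test)
  set.seed(seed)
  if (kind == "lasso-logistic") {
    # stratified folds so rare positives appear in every fold
    nf <- min(5, sum(y == 1))
    foldid <- integer(length(y))
    foldid[y == 1] <- rep_len(seq_len(nf), sum(y == 1))[sample.int(sum(y == 1))]
    foldid[y == 0] <- rep_len(seq_len(nf), sum(y == 0))[sample.int(sum(y == 0))]
    fit <- glmnet::cv.glmnet(Xtr, y, family = "binomial", foldid = foldid,
                             alpha = 1)
    sc <- drop(predict(fit, Xte, s = "lambda.min", type = "response"))
    list(scores = sc, predicted = as.integer(sc >= 0.5), kind = kind)
  } else {
    fit <- e1071::svm(Xtr, factor(y), kernel = "radial", scale = FALSE)
    pr <- predict(fit, Xte, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient decision values so larger means more likely positive
    if (grepl("^0", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
    list(scores = plogis(dv), predicted = as.integer(as.character(pr)),
         kind = kind)
  }
}

#' Full metrics report for a score vector
#'
#' @inheritParams confusion_metrics
#' @return list combining [confusion_metrics()] and [auc_delong()].
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_metrics(scores, labels, threshold)
  au <- auc_delong(scores, labels)
  c(cm, list(auc = au$auc, auc_var = au$var, auc_ci = au$ci))
}
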