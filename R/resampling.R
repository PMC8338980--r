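# Class-imbalance resampling: under-sampling and SMOTE-NC ---------------
#
# Acute SI has ~1% prevalence; three differently-resampled training sets
# feed the ensemble members: under-sampling to balance ratios 10 and 5,
# and SMOTE-NC over-sampling to ratio 1, where the balance ratio is the
# number of negatives per positive in the resampled data.

#' Resampling specification
#'
#' @param strategy `"under"` (majority under-sampling) or `"smote-nc"`
#'   (minority over-sampling for mixed ordinal/nominal features).
#' @param ratio balance ratio: negatives per positive after resampling
#'   (> 0).  Conventional settings: 10 and 5 for the two under-sampled
#'   members, 1 for the SMOTE-NC member.
#' @param k number of minority nearest neighbours for SMOTE-NC.
#' @param seed integer seed.
#' @return object of class `resample_spec`.
#' @export
resample_spec <- function(strategy = c("under", "smote-nc"), ratio,
                          k = 5, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(ratio > 0, k >= 1)
  structure(list(strategy = strategy, ratio = ratio, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "resample_spec")
}

#' Under-sample the majority class
#'
#' Keeps every positive row unchanged, samples negatives without
#' replacement down to `round(ratio * n_pos)` (or keeps all negatives
#' with a warning when fewer exist), and shuffles the row order.  The
#' RNG protocol is: `set.seed(spec$seed)`, one `sample()` over negative
#' row indices, one `sample()` for the final shuffle.
#'
#' @param table cohort data frame with an `acute_SI` (or `label_column`)
#'   column.
#' @param spec a [resample_spec()] with `strategy = "under"`.
#' @param label_column name of the binary label column.
#' @return the resampled data frame.
#' @export
undersample <- function(table, spec, label_column = "acute_SI") {
  stopifnot(inherits(spec, "resample_spec"), spec$strategy == "under")
  y <- table[[label_column]]
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0)
    stop_ginscreen("no positive rows to anchor under-sampling",
                   class = "ginscreen_resample_error")
  n_target <- round(spec$ratio * length(pos))
  set.seed(spec$seed)
  if (n_target >= length(neg)) {
    if (n_target > length(neg))
      warning("requested ", n_target, " negatives but only ", length(neg),
              " exist; keeping all", call. = FALSE)
    keep_neg <- neg
  } else {
    keep_neg <- neg[sample.int(length(neg), n_target)]
  }
  keep <- c(pos, keep_neg)
  out <- table[keep[sample.int(length(keep))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

smote_feature_columns <- function(table) {
  intersect(c(phq_cols(), gad_cols(), total_cols()), names(table))
}

#' SMOTE-NC over-sampling of the minority class
#'
#' Generates synthetic positive rows until the class ratio reaches
#' `spec$ratio` negatives per positive.  Continuous/ordinal features of a
#' synthetic row lie on the segment between a minority seed row and one
#' of its `k` nearest minority neighbours (then rounded back to the valid
#' grid: levels 1-4 for items, integers for totals); nominal features
#' take the majority vote of the `k` neighbours (ties keep the seed's
#' value).  Distances are Euclidean on the continuous features plus, for
#' each differing nominal feature, the squared median of the continuous
#' features' standard deviations.  Original rows are never altered.
#'
#' RNG protocol (reproduced by the test oracle): `set.seed(spec$seed)`;
#' draw all seed-row indices (`sample(n_pos, n_syn, replace = TRUE)`),
#' then all neighbour choices (`sample(k, n_syn, replace = TRUE)`), then
#' all interpolation gaps (`runif(n_syn)`).
#'
#' @param table cohort data frame.
#' @param spec a [resample_spec()] with `strategy = "smote-nc"`.
#' @param nominal_columns names of the nominal (categorical) feature
#'   columns.
#' @param label_column name of the binary label column.
#' @return data frame of original plus synthetic rows.
#' @export
smote_nc <- function(table, spec,
                     nominal_columns = c("lifetime_SA", "MaDE",
                                         "gender_female",
                                         "institution_hospital"),
                     label_column = "acute_SI") {
  stopifnot(inherits(spec, "resample_spec"), spec$strategy == "smote-nc")
  nominal_columns <- intersect(nominal_columns, names(table))
  y <- table[[label_column]]
  pos_idx <- which(y == 1)
  n_pos <- length(pos_idx); n_neg <- sum(y == 0)
  if (n_pos < spec$k + 1)
    stop_ginscreen("SMOTE-NC needs at least k + 1 = ", spec$k + 1,
                   " minority rows; got ", n_pos,
                   class = "ginscreen_resample_error")
  n_pos_final <- round(n_neg / spec$ratio)
  n_syn <- n_pos_final - n_pos
  if (n_syn <= 0) return(table)

  cont_cols <- smote_feature_columns(table)
  Xc <- as.matrix(table[pos_idx, cont_cols, drop = FALSE])
  Xn <- as.matrix(table[pos_idx, nominal_columns, drop = FALSE])
  sds <- apply(Xc, 2, sd)
  med2 <- median(sds)^2

  # pairwise squared distances among minority rows
  D <- as.matrix(dist(Xc))^2
  if (length(nominal_columns)) {
    for (j in seq_along(nominal_columns)) {
      diffm <- outer(Xn[, j], Xn[, j], "!=")
      D <- D + med2 * diffm
    }
  }
  diag(D) <- Inf
  # k nearest minority neighbours, ties broken by index order
  nbrs <- t(apply(D, 1, function(d) order(d)[seq_len(spec$k)]))

  set.seed(spec$seed)
  seed_i <- sample.int(n_pos, n_syn, replace = TRUE)
  nbr_choice <- sample.int(spec$k, n_syn, replace = TRUE)
  gaps <- runif(n_syn)

  nbr_i <- nbrs[cbind(seed_i, nbr_choice)]
  syn_c <- Xc[seed_i, , drop = FALSE] +
    gaps * (Xc[nbr_i, , drop = FALSE] - Xc[seed_i, , drop = FALSE])
  # snap back to the valid grid
  for (j in seq_along(cont_cols)) {
    v <- round(syn_c[, j])
    if (cont_cols[j] %in% c(phq_cols(), gad_cols()))
      v <- pmin(pmax(v, 1L), 4L)
    syn_c[, j] <- v
  }
  syn_n <- matrix(0L, n_syn, length(nominal_columns),
                  dimnames = list(NULL, nominal_columns))
  if (length(nominal_columns)) {
    for (i in seq_len(n_syn)) {
      vals <- Xn[nbrs[seed_i[i], ], , drop = FALSE]
      for (j in seq_along(nominal_columns)) {
        uv <- sort(unique(vals[, j]))
        cnt <- vapply(uv, function(u) sum(vals[, j] == u), 0)
        top <- uv[cnt == max(cnt)]
        syn_n[i, j] <- if (length(top) == 1) as.integer(top)
                       else as.integer(Xn[seed_i[i], j])
      }
    }
  }

  syn <- table[pos_idx[seed_i], , drop = FALSE]
  syn[, cont_cols] <- syn_c
  if (length(nominal_columns)) syn[, nominal_columns] <- syn_n
  if ("subject_id" %in% names(syn))
    syn$subject_id <- sprintf("SYN%06d", seq_len(n_syn))
  if ("MaDE_label" %in% names(syn)) syn$MaDE_label <- NA_integer_
  if ("KSSI_total" %in% names(syn)) syn$KSSI_total <- NA_integer_
  syn[[label_column]] <- 1L
  out <- rbind(table, syn)
  rownames(out) <- NULL
  out
}

#' Apply a resampling specification
#'
#' Dispatches to [undersample()] or [smote_nc()].
#'
#' @inheritParams smote_nc
#' @param spec a [resample_spec()].
#' @return the resampled data frame.
#' @export
resample_table <- function(table, spec,
                           nominal_columns = c("lifetime_SA", "MaDE",
                                               "gender_female",
                                               "institution_hospital"),
                           label_column = "acute_SI") {
  switch(spec$strategy,
         "under" = undersample(table, spec, label_column),
         "smote-nc" = smote_nc(table, spec, nominal_columns, label_column))
}
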