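# Synthetic cohort generation -------------------------------------------
#
# The generator emulates the statistical structure the screening method
# assumes: correlated ordinal questionnaire items driven by latent
# depression / anxiety / resilience / self-esteem traits, integer scale
# totals, rare binary outcomes with planted (and therefore recoverable)
# effect sizes, and partial availability of the diagnostic label.

#' Specify the latent-trait measurement model
#'
#' Items are generated as `loading * trait + N(0, 1)` noise and then cut
#' into four ordinal levels.  When `cutpoints` is `NULL` (the default),
#' each item uses the quartile cutpoints of its own latent scale,
#' `sqrt(1 + loading^2) * qnorm(c(.25, .5, .75))`, so that the marginal
#' distribution over the four levels is uniform and a zero loading yields
#' exactly the no-signal case.
#'
#' @param trait_cor 4x4 correlation matrix over
#'   (depression, anxiety, resilience, self_esteem).  Must be symmetric,
#'   unit-diagonal and positive semi-definite.
#' @param loadings named list mapping each item (PHQ_1..PHQ_9,
#'   GAD_1..GAD_7) to `list(trait =, loading =)`.
#' @param total_loadings named list for the three raw scale totals
#'   (STAI_T, RAS_T, RSES_T): owning trait, loading, mean, sd and
#'   integer range of the total.
#' @param cutpoints optional named list of 3 strictly increasing cutpoints
#'   per item, overriding the uniform-marginal default.
#' @return an object of class `latent_trait_spec`.
#' @export
latent_trait_spec <- function(trait_cor = default_trait_cor(),
                              loadings = default_item_loadings(),
                              total_loadings = default_total_loadings(),
                              cutpoints = NULL) {
  traits <- c("depression", "anxiety", "resilience", "self_esteem")
  trait_cor <- as.matrix(trait_cor)
  dimnames(trait_cor) <- list(traits, traits)
  if (!isTRUE(all.equal(trait_cor, t(trait_cor), tolerance = 1e-10)))
    stop_ginscreen("trait correlation matrix must be symmetric",
                   class = "ginscreen_invalid_spec")
  if (any(abs(diag(trait_cor) - 1) > 1e-10))
    stop_ginscreen("trait correlation matrix must have unit diagonal",
                   class = "ginscreen_invalid_spec")
  ev <- eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_ginscreen("trait correlation matrix is not positive semi-definite",
                   class = "ginscreen_invalid_spec")
  if (!all(vapply(loadings, function(l) is.finite(l$loading), logical(1))))
    stop_ginscreen("item loadings must be finite",
                   class = "ginscreen_invalid_spec")
  if (!is.null(cutpoints)) {
    ok <- vapply(cutpoints, function(cp) length(cp) == 3 && all(diff(cp) > 0),
                 logical(1))
    if (!all(ok))
      stop_ginscreen("cutpoints must be 3 strictly increasing values",
                     class = "ginscreen_invalid_spec")
  }
  structure(list(trait_cor = trait_cor, loadings = loadings,
                 total_loadings = total_loadings, cutpoints = cutpoints),
            class = "latent_trait_spec")
}

#' @rdname latent_trait_spec
#' @export
default_trait_cor <- function() {
  traits <- c("depression", "anxiety", "resilience", "self_esteem")
  R <- diag(4)
  dimnames(R) <- list(traits, traits)
  R["depression", "anxiety"] <- R["anxiety", "depression"] <- 0.6
  R["depression", "resilience"] <- R["resilience", "depression"] <- -0.4
  R["depression", "self_esteem"] <- R["self_esteem", "depression"] <- -0.45
  R["anxiety", "resilience"] <- R["resilience", "anxiety"] <- -0.5
  R["anxiety", "self_esteem"] <- R["self_esteem", "anxiety"] <- -0.5
  R["resilience", "self_esteem"] <- R["self_esteem", "resilience"] <- 0.55
  R
}

#' @rdname latent_trait_spec
#' @export
default_item_loadings <- function() {
  # loadings of 1.6 put item-trait correlations near 0.85 and
  # within-scale inter-item correlations near 0.65-0.7, so the sparse
  # correlation network retains within-scale edges at the 0.6 threshold
  # the screening graph assumes
  l <- list()
  for (i in 1:9)
    l[[paste0("PHQ_", i)]] <- list(trait = "depression", loading = 1.6)
  # anhedonia carries the strongest planted depression signal, so the
  # generator's Bayes-optimal saliency ranking is known in advance
  l[["PHQ_2"]] <- list(trait = "depression", loading = 2.2)
  for (i in 1:7)
    l[[paste0("GAD_", i)]] <- list(trait = "anxiety", loading = 1.6)
  l
}

#' @rdname latent_trait_spec
#' @export
default_total_loadings <- function() {
  list(
    STAI_T = list(trait = "anxiety",     loading = 2.0, mean = 42, sd = 9,
                  range = c(20L, 80L)),
    RAS_T  = list(trait = "resilience",  loading = 2.0, mean = 40, sd = 8,
                  range = c(12L, 60L)),
    RSES_T = list(trait = "self_esteem", loading = 2.0, mean = 28, sd = 5,
                  range = c(10L, 40L))
  )
}

#' Specify outcome models and label availability
#'
#' Each binary outcome follows a logistic model on the latent traits (and,
#' for acute suicidal ideation, on lifetime suicide attempt, major
#' depressive episode, gender and institution), with the intercept
#' calibrated by [calibrate_intercept()] so the population prevalence hits
#' its target.
#'
#' @param si_coef,sa_coef,made_coef named logistic coefficients for acute
#'   SI, lifetime SA, and MaDE.
#' @param item_coef named direct logistic coefficients of standardized
#'   latent item scores on acute SI, over and above the trait paths.
#'   The default plants a direct anhedonia (PHQ_2) effect, so that one
#'   item unambiguously carries the strongest single-item association
#'   with the outcome — the planted signal the attribution recovery
#'   experiments are scored against.  (A trait-level coefficient alone
#'   cannot make one item dominant: the effect is shared by every item
#'   loading on the trait.)
#' @param prevalence named target prevalences in (0, 1) for
#'   `acute_SI`, `lifetime_SA`, `MaDE`.
#' @param labeled_fraction fraction in (0, 1] of subjects carrying a true
#'   MaDE label.
#' @param covariate_prob named Bernoulli probabilities for
#'   `gender_female` and `institution_hospital`.
#' @param kssi_fraction fraction of subjects with an observed
#'   suicide-ideation scale total (the external criterion).
#' @return an object of class `outcome_spec`.
#' @export
outcome_spec <- function(si_coef = c(depression = 1.5, anxiety = 0.5,
                                     resilience = -0.5, self_esteem = -0.3,
                                     lifetime_SA = 1.5, MaDE = 0.8,
                                     gender_female = 0.3,
                                     institution_hospital = 0.2),
                         item_coef = c(PHQ_2 = 0.8),
                         sa_coef = c(depression = 0.8, anxiety = 0.4,
                                     resilience = -0.4, self_esteem = -0.2),
                         made_coef = c(depression = 3),
                         prevalence = c(acute_SI = 0.01, lifetime_SA = 0.014,
                                        MaDE = 0.10),
                         labeled_fraction = 0.011,
                         covariate_prob = c(gender_female = 0.318,
                                            institution_hospital = 0.45),
                         kssi_fraction = 0.06) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop_ginscreen("target prevalences must lie in (0, 1)",
                   class = "ginscreen_invalid_spec")
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop_ginscreen("labeled_fraction must lie in (0, 1]",
                   class = "ginscreen_invalid_spec")
  structure(list(si_coef = si_coef, item_coef = item_coef, sa_coef = sa_coef,
                 made_coef = made_coef,
                 prevalence = prevalence, labeled_fraction = labeled_fraction,
                 covariate_prob = covariate_prob,
                 kssi_fraction = kssi_fraction),
            class = "outcome_spec")
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Finds, by bisection on \[-20, 20\], the intercept `b0` such that
#' `mean(plogis(b0 + X %*% coefficients))` equals `target_prevalence` to
#' within 1e-6.  The mean probability is monotone increasing in the
#' intercept, so bisection always converges when the target is
#' bracketed.
#'
#' @param coefficients numeric coefficient vector.
#' @param covariate_sample matrix (or data.frame) of covariates, columns
#'   matching `coefficients`.
#' @param target_prevalence target in (0, 1).
#' @return the calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(coefficients, covariate_sample,
                                target_prevalence) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  X <- as.matrix(covariate_sample)
  if (nrow(X) == 0) stop_ginscreen("covariate sample is empty",
                                   class = "ginscreen_invalid_spec")
  lp <- drop(X %*% coefficients)
  if (any(!is.finite(lp)))
    stop_ginscreen("non-finite linear predictors",
                   class = "ginscreen_calibration_error")
  f <- function(b0) mean(plogis(b0 + lp)) - target_prevalence
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop_ginscreen("target prevalence not achievable on [-20, 20]",
                   class = "ginscreen_calibration_error")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) > 1e-6)
    stop_ginscreen("intercept calibration did not converge",
                   class = "ginscreen_calibration_error")
  mid
}

cut_ordinal <- function(z, cutpoints) {
  1L + (z > cutpoints[1]) + (z > cutpoints[2]) + (z > cutpoints[3])
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws `n` subjects: multivariate-normal latent traits, ordinal items
#' through the measurement model in `spec`, integer scale totals, binary
#' covariates, and the three binary outcomes with intercepts calibrated to
#' the target prevalences.  The true (complete) MaDE indicator and the
#' latent traits are kept in the `truth` element so planted effects can be
#' scored against an oracle; the cohort table itself only carries the
#' partially observed `MaDE_label`.
#'
#' @param spec a [latent_trait_spec()].
#' @param outcomes an [outcome_spec()].
#' @param n number of subjects (>= 50).
#' @param seed integer seed; the same `(spec, outcomes, n, seed)` always
#'   reproduces the same cohort bit-for-bit.
#' @return an object of class `synthetic_cohort` with elements `cohort`
#'   (the data frame), `truth`, `spec`, `outcomes`, `seed`.
#' @export
generate_cohort <- function(spec = latent_trait_spec(),
                            outcomes = outcome_spec(), n, seed) {
  stopifnot(inherits(spec, "latent_trait_spec"),
            inherits(outcomes, "outcome_spec"))
  if (n < 50) stop_ginscreen("n must be at least 50",
                             class = "ginscreen_invalid_spec")
  set.seed(seed)
  traits <- colnames(spec$trait_cor)
  L <- chol(spec$trait_cor + diag(1e-10, 4))
  Tm <- matrix(rnorm(n * 4), n, 4) %*% L
  colnames(Tm) <- traits

  items <- names(spec$loadings)
  item_m <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  direct_items <- intersect(names(outcomes$item_coef %||% numeric(0)), items)
  item_z <- matrix(0, n, length(direct_items),
                   dimnames = list(NULL, direct_items))
  for (it in items) {
    ld <- spec$loadings[[it]]
    z <- ld$loading * Tm[, ld$trait] + rnorm(n)
    cp <- spec$cutpoints[[it]] %||%
      (sqrt(1 + ld$loading^2) * qnorm(c(.25, .5, .75)))
    item_m[, it] <- cut_ordinal(z, cp)
    if (it %in% direct_items)
      item_z[, it] <- z / sqrt(1 + ld$loading^2)   # standardized latent score
  }

  totals <- lapply(names(spec$total_loadings), function(tot) {
    tl <- spec$total_loadings[[tot]]
    z <- (tl$loading * Tm[, tl$trait] + rnorm(n)) / sqrt(1 + tl$loading^2)
    pmin(pmax(round(tl$mean + tl$sd * z), tl$range[1]), tl$range[2])
  })
  names(totals) <- names(spec$total_loadings)

  gender <- rbinom(n, 1, outcomes$covariate_prob[["gender_female"]])
  instit <- rbinom(n, 1, outcomes$covariate_prob[["institution_hospital"]])

  draw_outcome <- function(coef, X, target) {
    b0 <- calibrate_intercept(coef, X, target)
    p <- plogis(b0 + drop(as.matrix(X) %*% coef))
    rbinom(n, 1, p)
  }
  sa <- draw_outcome(outcomes$sa_coef, Tm[, names(outcomes$sa_coef), drop = FALSE],
                     outcomes$prevalence[["lifetime_SA"]])
  made <- draw_outcome(outcomes$made_coef,
                       Tm[, names(outcomes$made_coef), drop = FALSE],
                       outcomes$prevalence[["MaDE"]])

  si_X <- cbind(Tm, lifetime_SA = sa, MaDE = made, gender_female = gender,
                institution_hospital = instit)[, names(outcomes$si_coef),
                                               drop = FALSE]
  si_coef_all <- outcomes$si_coef
  if (length(direct_items)) {
    si_X <- cbind(si_X, item_z[, direct_items, drop = FALSE])
    si_coef_all <- c(si_coef_all, outcomes$item_coef[direct_items])
  }
  si_b0 <- calibrate_intercept(si_coef_all, si_X,
                               outcomes$prevalence[["acute_SI"]])
  si_lp <- si_b0 + drop(si_X %*% si_coef_all)
  si <- rbinom(n, 1, plogis(si_lp))

  labeled <- sample.int(n, max(1L, round(outcomes$labeled_fraction * n)))
  made_label <- rep(NA_integer_, n)
  made_label[labeled] <- made[labeled]

  kssi <- rep(NA_integer_, n)
  kssi_obs <- sample.int(n, round(outcomes$kssi_fraction * n))
  z <- (si_lp - mean(si_lp)) / sd(si_lp)
  kssi[kssi_obs] <- pmax(0L, as.integer(round(8 + 6 * z[kssi_obs] +
                                                2 * rnorm(length(kssi_obs)))))

  cohort <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                       item_m, STAI_T = totals$STAI_T, RAS_T = totals$RAS_T,
                       RSES_T = totals$RSES_T, lifetime_SA = sa,
                       gender_female = gender, institution_hospital = instit,
                       MaDE_label = made_label, acute_SI = si,
                       KSSI_total = kssi,
                       stringsAsFactors = FALSE)
  structure(list(cohort = cohort,
                 truth = data.frame(Tm, MaDE_true = made, si_lp = si_lp),
                 spec = spec, outcomes = outcomes, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$cohort)
  cat("Synthetic questionnaire cohort: ", n, " subjects (seed ", x$seed,
      ")\n", sep = "")
  cat("  acute SI: ", sum(x$cohort$acute_SI), " (",
      format_pct(sum(x$cohort$acute_SI), n), "%)\n", sep = "")
  cat("  lifetime SA: ", sum(x$cohort$lifetime_SA), "; MaDE labels: ",
      sum(!is.na(x$cohort$MaDE_label)), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort and its provenance sidecar
#'
#' The cohort goes to `path` as CSV; the generating seed and target
#' prevalences go to `<path>.json`.
#'
#' @param x a `synthetic_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(x, path) {
  stopifnot(inherits(x, "synthetic_cohort"))
  write_cohort(x$cohort, path)
  side <- list(seed = x$seed,
               n = nrow(x$cohort),
               prevalence = as.list(x$outcomes$prevalence),
               labeled_fraction = x$outcomes$labeled_fraction)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
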