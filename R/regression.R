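# Linear expression models: log10 TPM_i = intercept + sum_j w_j S_ij + e_i.
# A positive regression coefficient (RC) reads as activator-like, a negative
# one as repressor-like. Model quality is summarized by the residual
# standard error RSE = sqrt(RSS / (n_genes - 2)) and by
# AIC = n * ln(RSS / n) + 2 * (p + 1), p counting the slope terms.

rss_aic <- function(rss, n, p) n * log(pmax(rss, 1e-300) / n) + 2 * (p + 1)

rse_from_rss <- function(rss, n) sqrt(rss / (n - 2))

# Core least-squares fit on a subset of columns; intercept always included.
ols_fit <- function(S, y, features) {
  X <- cbind(`(Intercept)` = 1, S[, features, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    abort(paste0("singular design; offending column(s): ",
                 paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  list(qr = qr_x, X = X, coefficients = coefs, fitted = fitted,
       residuals = res, rss = sum(res^2), n = length(y),
       p = length(features), features = features)
}

#' Deduplicate a design matrix
#'
#' Drops zero-variance columns and exact duplicates (keeping the first of
#' each duplicate group) before fitting, with a warning naming the dropped
#' columns.
#'
#' @param fm A `regdom_features` object.
#' @return The object with offending columns removed; dropped names in
#'   `attr(, "dropped")`.
#' @export
dedup_features <- function(fm) {
  S <- fm$S
  const <- apply(S, 2, function(x) max(x) == min(x))
  dup <- duplicated(t(S))
  drop <- const | dup
  if (any(drop)) {
    warn(paste0("dropping constant/duplicate feature column(s): ",
                paste(colnames(S)[drop], collapse = ", ")))
    fm$S <- S[, !drop, drop = FALSE]
    fm$feature_names <- colnames(fm$S)
    fm$location <- fm$location[!drop]
  }
  attr(fm, "dropped") <- colnames(S)[drop]
  fm
}

#' Fit the linear expression model
#'
#' Ordinary least squares of the log-scale response on all (or a subset of)
#' feature columns, with an intercept. Returns a `regdom_fit` carrying
#' coefficients, residuals, RSE, AIC, 5-fold cross-validated RSE and the
#' Pearson correlation of fitted vs observed response.
#'
#' @param fm A `regdom_features` object (see [assemble_feature_matrix()]).
#' @param features Feature names to include; default all.
#' @param cv_seed Seed fixing the cross-validation folds.
#' @return A `regdom_fit` object.
#' @export
fit_linear <- function(fm, features = fm$feature_names, cv_seed = 1L) {
  n <- length(fm$y)
  if (n <= length(features) + 2) {
    abort("need n_genes > n_features + 2")
  }
  fit <- ols_fit(fm$S, fm$y, features)
  folds <- make_cv_folds(fm$y, k = 5L, seed = cv_seed)
  cv <- cv_eval(fm$S, fm$y, features, folds)
  structure(
    list(feature_names = features,
         intercept = unname(fit$coefficients[1]),
         coefficients = fit$coefficients[-1],
         residuals = fit$residuals,
         fitted = fit$fitted,
         rse = rse_from_rss(fit$rss, n),
         aic = rss_aic(fit$rss, n, fit$p),
         cv_rse = cv$rse,
         cv_pred = cv$pred,
         pearson_r = if (sd(fit$fitted) > 0) cor(fit$fitted, fm$y) else NA_real_,
         n = n, location = fm$location[features],
         model_kind = fm$model_kind),
    class = "regdom_fit"
  )
}

#' @export
print.regdom_fit <- function(x, ...) {
  cat(sprintf("<regdom_fit> %d features, n = %d | RSE %.4f, CV-RSE %.4f, AIC %.1f, r %.3f\n",
              length(x$feature_names), x$n, x$rse, x$cv_rse, x$aic,
              x$pearson_r))
  invisible(x)
}

# Gene-level k-fold split stratified by response quintile.
make_cv_folds <- function(y, k = 5L, seed = 1L) {
  n <- length(y)
  strata <- cut(rank(y, ties.method = "first"),
                breaks = 5L, labels = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Mean per-fold held-out RSE plus the pooled held-out predictions.
cv_eval <- function(S, y, features, folds) {
  k <- max(folds)
  pred_all <- numeric(length(y))
  rses <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    X <- cbind(1, S[tr, features, drop = FALSE])
    cf <- qr.coef(qr(X), y[tr])
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, S[!tr, features, drop = FALSE]) %*% cf)
    pred_all[!tr] <<- pred
    rse_from_rss(sum((y[!tr] - pred)^2), sum(!tr))
  }, numeric(1))
  list(rse = mean(rses), pred = pred_all)
}

#' Stepwise AIC selection
#'
#' Starting from the full model, repeatedly applies the single feature
#' removal (and, for `direction = "both"`, addition) that most lowers
#' `AIC = n ln(RSS/n) + 2(p+1)`, until no move improves it. Single-move
#' deltas are computed exactly from the current fit's QR decomposition
#' rather than by refitting every candidate.
#'
#' The default is backward-only elimination: the removed set then still
#' contains features whose reintroduction can improve the model, which is
#' what gives [greedy_reintroduction()] its role. Running `"both"` to
#' convergence instead guarantees that no single re-addition can lower the
#' AIC, making the greedy stage a no-op under its conjunctive acceptance
#' rule.
#'
#' @param fm A `regdom_features` object (deduplicated internally).
#' @param direction `"backward"` (default) or `"both"`.
#' @param trace Print each accepted step?
#' @return List with `fit` (the reduced model M1, a `regdom_fit`),
#'   `removed` (features excluded from M1) and `fm` (the deduplicated
#'   feature object used).
#' @export
stepwise_aic <- function(fm, direction = c("backward", "both"),
                         trace = FALSE) {
  direction <- match.arg(direction)
  fm <- dedup_features(fm)
  S <- fm$S
  y <- fm$y
  n <- length(y)
  included <- colnames(S)
  repeat {
    fit <- ols_fit(S, y, included)
    aic_now <- rss_aic(fit$rss, n, fit$p)
    # exact drop-one RSS increase: coef^2 / [(X'X)^-1]_jj
    drop_aic <- setNames(numeric(0), character(0))
    if (fit$p > 0) {
      R <- qr.R(fit$qr)
      inv_pp <- diag(chol2inv(R))
      dj <- numeric(ncol(fit$X))
      dj[fit$qr$pivot] <- inv_pp # undo any column pivoting
      dj <- dj[-1]
      cf <- fit$coefficients[-1]
      drop_rss <- fit$rss + cf^2 / dj
      drop_aic <- rss_aic(drop_rss, n, fit$p - 1L)
      names(drop_aic) <- included
    }

    excluded <- if (direction == "both") setdiff(colnames(S), included) else character(0)
    add_aic <- setNames(numeric(0), character(0))
    if (length(excluded) > 0) {
      Q <- qr.Q(fit$qr)
      Xe <- S[, excluded, drop = FALSE]
      qtx <- crossprod(Q, Xe)
      xmx <- colSums(Xe^2) - colSums(qtx^2)
      xtr <- drop(crossprod(Xe, fit$residuals))
      gain <- ifelse(xmx > 1e-10, xtr^2 / xmx, 0)
      add_aic <- rss_aic(pmax(fit$rss - gain, 0), n, fit$p + 1L)
      names(add_aic) <- excluded
      add_aic <- add_aic[xmx > 1e-10]
    }

    cand <- c(drop_aic, add_aic)
    if (length(cand) == 0) break
    best <- which.min(cand)
    if (cand[best] >= aic_now - 1e-9) break
    feat <- names(cand)[best]
    if (feat %in% included) {
      included <- setdiff(included, feat)
      if (trace) inform(sprintf("step: - %s (AIC %.2f)", feat, cand[best]))
    } else {
      included <- c(included, feat)
      if (trace) inform(sprintf("step: + %s (AIC %.2f)", feat, cand[best]))
    }
  }
  list(fit = fit_linear(fm, included),
       removed = setdiff(colnames(S), included),
       fm = fm)
}

#' Greedy seeded reintroduction of removed features
#'
#' Visits the features removed by [stepwise_aic()] once each, in a seeded
#' random order. Each candidate forms a trial model (current + candidate),
#' accepted only if it improves both the AIC and the 5-fold
#' cross-validated RSE (folds fixed by the same seed).
#'
#' @param m1 List returned by [stepwise_aic()].
#' @param seed Seed controlling the visiting order and the CV folds.
#' @param require_both If `FALSE`, AIC improvement alone accepts a
#'   candidate.
#' @return A `regdom_fit` for the final model.
#' @export
greedy_reintroduction <- function(m1, seed = 1L, require_both = TRUE) {
  fm <- m1$fm
  removed <- m1$removed
  current <- fit_linear(fm, m1$fit$feature_names, cv_seed = seed)
  if (length(removed) == 0) return(current)
  order <- withr::with_seed(seed, sample(removed))
  for (cand in order) {
    trial <- fit_linear(fm, c(current$feature_names, cand), cv_seed = seed)
    ok <- trial$aic < current$aic &&
      (!require_both || trial$cv_rse < current$cv_rse)
    if (ok) current <- trial
  }
  current
}

#' Run the seeded selection ensemble
#'
#' Performs stepwise AIC selection once (it is deterministic), then the
#' greedy reintroduction with `n_runs` different seeds
#' (`base_seed .. base_seed + n_runs - 1`). Each feature's RC ensemble is
#' its coefficient in every run's final model, 0 when unselected.
#'
#' @param fm A `regdom_features` object.
#' @param n_runs Number of seeded runs (default 10).
#' @param base_seed First seed.
#' @param require_both Passed to [greedy_reintroduction()].
#' @param direction Passed to [stepwise_aic()].
#' @return A `regdom_ensemble` tibble: one row per feature with `feature`,
#'   `location`, `mean_rc`, `n_selected` and the per-run coefficients in the
#'   list-column `rcs`; attributes `mean_rse`, `pooled_pearson_r`, `n_runs`,
#'   `model_kind`, `fits`.
#' @export
run_ensemble <- function(fm, n_runs = 10L, base_seed = 1L,
                         require_both = TRUE,
                         direction = c("backward", "both")) {
  m1 <- stepwise_aic(fm, direction = direction)
  seeds <- base_seed + seq_len(n_runs) - 1L
  fits <- purrr::map(seeds, function(s) {
    greedy_reintroduction(m1, seed = s, require_both = require_both)
  })
  feats <- m1$fm$feature_names
  rc_mat <- matrix(0, nrow = length(feats), ncol = n_runs,
                   dimnames = list(feats, paste0("run", seq_len(n_runs))))
  for (r in seq_len(n_runs)) {
    cf <- fits[[r]]$coefficients
    rc_mat[names(cf), r] <- unname(cf)
  }
  res <- tibble(
    feature = feats,
    location = unname(m1$fm$location[feats]),
    mean_rc = rowMeans(rc_mat),
    n_selected = rowSums(rc_mat != 0),
    rcs = lapply(seq_along(feats), function(i) unname(rc_mat[i, ]))
  )
  # model comparison pools held-out (5-fold CV) predictions across runs
  pooled_pred <- unlist(purrr::map(fits, "cv_pred"))
  pooled_obs <- rep(unname(fm$y), n_runs)
  attr(res, "mean_rse") <- mean(purrr::map_dbl(fits, "rse"))
  attr(res, "mean_cv_rse") <- mean(purrr::map_dbl(fits, "cv_rse"))
  attr(res, "pooled_pearson_r") <-
    if (sd(pooled_pred) > 0) cor(pooled_pred, pooled_obs) else NA_real_
  attr(res, "n_runs") <- n_runs
  attr(res, "model_kind") <- fm$model_kind
  attr(res, "fits") <- fits
  class(res) <- c("regdom_ensemble", class(res))
  res
}

#' Test RC ensembles against zero
#'
#' One-sample two-tailed t-test of each feature's RC ensemble against 0,
#' Bonferroni-corrected over the number of features tested. A zero-variance
#' ensemble gets p = 1 when its mean is 0 and p = 0 otherwise (a constant
#' nonzero coefficient across seeds is unambiguous evidence of selection).
#'
#' @param ensembles A `regdom_ensemble` (see [run_ensemble()]).
#' @return The ensemble tibble with `t_stat`, `p_value`, `p_adjusted`,
#'   `significant` columns.
#' @export
test_rc_significance <- function(ensembles) {
  n_runs <- attr(ensembles, "n_runs") %||% length(ensembles$rcs[[1]])
  if (n_runs < 2) abort("t-test needs at least 2 runs")
  stats <- purrr::map(ensembles$rcs, function(rc) {
    s <- sd(rc)
    if (s == 0) {
      list(t = if (mean(rc) == 0) 0 else Inf,
           p = if (mean(rc) == 0) 1 else 0)
    } else {
      t <- mean(rc) / (s / sqrt(length(rc)))
      list(t = t, p = 2 * pt(abs(t), df = length(rc) - 1, lower.tail = FALSE))
    }
  })
  out <- ensembles
  out$t_stat <- purrr::map_dbl(stats, "t")
  out$p_value <- purrr::map_dbl(stats, "p")
  out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  out$significant <- out$p_adjusted < 0.05
  out
}

# Restrict a feature object to a gene subset.
subset_genes <- function(fm, gene_ids) {
  unknown <- setdiff(gene_ids, fm$gene_ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  fm$gene_ids <- gene_ids
  fm$S <- fm$S[gene_ids, , drop = FALSE]
  fm$y <- fm$y[gene_ids]
  fm
}

#' Compare model kinds (and their randomized twins) on gene sets
#'
#' Runs the full selection ensemble for every supplied feature matrix and
#' gene set, reporting the mean RSE across runs and the Pearson correlation
#' of pooled predictions.
#'
#' @param matrices Named list of `regdom_features` objects (e.g. B, BH, BL,
#'   BHL and randomized twins).
#' @param gene_sets Optional named list of gene-id vectors; default uses all
#'   genes of each matrix.
#' @param n_runs,base_seed Passed to [run_ensemble()].
#' @return Tibble `model`, `gene_set`, `n_genes`, `n_features`, `mean_rse`,
#'   `mean_cv_rse`, `pearson_r`.
#' @export
evaluate_models <- function(matrices, gene_sets = NULL, n_runs = 10L,
                            base_seed = 1L) {
  if (is.null(gene_sets)) gene_sets <- list(all = NULL)
  combos <- tidyr::expand_grid(model = names(matrices),
                               gene_set = names(gene_sets))
  purrr::pmap_dfr(combos, function(model, gene_set) {
    fm <- matrices[[model]]
    ids <- gene_sets[[gene_set]]
    if (!is.null(ids)) fm <- subset_genes(fm, ids)
    ens <- run_ensemble(fm, n_runs = n_runs, base_seed = base_seed)
    tibble(model = model, gene_set = gene_set,
           n_genes = length(fm$gene_ids),
           n_features = length(fm$feature_names),
           mean_rse = attr(ens, "mean_rse"),
           mean_cv_rse = attr(ens, "mean_cv_rse"),
           pearson_r = attr(ens, "pooled_pearson_r"))
  })
}
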