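#' Reduce a predictor block by PCA
#'
#' Centers the subjects-by-features matrix and keeps the first
#' `n_components` principal-component scores (fewer if rank-limited,
#' messaged). Loadings and the explained-variance spectrum are returned so
#' top feature contributors per PC can be reported.
#'
#' @param m Numeric matrix, subjects x features (rownames = subject ids).
#' @param n_components Number of PCs to keep (default 3).
#' @return list: `scores` (subjects x PCs), `loadings`,
#'   `explained_variance` (proportions).
#' @export
pca_reduce <- function(m, n_components = 3) {
  m <- as.matrix(m)
  if (nrow(m) < n_components + 2) stop("too few subjects for PCA reduction")
  if (all(apply(m, 2, stats::sd) == 0)) stop("zero-variance matrix")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  keep <- min(n_components, rank)
  if (keep < n_components)
    message(sprintf("rank-limited: keeping %d of %d requested PCs",
                    keep, n_components))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(keep), drop = FALSE],
       loadings = pc$rotation[, seq_len(keep), drop = FALSE],
       explained_variance = ev)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = n ln(rss/n) + 2k + 2k(k+1)/(n - k - 1), with k counting every
#' estimated parameter (intercept, covariate, predictors, residual
#' variance).
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares (> 0).
#' @param k_params Total parameter count k.
#' @return The AICc value.
#' @examples
#' aicc(20, 20, 3)  # 7.5
#' @export
aicc <- function(n, rss, k_params) {
  if (rss <= 0) stop("rss must be positive")
  if (n <= k_params + 1) stop("AICc undefined: n <= k + 1")
  n * log(rss / n) + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

fit_ols <- function(y, X) {
  # X: design without intercept column; returns fit stats used by the screen
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  n <- length(y)
  p_model <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  list(fit = fit, adj_r2 = sm$adj.r.squared, rss = rss, n = n,
       p_model = unname(p_model),
       coef = stats::coef(fit),
       coef_p = sm$coefficients[, "Pr(>|t|)"])
}

adj_r2_of <- function(y, block, covariate, subset) {
  X <- block[, subset, drop = FALSE]
  if (!is.null(covariate)) X <- cbind(dose_sex = covariate, X)
  fit_ols(y, X)$adj_r2
}

#' Best-subset regression by sequential replacement
#'
#' Selects the best 1- or 2-predictor ordinary least squares model of
#' `response` on a predictor block, always adjusted for `covariate`.
#' Search: the best single predictor by adjusted R-squared seeds the
#' size-2 search; one member is then swapped for any non-member while the
#' adjusted R-squared improves (sequential replacement); the best model of
#' each size competes by adjusted R-squared. Reported per model: selected
#' predictors, coefficients, adjusted R-squared, overall F-test p,
#' per-predictor t-test p, and AICc (k counts intercept, covariate,
#' predictors and residual variance). A selected pair whose design is
#' numerically collinear (condition number > 1e8) is replaced by the
#' next-best subset, with a message.
#'
#' @param response Numeric vector over subjects.
#' @param block Numeric matrix subjects x features (>= 1 column, named).
#' @param covariate Optional numeric/binary adjustment vector (the
#'   dose/sex covariate in a two-arm design).
#' @param max_predictors 1 or 2.
#' @return list of class `mlr_model`: predictors, beta, adj_r2, p_model,
#'   p_predictors, aicc, n.
#' @export
best_subset_mlr <- function(response, block, covariate = NULL,
                            max_predictors = 2) {
  block <- as.matrix(block)
  if (is.null(colnames(block)))
    colnames(block) <- paste0("X", seq_len(ncol(block)))
  keep <- stats::complete.cases(response, block,
                                if (is.null(covariate)) rep(0, length(response))
                                else covariate)
  response <- response[keep]
  block <- block[keep, , drop = FALSE]
  if (!is.null(covariate)) covariate <- covariate[keep]
  n <- length(response)
  n_cov <- if (is.null(covariate)) 0 else 1
  if (n < 2 + n_cov + max_predictors + 2)
    stop("too few subjects for the requested model size")
  feats <- colnames(block)
  usable <- feats[apply(block, 2, stats::sd) > 0]
  if (length(usable) < 1) stop("no usable (non-constant) feature in block")

  score <- function(subset) adj_r2_of(response, block, covariate, subset)
  # best single
  r2_single <- vapply(usable, function(f) score(f), numeric(1))
  best1 <- usable[which.max(r2_single)]
  best <- list(subset = best1, adj_r2 = max(r2_single))

  if (max_predictors >= 2 && length(usable) >= 2) {
    # forward step from the best single, then sequential replacement
    others <- setdiff(usable, best1)
    r2_add <- vapply(others, function(f) score(c(best1, f)), numeric(1))
    cur <- c(best1, others[which.max(r2_add)])
    cur_r2 <- max(r2_add)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_along(cur)) {
        for (f in setdiff(usable, cur)) {
          cand <- cur; cand[i] <- f
          r2 <- score(cand)
          if (r2 > cur_r2 + 1e-12) {
            cur <- cand; cur_r2 <- r2; improved <- TRUE
          }
        }
      }
    }
    # collinearity guard on the selected pair
    if (kappa(cbind(1, block[, cur, drop = FALSE]), exact = TRUE) > 1e8) {
      message("collinear pair replaced by next-best subset")
      pairs <- utils::combn(usable, 2, simplify = FALSE)
      r2s <- vapply(pairs, score, numeric(1))
      for (j in order(r2s, decreasing = TRUE)) {
        if (kappa(cbind(1, block[, pairs[[j]], drop = FALSE]), exact = TRUE) <= 1e8) {
          cur <- pairs[[j]]; cur_r2 <- r2s[j]; break
        }
      }
    }
    if (cur_r2 > best$adj_r2) best <- list(subset = cur, adj_r2 = cur_r2)
  }

  X <- block[, best$subset, drop = FALSE]
  if (!is.null(covariate)) X <- cbind(dose_sex = covariate, X)
  f <- fit_ols(response, X)
  k <- 1 + ncol(X) + 1  # intercept + design columns + residual variance
  structure(list(
    predictors = best$subset,
    beta = f$coef[best$subset],
    adj_r2 = f$adj_r2,
    p_model = f$p_model,
    p_predictors = f$coef_p[best$subset],
    aicc = aicc(f$n, f$rss, k),
    n = f$n), class = "mlr_model")
}

#' Relative AICc matrix
#'
#' Converts a grid of AICc values to percentages of the worst (highest)
#' model: cell = 100 * AICc / max(AICc); lower percentages mark
#' higher-quality models. When any AICc is non-positive the whole grid is
#' first shifted so its minimum equals 1 (messaged) — the ratio formula
#' presumes positive values.
#'
#' @param values Numeric vector or matrix of AICc values.
#' @return Same shape, percentages in (0, 100].
#' @export
relative_aicc_matrix <- function(values) {
  stopifnot(length(values) > 0)
  v <- values
  ok <- !is.na(v)
  if (any(v[ok] <= 0)) {
    message("non-positive AICc present; grid shifted so the minimum equals 1")
    v[ok] <- v[ok] - min(v[ok]) + 1
  }
  v[ok] <- 100 * v[ok] / max(v[ok])
  v
}

#' Predictability screen: responses x predictor blocks
#'
#' Fits one [best_subset_mlr()] per (response, block) cell with a common
#' covariate, applies BH-FDR over the model p values of the whole screen,
#' and computes relative AICc within each response (so models predicting
#' the same response are comparable). Cells whose block has no usable
#' feature are skipped with a message.
#'
#' @param responses Named list of numeric response vectors (same subject
#'   order).
#' @param blocks Named list of predictor matrices.
#' @param covariate Common adjustment vector (dose/sex).
#' @param max_predictors Passed to [best_subset_mlr()].
#' @param q_threshold Significance level on q (default 0.05).
#' @return data.frame of class `mlr_screen`: response, block, predictors,
#'   beta, adj_r2, p, q, p_predictors, aicc, rel_aicc, significant, n.
#' @export
predictability_screen <- function(responses, blocks, covariate = NULL,
                                  max_predictors = 2, q_threshold = 0.05) {
  rows <- list()
  for (rn in names(responses)) for (bn in names(blocks)) {
    cell <- tryCatch(
      best_subset_mlr(responses[[rn]], blocks[[bn]], covariate,
                      max_predictors = max_predictors),
      error = function(e) {
        message(sprintf("cell (%s, %s) skipped: %s", rn, bn, conditionMessage(e)))
        NULL
      })
    if (is.null(cell)) next
    rows[[length(rows) + 1]] <- data.frame(
      response = rn, block = bn,
      predictors = paste(cell$predictors, collapse = "+"),
      beta = paste(sprintf("%.4g", cell$beta), collapse = ","),
      adj_r2 = cell$adj_r2, p = cell$p_model,
      p_predictors = paste(sprintf("%.4g", cell$p_predictors), collapse = ","),
      aicc = cell$aicc, n = cell$n, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no screen cell could be fitted")
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$rel_aicc <- NA_real_
  for (rn in unique(out$response)) {
    idx <- out$response == rn
    out$rel_aicc[idx] <- relative_aicc_matrix(out$aicc[idx])
  }
  out$significant <- out$q < q_threshold
  class(out) <- c("mlr_screen", class(out))
  out
}
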