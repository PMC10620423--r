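# Per-phenotype scoring engine. For each term, a ridge-penalized logistic
# regression of the term's gene annotations on the merged eigenvector
# loadings yields a gene log-odds score
#   log_odds_g = beta_0 + beta_1 * loading_g1 + ... + beta_K * loading_gK.
# Annotated genes are scored leave-one-out (refit without the gene) to block
# label leakage; a permutation null (labels reassigned uniformly at random,
# model refit, log-odds pooled over genes and permutations) converts log-odds
# to calibrated per-term z-scores.

# Penalized IRLS. X must contain the intercept as its first column; the L2
# penalty applies to all coefficients except the intercept. Maximizes
# loglik(beta) - (lambda/2) * sum(beta[-1]^2).
ridge_logistic_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 1000,
                               beta_init = NULL) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1))
  beta <- beta_init %||% c(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)),
                           rep(0, p - 1))
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      if (lambda == 0) {
        stop_nephronet(
          "logistic fit did not converge (labels may be perfectly separable); supply ridge_penalty > 0",
          "nephronet_convergence_error")
      }
      stop_nephronet("logistic fit failed: singular penalized Hessian",
                     "nephronet_convergence_error")
    }
    # step-halving keeps the penalized likelihood monotone
    step <- 1
    repeat {
      cand <- beta + step * delta
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; f_new <- f_old; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand
    f_old <- f_new
    if (moved < tol) { converged <- TRUE; break }
    if (lambda == 0 && max(abs(beta)) > 1e3) {
      stop_nephronet(
        "logistic fit diverging (perfect separation); supply ridge_penalty > 0",
        "nephronet_convergence_error")
    }
  }
  if (!converged && lambda == 0) {
    stop_nephronet(
      "logistic fit did not converge within max_iter; supply ridge_penalty > 0",
      "nephronet_convergence_error")
  }
  list(beta = beta, converged = converged, n_iter = it)
}

# The L2 penalty is applied on per-column standardized features (mean 0,
# sd 1 across genes) so its strength does not depend on how the loadings are
# normalized (unit-norm singular vectors have entries ~ 1/sqrt(n_genes),
# which would otherwise let a fixed penalty crush every coefficient at genome
# scale). Coefficients are back-transformed to the input loading scale.
standardize_columns <- function(L) {
  center <- colMeans(L)
  sc <- apply(L, 2, sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  list(X = sweep(sweep(L, 2, center), 2, sc, "/"), center = center, scale = sc)
}

backtransform_beta <- function(beta_std, center, scale) {
  coefs <- beta_std[-1] / scale
  list(intercept = unname(beta_std[1] - sum(beta_std[-1] * center / scale)),
       coefficients = coefs)
}

# Normalize a label argument to a 0/1 vector aligned with `genes`. Accepts a
# character vector of positive gene IDs, or a (named) logical/numeric vector.
align_labels <- function(labels, genes, what = "labels") {
  if (is.character(labels)) {
    unknown <- setdiff(labels, genes)
    if (length(unknown)) {
      stop_nephronet(sprintf("%s name gene(s) absent from the components: %s",
                             what, paste(head(unknown, 5), collapse = ", ")),
                     "nephronet_alignment_error")
    }
    return(as.integer(genes %in% labels))
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop_nephronet(sprintf("%s must be binary (0/1 or logical) or positive gene IDs", what),
                   "nephronet_format_error")
  }
  if (!is.null(names(labels))) {
    if (!all(genes %in% names(labels))) {
      stop_nephronet(sprintf("%s do not cover every component gene", what),
                     "nephronet_alignment_error")
    }
    return(as.integer(labels[genes]))
  }
  if (length(labels) != length(genes)) {
    stop_nephronet(sprintf("%s length (%d) does not match gene count (%d)",
                           what, length(labels), length(genes)),
                   "nephronet_alignment_error")
  }
  as.integer(labels)
}

#' Fit one phenotype's ridge-penalized logistic model
#'
#' Regresses a term's binary gene annotations on the merged eigenvector
#' loadings. The L2 penalty applies to the component coefficients, not the
#' intercept; with hundreds of components and tens of positives an unpenalized
#' fit is fragile, so the default penalty is 1 (set 0 for plain maximum
#' likelihood). The penalty acts on per-column standardized features (mean 0,
#' sd 1 across genes) so its strength is independent of the loading
#' normalization; the returned coefficients are on the input loading scale.
#'
#' @param components A [merge_components()] / [as_merged_components()] result
#'   (or an `eigenvector_matrix`).
#' @param labels Positive genes: a character vector of gene IDs, or a binary /
#'   logical vector aligned to (or named by) the component genes.
#' @param ridge_penalty Nonnegative L2 penalty on the coefficients.
#' @param term_id Optional term identifier stored in the model.
#' @return A `phenotype_model`: `term_id`, `intercept`, `coefficients`
#'   (named by component), `ridge_penalty`, `n_positives`, `converged`,
#'   `n_iter`.
#' @export
fit_term_model <- function(components, labels, ridge_penalty = 1, term_id = NULL) {
  L <- loading_matrix(components)
  y <- align_labels(labels, rownames(L))
  if (sum(y) < 1 || sum(1 - y) < 1) {
    stop_nephronet("need at least one positive and one negative gene",
                   "nephronet_degenerate_error")
  }
  if (!is.numeric(ridge_penalty) || ridge_penalty < 0) {
    stop_nephronet("ridge_penalty must be >= 0", "nephronet_config_error")
  }
  std <- standardize_columns(L)
  X <- cbind(`(Intercept)` = 1, std$X)
  fit <- ridge_logistic_fit(X, y, ridge_penalty)
  bt <- backtransform_beta(fit$beta, std$center, std$scale)
  structure(
    list(term_id = term_id %||% NA_character_,
         intercept = bt$intercept,
         coefficients = setNames(bt$coefficients, colnames(L)),
         ridge_penalty = ridge_penalty,
         n_positives = sum(y),
         converged = fit$converged,
         n_iter = fit$n_iter),
    class = "phenotype_model"
  )
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("<phenotype_model> term %s: %d positives, %d components, ridge %g, %s in %d iter\n",
              x$term_id, x$n_positives, length(x$coefficients), x$ridge_penalty,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

log_odds_vec <- function(beta0, coefs, L) {
  drop(beta0 + L %*% coefs)
}

#' Gene log-odds scores under a fitted phenotype model
#'
#' `score_g = beta_0 + sum_i beta_i * loading[g, i]`.
#'
#' @param model A [fit_term_model()] result.
#' @param components Component loadings with the same columns the model was
#'   trained on.
#' @return Tibble `gene_id`, `log_odds`.
#' @export
gene_log_odds <- function(model, components) {
  stopifnot(inherits(model, "phenotype_model"))
  L <- loading_matrix(components)
  if (ncol(L) != length(model$coefficients) ||
      !identical(colnames(L), names(model$coefficients))) {
    stop_nephronet("component columns do not match the model's coefficients",
                   "nephronet_alignment_error")
  }
  tibble(gene_id = rownames(L),
         log_odds = unname(log_odds_vec(model$intercept, model$coefficients, L)))
}

#' Leave-one-out gene log-odds for a term
#'
#' Every annotated (positive) gene is scored by a model refit with that gene
#' removed from training, so its own label cannot inflate its score; negatives
#' and unlabeled genes are scored by the full model (bit-identical to
#' [gene_log_odds()] for those genes).
#'
#' @inheritParams fit_term_model
#' @return Tibble `gene_id`, `log_odds`, `loo` (TRUE where the score came
#'   from a leave-one-out refit).
#' @export
loo_log_odds <- function(components, labels, ridge_penalty = 1) {
  L <- loading_matrix(components)
  y <- align_labels(labels, rownames(L))
  if (sum(y) < 2) {
    stop_nephronet(
      "leave-one-out needs at least 2 positives (a refit would lose every positive)",
      "nephronet_degenerate_error")
  }
  std <- standardize_columns(L)
  X <- cbind(`(Intercept)` = 1, std$X)
  full <- ridge_logistic_fit(X, y, ridge_penalty)
  bt <- backtransform_beta(full$beta, std$center, std$scale)
  # score through the back-transformed model so unlabeled genes are
  # bit-identical to gene_log_odds() of the full model
  scores <- log_odds_vec(bt$intercept, bt$coefficients, L)
  pos_idx <- which(y == 1)
  for (i in pos_idx) {
    refit <- ridge_logistic_fit(X[-i, , drop = FALSE], y[-i], ridge_penalty,
                                beta_init = full$beta)
    bt_i <- backtransform_beta(refit$beta, std$center, std$scale)
    scores[i] <- bt_i$intercept + sum(bt_i$coefficients * L[i, ])
  }
  tibble(gene_id = rownames(L), log_odds = unname(scores),
         loo = seq_along(y) %in% pos_idx)
}

#' z-score from an explicit null pool
#'
#' `z = (observed - mean(pool)) / sd(pool)`; the calibration step shared by
#' [permutation_null_z()].
#'
#' @param observed Observed log-odds (vector).
#' @param null_pool Pooled null log-odds values.
#' @return Numeric z-scores, same length as `observed`.
#' @export
null_z <- function(observed, null_pool) {
  s <- sd(null_pool)
  if (!is.finite(s) || s == 0) {
    stop_nephronet("null distribution is degenerate (sd = 0)",
                   "nephronet_degenerate_error")
  }
  (observed - mean(null_pool)) / s
}

#' Permutation-calibrated z-scores for one term
#'
#' For each permutation, the term's positive-label count is reassigned
#' uniformly at random over genes, the ridge-logistic model is refit, and the
#' resulting log-odds of all genes are pooled into the term's null. Observed
#' leave-one-out log-odds are then standardized against the pooled null.
#'
#' @inheritParams fit_term_model
#' @param n_permutations Number of label permutations (>= 100; the pooled
#'   null draws `n_permutations * n_genes` values, so modest permutation
#'   counts already give a stable sd).
#' @param seed Seed; results are deterministic given it.
#' @return List: `scores` (tibble `gene_id`, `log_odds`, `loo`, `z`),
#'   `null_mean`, `null_sd`, `n_permutations`, `seed`.
#' @export
permutation_null_z <- function(components, labels, ridge_penalty = 1,
                               n_permutations = 200, seed = 1) {
  if (!is_count_scalar(n_permutations) || n_permutations < 100) {
    stop_nephronet("n_permutations must be an integer >= 100",
                   "nephronet_config_error")
  }
  L <- loading_matrix(components)
  y <- align_labels(labels, rownames(L))
  obs <- loo_log_odds(components, y, ridge_penalty)
  std <- standardize_columns(L)
  X <- cbind(`(Intercept)` = 1, std$X)
  n_pos <- sum(y)
  pool <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      yp <- integer(length(y))
      yp[sample(length(y), n_pos)] <- 1L
      fit <- ridge_logistic_fit(X, yp, ridge_penalty)
      drop(X %*% fit$beta)
    }, numeric(length(y)))
  })
  z <- null_z(obs$log_odds, pool)
  list(scores = mutate(obs, z = z),
       null_mean = mean(pool), null_sd = sd(pool),
       n_permutations = n_permutations, seed = seed)
}

#' Score every term of an annotation set against merged components
#'
#' Runs [loo_log_odds()] and [permutation_null_z()] per term. Terms with
#' fewer than two positives among the component genes are skipped with a
#' warning (a leave-one-out refit would lose every positive). Per-term
#' permutation seeds are derived deterministically from `seed` and the term
#' ID, so results do not depend on term order.
#'
#' @inheritParams fit_term_model
#' @param annotations An [annotation_set()] (typically after
#'   [filter_annotations()]).
#' @param n_permutations Permutations per term; `0` skips z-score calibration
#'   (z columns are `NA`), which is enough for rank-based evaluation since z
#'   is a per-term affine transform of the leave-one-out log-odds.
#' @param seed Global seed for the permutation nulls.
#' @return A `prediction_matrix`: `z` and `log_odds` (gene x term matrices),
#'   `null_params` (tibble per term), `annotations`, `skipped_terms`.
#' @export
predict_terms <- function(components, annotations, ridge_penalty = 1,
                          n_permutations = 200, seed = 1) {
  stopifnot(inherits(annotations, "annotation_set"))
  L <- loading_matrix(components)
  genes <- rownames(L)
  amat <- annotation_matrix(annotations, genes = genes)
  term_ids <- colnames(amat)

  z <- matrix(NA_real_, length(genes), 0, dimnames = list(genes, NULL))
  lo <- z
  null_params <- list()
  skipped <- character()
  for (t in term_ids) {
    y <- amat[, t]
    if (sum(y) < 2) {
      warn(sprintf("predict_terms(): skipping term %s (%d positive gene(s) among components)",
                   t, sum(y)))
      skipped <- c(skipped, t)
      next
    }
    if (n_permutations == 0) {
      obs <- loo_log_odds(components, y, ridge_penalty)
      lo <- cbind(lo, obs$log_odds)
      z <- cbind(z, NA_real_)
      null_params[[t]] <- tibble(term_id = t, null_mean = NA_real_,
                                 null_sd = NA_real_, n_permutations = 0L,
                                 seed = NA_integer_, n_positives = sum(y))
    } else {
      res <- permutation_null_z(components, y, ridge_penalty, n_permutations,
                                seed = derive_seed(seed, t))
      lo <- cbind(lo, res$scores$log_odds)
      z <- cbind(z, res$scores$z)
      null_params[[t]] <- tibble(term_id = t, null_mean = res$null_mean,
                                 null_sd = res$null_sd,
                                 n_permutations = n_permutations,
                                 seed = res$seed, n_positives = sum(y))
    }
    colnames(lo)[ncol(lo)] <- t
    colnames(z)[ncol(z)] <- t
  }
  structure(
    list(z = z, log_odds = lo, null_params = bind_rows(null_params),
         annotations = annotations, skipped_terms = skipped,
         ridge_penalty = ridge_penalty),
    class = "prediction_matrix"
  )
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d genes x %d terms (%d skipped)\n",
              nrow(x$log_odds), ncol(x$log_odds), length(x$skipped_terms)))
  invisible(x)
}

#' Gene-gene co-regulation z-score
#'
#' Pearson correlation of two genes' component-loading vectors, Fisher
#' r-to-z transformed: `z = atanh(r) * sqrt(K - 3)` over K components. High
#' values mean the two genes sit in the same transcriptional programs (the
#' statistic behind "highly co-regulated" gene pairs).
#'
#' @inheritParams fit_term_model
#' @param gene_a,gene_b Gene IDs present in the components.
#' @return A single z value. Self-correlation (r = 1) is capped at
#'   `atanh(1 - 1e-15) * sqrt(K - 3)` with a warning.
#' @export
coregulation_z <- function(components, gene_a, gene_b) {
  L <- loading_matrix(components)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(L)) {
      stop_nephronet(sprintf("gene %s absent from the components", g),
                     "nephronet_alignment_error")
    }
  }
  k <- ncol(L)
  if (k < 4) {
    stop_nephronet("co-regulation z needs at least 4 components",
                   "nephronet_dimension_error")
  }
  a <- L[gene_a, ]; b <- L[gene_b, ]
  if (sd(a) == 0 || sd(b) == 0) {
    stop_nephronet("a gene has a zero-variance loading vector; correlation undefined",
                   "nephronet_degenerate_error")
  }
  r <- cor(a, b)
  if (abs(r) >= 1 - 1e-15) {
    warn("coregulation_z(): |r| = 1; z capped at the atanh(1 - 1e-15) sentinel")
    r <- sign(r) * (1 - 1e-15)
  }
  atanh(r) * sqrt(k - 3)
}
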