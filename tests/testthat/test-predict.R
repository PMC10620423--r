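# Independent oracle: maximize the penalized log-likelihood directly with
# optim() on the same standardized-feature objective, then back-transform.
ridge_logistic_oracle <- function(L, y, lambda) {
  ctr <- colMeans(L)
  sc <- apply(L, 2, sd)
  X <- cbind(1, sweep(sweep(L, 2, ctr), 2, sc, "/"))
  negobj <- function(b) {
    eta <- drop(X %*% b)
    -(sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(b[-1]^2))
  }
  fit <- optim(rep(0, ncol(X)), negobj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  b <- fit$par
  c(intercept = b[1] - sum(b[-1] * ctr / sc), b[-1] / sc)
}

test_that("ridge-logistic coefficients match an independent optimizer on a toy", {
  set.seed(41)
  L <- matrix(rnorm(20 * 2), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("C1", "C2")))
  y <- as.integer(L[, 1] + 0.5 * rnorm(20) > 0)
  model <- fit_term_model(make_merged(L), y, ridge_penalty = 1)
  oracle <- ridge_logistic_oracle(L, y, 1)
  expect_equal(model$intercept, unname(oracle["intercept"]), tolerance = 1e-5)
  expect_equal(unname(model$coefficients), unname(oracle[-1]), tolerance = 1e-5)
  expect_true(model$converged)
})

test_that("uninformative labels give near-zero coefficients and a prevalence intercept", {
  L <- random_loadings(2000, 5, seed = 42)
  set.seed(43)
  y <- integer(2000); y[sample(2000, 200)] <- 1L
  model <- fit_term_model(make_merged(L), y, ridge_penalty = 1)
  # coefficients on the original scale are large numbers; compare their
  # contribution to the linear predictor instead
  contrib <- apply(L, 2, sd) * model$coefficients
  expect_lt(max(abs(contrib)), 0.15)
  expect_equal(model$intercept, qlogis(0.1), tolerance = 0.2)
})

test_that("a single informative component earns the dominant positive coefficient", {
  set.seed(44)
  n <- 60
  L <- cbind(C1 = c(rep(1, 15), rep(-1, 45)) + rnorm(n, sd = 0.05),
             C2 = rnorm(n), C3 = rnorm(n))
  rownames(L) <- sprintf("G%02d", 1:n)
  y <- c(rep(1L, 15), rep(0L, 45))
  model <- fit_term_model(make_merged(L), y, ridge_penalty = 1)
  std_coefs <- model$coefficients * apply(L, 2, sd)
  expect_gt(std_coefs["C1"], 0)
  expect_gt(std_coefs["C1"], 3 * max(abs(std_coefs[c("C2", "C3")])))
})

test_that("perfect separation without a penalty is a convergence error", {
  L <- cbind(C1 = c(rep(2, 5), rep(-2, 15)))
  rownames(L) <- sprintf("G%02d", 1:20)
  y <- c(rep(1L, 5), rep(0L, 15))
  expect_error(fit_term_model(make_merged(L), y, ridge_penalty = 0),
               "penalty", class = "nephronet_convergence_error")
  # the penalized fit handles the same labels fine
  expect_s3_class(fit_term_model(make_merged(L), y, ridge_penalty = 1),
                  "phenotype_model")
})

test_that("label handling validates alignment and degenerate cases", {
  L <- random_loadings(30, 3, seed = 45)
  mc <- make_merged(L)
  expect_error(fit_term_model(mc, rep(1L, 30)), class = "nephronet_degenerate_error")
  expect_error(fit_term_model(mc, c("NOT_A_GENE")), class = "nephronet_alignment_error")
  expect_error(fit_term_model(mc, rep(0L, 10)), class = "nephronet_alignment_error")
  # character positives and aligned binary labels agree
  pos <- rownames(L)[1:5]
  m1 <- fit_term_model(mc, pos)
  m2 <- fit_term_model(mc, as.integer(rownames(L) %in% pos))
  expect_equal(m1$coefficients, m2$coefficients)
})

test_that("gene log-odds is the stated linear score", {
  L <- matrix(c(0.3, 0.1,
                0, 0,
                1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("C1", "C2")))
  model <- structure(list(term_id = "T", intercept = 0.5,
                          coefficients = c(C1 = 1, C2 = -2),
                          ridge_penalty = 1, n_positives = 2,
                          converged = TRUE, n_iter = 1),
                     class = "phenotype_model")
  lo <- gene_log_odds(model, make_merged(L))
  expect_equal(lo$log_odds[lo$gene_id == "g1"], 0.5 + 0.3 - 0.2)  # 0.6
  expect_equal(lo$log_odds[lo$gene_id == "g2"], 0.5)              # zero loadings
  model0 <- model; model0$coefficients[] <- 0
  expect_equal(gene_log_odds(model0, make_merged(L))$log_odds, rep(0.5, 3))
  # linearity: score(a + b) = score(a) + score(b) - intercept
  L2 <- rbind(L, g4 = L["g1", ] + L["g3", ])
  lo2 <- gene_log_odds(model, make_merged(L2))$log_odds
  expect_equal(lo2[4], lo2[1] + lo2[3] - 0.5)
  # mismatched columns are an alignment error
  expect_error(gene_log_odds(model, make_merged(L[, 1, drop = FALSE])),
               class = "nephronet_alignment_error")
})

test_that("leave-one-out scoring blocks label leakage without touching negatives", {
  set.seed(46)
  n <- 60
  # positives share C1; one positive ("singleton") is alone on C3
  L <- cbind(C1 = c(rep(1.5, 8), rep(0, n - 8)) + rnorm(n, sd = 0.1),
             C2 = rnorm(n),
             C3 = c(rep(0, 8), 2, rep(0, n - 9)) + rnorm(n, sd = 0.05))
  rownames(L) <- sprintf("G%02d", 1:n)
  y <- c(rep(1L, 9), rep(0L, n - 9))
  mc <- make_merged(L)

  loo <- loo_log_odds(mc, y, ridge_penalty = 1)
  full <- gene_log_odds(fit_term_model(mc, y, ridge_penalty = 1), mc)

  # unlabeled genes: bit-identical to the full model
  expect_identical(loo$log_odds[10:n], full$log_odds[10:n])
  expect_identical(loo$loo, c(rep(TRUE, 9), rep(FALSE, n - 9)))
  # the singleton-information positive must drop under LOO
  expect_lt(loo$log_odds[9], full$log_odds[9])

  # a duplicated positive (identical loadings) retains its information
  L2 <- rbind(L[1:8, ], twin = L[1, ], L[9:n, ])
  y2 <- c(rep(1L, 9), y[9:n])
  rownames(L2)[1:9] <- sprintf("P%02d", 1:9)
  mc2 <- make_merged(L2)
  loo2 <- loo_log_odds(mc2, y2, ridge_penalty = 1)
  full2 <- gene_log_odds(fit_term_model(mc2, y2, ridge_penalty = 1), mc2)
  drop_twin <- abs(full2$log_odds[9] - loo2$log_odds[9])
  drop_singleton <- full$log_odds[9] - loo$log_odds[9]
  expect_lt(drop_twin, 0.3 * drop_singleton)

  # a single positive cannot be scored leave-one-out
  expect_error(loo_log_odds(mc, c(1L, rep(0L, n - 1))),
               class = "nephronet_degenerate_error")
})

test_that("null_z standardizes against an explicit pool", {
  expect_equal(null_z(3, c(1, 2, 3)), (3 - 2) / sd(c(1, 2, 3)))
  expect_equal(null_z(2, c(1, 2, 3)), 0)
  expect_error(null_z(1, c(2, 2, 2)), class = "nephronet_degenerate_error")
})

test_that("permutation z-scores are reproducible given the seed", {
  L <- random_loadings(80, 4, seed = 47)
  set.seed(48)
  y <- integer(80); y[sample(80, 10)] <- 1L
  mc <- make_merged(L)
  r1 <- permutation_null_z(mc, y, n_permutations = 100, seed = 7)
  r2 <- permutation_null_z(mc, y, n_permutations = 100, seed = 7)
  expect_identical(r1, r2)
  r3 <- permutation_null_z(mc, y, n_permutations = 100, seed = 8)
  expect_false(identical(r1$null_mean, r3$null_mean))
  expect_error(permutation_null_z(mc, y, n_permutations = 10),
               class = "nephronet_config_error")
  expect_true(all(is.finite(r1$scores$z)))
  expect_gt(r1$null_sd, 0)
})

test_that("predict_terms scores all evaluable terms and skips tiny ones", {
  fix <- small_pipeline(seed = 51, n_permutations = 0)
  anns <- fix$study$annotations
  # add a term with a single positive: must be skipped with a warning
  assoc <- dplyr::bind_rows(anns$associations,
                            tibble::tibble(gene_id = "G00001", term_id = "TINY",
                                           term_name = "tiny", provenance = "",
                                           line = 999L))
  anns2 <- annotation_set(assoc)
  expect_warning(pred <- predict_terms(fix$components, anns2, n_permutations = 0),
                 "TINY")
  expect_identical(pred$skipped_terms, "TINY")
  expect_setequal(colnames(pred$log_odds), anns$terms$term_id)
  # z-free mode leaves z as NA but fills log-odds
  expect_true(all(is.na(pred$z)))
  expect_true(all(is.finite(pred$log_odds)))
})

test_that("co-regulation z follows the Fisher transform of loading correlation", {
  # K = 10 toy with known correlation
  set.seed(52)
  a <- rnorm(10)
  e <- residuals(lm(rnorm(10) ~ a))
  rho <- 0.8
  b <- rho * scale(a)[, 1] + sqrt(1 - rho^2) * scale(e)[, 1]
  r <- cor(a, b)  # computed independently of the package
  L <- rbind(ga = a, gb = b, gc = rep(1, 10))
  colnames(L) <- paste0("C", 1:10)
  mc <- make_merged(L)
  expect_equal(coregulation_z(mc, "ga", "gb"), atanh(r) * sqrt(10 - 3))

  # exactly orthogonal (after centering) vectors give z = 0
  L2 <- rbind(g1 = rep(c(1, -1), 4), g2 = rep(c(1, 1, -1, -1), 2))
  colnames(L2) <- paste0("C", 1:8)
  expect_equal(coregulation_z(make_merged(L2), "g1", "g2"), 0)

  # self-correlation is capped with a warning, not infinite
  expect_warning(zc <- coregulation_z(mc, "ga", "ga"), "capped")
  expect_true(is.finite(zc))
  expect_equal(zc, atanh(1 - 1e-15) * sqrt(7))

  # degenerate inputs
  expect_error(coregulation_z(mc, "ga", "gc"), class = "nephronet_degenerate_error")
  expect_error(coregulation_z(mc, "ga", "NOPE"), class = "nephronet_alignment_error")
  L3 <- L[, 1:3]
  expect_error(coregulation_z(make_merged(L3), "ga", "gb"),
               class = "nephronet_dimension_error")
})

test_that("genes in the same planted module are strongly co-regulated", {
  fix <- small_pipeline(seed = 53, n_permutations = 0)
  mod1 <- fix$study$modules[[1]]
  z_within <- coregulation_z(fix$components, mod1[1], mod1[2])
  z_across <- coregulation_z(fix$components, mod1[1], fix$study$modules[[3]][1])
  expect_gt(z_within, 3)
  expect_gt(z_within, z_across + 2)
})
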