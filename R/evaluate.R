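# Per-term prediction accuracy and between-network comparison.
#
# AUC is the Mann-Whitney U statistic normalized by n_pos * n_neg (midrank
# ties); significance comes from the two-sided Mann-Whitney test. Paired
# network comparison uses the DeLong structural-components estimator for the
# variance of an AUC difference.

#' AUC and two-sided Mann-Whitney test for one score vector
#'
#' AUC = U / (n_pos * n_neg) with midrank tie handling. The p-value uses the
#' exact null distribution when there are no ties and at most 20 observations,
#' and the normal approximation with tie-corrected variance and continuity
#' correction otherwise.
#'
#' @param scores Numeric prediction scores, one per gene.
#' @param labels Binary labels (1 = annotated gene), same length.
#' @return List: `auc`, `p_value`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !all(labels %in% c(0L, 1L))) {
    stop_nephronet("scores and binary labels must align", "nephronet_format_error")
  }
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n2 <- sum(labels == 0L)
  if (n1 == 0 || n2 == 0) {
    stop_nephronet("evaluation needs at least one positive and one negative",
                   "nephronet_degenerate_error")
  }
  r <- rank(scores)  # midranks
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)

  n <- n1 + n2
  ties <- table(scores)
  has_ties <- any(ties > 1)
  if (!has_ties && n <= 20) {
    # exact two-sided p from the null U distribution (symmetric)
    p <- min(1, 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2)))
  } else {
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # every score tied
    } else {
      dev <- U - n1 * n2 / 2
      dev <- dev - sign(dev) * 0.5  # continuity correction toward the mean
      p <- min(1, 2 * pnorm(-abs(dev) / sqrt(sigma2)))
    }
  }
  list(auc = auc, p_value = p, n_pos = n1, n_neg = n2)
}

#' Bonferroni significance flags
#'
#' @param p_values Per-term p-values in (0, 1].
#' @param alpha Family-wise error rate.
#' @return Logical vector: `p < alpha / n_terms` (strict).
#' @export
bonferroni_flags <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop_nephronet("p-values must lie in (0, 1]", "nephronet_format_error")
  }
  p_values < alpha / length(p_values)
}

# Placement values via midranks (the fast DeLong computation): for positives,
# V10_i = (global midrank - within-positive midrank) / n_neg, and dually for
# negatives.
placements <- function(scores, is_pos) {
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  r_all <- rank(scores)
  v10 <- (r_all[is_pos] - rank(scores[is_pos])) / n2
  v01 <- 1 - (r_all[!is_pos] - rank(scores[!is_pos])) / n1
  # same U/(n1*n2) arithmetic as the Mann-Whitney AUC, for bit-identity
  auc <- (sum(r_all[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' DeLong test for two correlated AUCs
#'
#' Structural-components estimator of `var(auc_a - auc_b)` from per-positive
#' and per-negative placement values of both classifiers;
#' `z = (auc_a - auc_b) / sqrt(var)`, two-sided normal p.
#'
#' @param scores_a,scores_b Score vectors from the two classifiers over the
#'   same genes.
#' @param labels Shared binary labels; needs >= 2 positives and >= 2 negatives.
#' @return List: `auc_a`, `auc_b`, `var_diff`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop_nephronet("score vectors and labels must align", "nephronet_format_error")
  }
  is_pos <- labels == 1L
  if (sum(is_pos) < 2 || sum(!is_pos) < 2) {
    stop_nephronet("DeLong needs >= 2 positives and >= 2 negatives",
                   "nephronet_degenerate_error")
  }
  pa <- placements(scores_a, is_pos)
  pb <- placements(scores_b, is_pos)
  d_auc <- pa$auc - pb$auc
  if (identical(scores_a, scores_b)) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0, z = 0, p_value = 1))
  }
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / sum(is_pos) +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / sum(!is_pos)
  if (var_diff <= 0) {
    if (abs(d_auc) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0, z = 0, p_value = 1))
    }
    stop_nephronet("degenerate DeLong variance with unequal AUCs",
                   "nephronet_degenerate_error")
  }
  z <- d_auc / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Evaluate a prediction matrix against its annotations
#'
#' Per evaluable term (>= 1 positive and >= 1 negative among scored genes):
#' AUC, two-sided Mann-Whitney p, Bonferroni significance across the evaluated
#' terms, and derived precision / sensitivity / F1 at the candidate threshold
#' `z >= z_threshold`.
#'
#' @param pred A [predict_terms()] result.
#' @param annotations Annotation set providing the labels; defaults to the one
#'   stored in `pred`.
#' @param alpha Family-wise error rate for the Bonferroni flags.
#' @param z_threshold Candidate threshold for the derived
#'   precision/sensitivity/F1 columns (`NA` when z-scores were not computed).
#' @return A tibble, one row per term: `term_id`, `auc`, `mwu_p`,
#'   `significant`, `n_pos`, `n_neg`, `precision`, `sensitivity`, `f1`,
#'   `group_tags` (list-column).
#' @export
evaluate_network <- function(pred, annotations = NULL, alpha = 0.05,
                             z_threshold = 5) {
  stopifnot(inherits(pred, "prediction_matrix"))
  annotations <- annotations %||% pred$annotations
  genes <- rownames(pred$log_odds)
  amat <- annotation_matrix(annotations, genes = genes)
  terms <- intersect(colnames(pred$log_odds), colnames(amat))
  rows <- purrr::map(terms, function(t) {
    y <- amat[, t]
    if (sum(y) < 1 || sum(1 - y) < 1) return(NULL)
    scores <- if (all(is.na(pred$z[, t]))) pred$log_odds[, t] else pred$z[, t]
    res <- auc_mann_whitney(scores, y)
    zs <- pred$z[, t]
    if (all(is.na(zs))) {
      prec <- sens <- f1 <- NA_real_
    } else {
      called <- zs >= z_threshold
      tp <- sum(called & y == 1)
      prec <- if (sum(called) == 0) NA_real_ else tp / sum(called)
      sens <- tp / sum(y)
      f1 <- if (is.na(prec) || (prec + sens) == 0) NA_real_ else
        2 * prec * sens / (prec + sens)
    }
    tibble(term_id = t, auc = res$auc, mwu_p = res$p_value,
           n_pos = res$n_pos, n_neg = res$n_neg,
           precision = prec, sensitivity = sens, f1 = f1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    stop_nephronet("no term is evaluable (need >= 1 positive and negative each)",
                   "nephronet_degenerate_error")
  }
  out$significant <- bonferroni_flags(out$mwu_p, alpha)
  groups <- term_groups(annotations)
  out$group_tags <- unname(groups[out$term_id])
  out[, c("term_id", "auc", "mwu_p", "significant", "n_pos", "n_neg",
          "precision", "sensitivity", "f1", "group_tags")]
}

#' Compare two networks term by term
#'
#' For every term evaluable in both prediction matrices (labels taken from the
#' shared annotation set, restricted to the genes both networks scored), runs
#' the DeLong test and calls a term significantly better for one network when
#' the (optionally Bonferroni-adjusted) DeLong p falls below `alpha` with the
#' corresponding AUC-difference sign. Group summaries report term counts,
#' better-counts per side, mean AUCs, and a paired two-sided t-test over the
#' per-term AUCs.
#'
#' @param pred_a,pred_b [predict_terms()] results (networks A and B).
#' @param annotations Shared annotation set; defaults to the one in `pred_a`.
#' @param groups Character vector of group tags to summarize; defaults to all
#'   tags present plus the whole shared set (`"all"`).
#' @param alpha Significance level for "significantly better".
#' @param adjust `"bonferroni"` (over compared terms, default) or `"none"`.
#' @return A `network_comparison`: `$terms` (per-term tibble with `auc_a`,
#'   `auc_b`, `delong_p`, `better`), `$groups` (summary tibble with
#'   `paired_t_p` and `zero_difference` flag).
#' @export
compare_networks <- function(pred_a, pred_b, annotations = NULL, groups = NULL,
                             alpha = 0.05, adjust = c("bonferroni", "none")) {
  stopifnot(inherits(pred_a, "prediction_matrix"),
            inherits(pred_b, "prediction_matrix"))
  adjust <- match.arg(adjust)
  annotations <- annotations %||% pred_a$annotations
  genes <- intersect(rownames(pred_a$log_odds), rownames(pred_b$log_odds))
  terms <- intersect(colnames(pred_a$log_odds), colnames(pred_b$log_odds))
  if (length(genes) == 0 || length(terms) == 0) {
    stop_nephronet("networks share no genes or no terms", "nephronet_comparison_error")
  }
  amat <- annotation_matrix(annotations, genes = genes)
  terms <- intersect(terms, colnames(amat))

  pick_scores <- function(pred, t) {
    if (all(is.na(pred$z[genes, t]))) pred$log_odds[genes, t] else pred$z[genes, t]
  }
  rows <- purrr::map(terms, function(t) {
    y <- amat[, t]
    if (sum(y) < 2 || sum(1 - y) < 2) return(NULL)
    dl <- delong_test(pick_scores(pred_a, t), pick_scores(pred_b, t), y)
    tibble(term_id = t, auc_a = dl$auc_a, auc_b = dl$auc_b,
           delong_p = dl$p_value)
  })
  per_term <- bind_rows(rows)
  if (nrow(per_term) == 0) {
    stop_nephronet("no shared evaluable terms", "nephronet_comparison_error")
  }
  thresh <- if (adjust == "bonferroni") alpha / nrow(per_term) else alpha
  per_term$better <- dplyr::case_when(
    per_term$delong_p < thresh & per_term$auc_a > per_term$auc_b ~ "a",
    per_term$delong_p < thresh & per_term$auc_b > per_term$auc_a ~ "b",
    TRUE ~ "none"
  )

  tags <- term_groups(annotations)
  group_of <- function(t) tags[[t]] %||% character()
  all_tags <- unique(unlist(lapply(per_term$term_id, group_of)))
  groups <- groups %||% all_tags
  summarize_group <- function(name, ids) {
    sub <- per_term[per_term$term_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    diffs <- sub$auc_a - sub$auc_b
    zero_diff <- all(abs(diffs) < 1e-12) || nrow(sub) < 2 || sd(diffs) == 0
    t_p <- if (zero_diff) 1 else t.test(sub$auc_a, sub$auc_b, paired = TRUE)$p.value
    tibble(group = name, n_terms = nrow(sub),
           n_sig_better_a = sum(sub$better == "a"),
           n_sig_better_b = sum(sub$better == "b"),
           mean_auc_a = mean(sub$auc_a), mean_auc_b = mean(sub$auc_b),
           paired_t_p = t_p, zero_difference = zero_diff)
  }
  group_rows <- c(
    list(summarize_group("all", per_term$term_id)),
    lapply(groups, function(g) {
      ids <- per_term$term_id[vapply(per_term$term_id,
                                     function(t) g %in% group_of(t), logical(1))]
      summarize_group(g, ids)
    })
  )
  structure(list(terms = per_term, groups = bind_rows(group_rows),
                 alpha = alpha, adjust = adjust),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> %d terms (alpha = %g, %s adjustment)\n",
              nrow(x$terms), x$alpha, x$adjust))
  print(x$groups)
  invisible(x)
}
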