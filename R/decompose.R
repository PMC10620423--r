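# Eigenvector decomposition of a processed compendium and merging of
# gene-level loadings across compendia. The decomposition is the SVD of the
# per-gene standardized gene x sample matrix; the gene-side singular vectors
# (one loading per gene per component) are the features later fed to the
# per-phenotype logistic regressions. This is equivalent to an
# eigendecomposition of the gene correlation matrix.

standardize_genes <- function(m, caller) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  zero <- s == 0 | !is.finite(s)
  if (all(zero)) {
    stop_nephronet("all genes are constant; nothing to decompose",
                   "nephronet_degenerate_error")
  }
  if (any(zero)) {
    warn(sprintf("%s: dropping %d zero-variance gene(s)", caller, sum(zero)))
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
  }
  (m - mu) / s
}

# Deterministic sign convention: each column's largest-magnitude entry is
# positive, so loadings are reproducible across linear-algebra backends.
fix_signs <- function(u) {
  flip <- apply(u, 2, function(col) sign(col[which.max(abs(col))]))
  sweep(u, 2, ifelse(flip == 0, 1, flip), "*")
}

#' Eigenvector decomposition of a processed compendium
#'
#' Standardizes each gene (mean 0, sd 1 across samples; constant genes are
#' dropped with a warning) and takes the singular value decomposition. The
#' returned component scores are the gene-side singular vectors for the top
#' `k` singular values, with a deterministic sign convention.
#'
#' @param expr Expression table at stage `log_corrected`.
#' @param k Number of components to keep; at most `min(n_genes, n_samples)`.
#' @param source_label Label recording which compendium the loadings come
#'   from; preserved through merging.
#' @return An `eigenvector_matrix`: list with `loadings` (gene x k matrix),
#'   `singular_values` (length k, descending), `total_ss` (total squared
#'   singular value mass of the standardized matrix), `source_label`.
#' @export
compute_components <- function(expr, k, source_label = "compendium") {
  check_stage(expr, "log_corrected", "compute_components()")
  m <- expr_values(expr)
  if (!is_count_scalar(k) || k > min(dim(m))) {
    stop_nephronet(sprintf("k must be a positive integer <= min(%d genes, %d samples)",
                           nrow(m), ncol(m)),
                   "nephronet_dimension_error")
  }
  z <- standardize_genes(m, "compute_components()")
  dec <- svd(z, nu = k, nv = 0)
  structure(
    list(loadings = structure(fix_signs(dec$u),
                              dimnames = list(rownames(z), paste0("C", seq_len(k)))),
         singular_values = dec$d[seq_len(k)],
         total_ss = sum(dec$d^2),
         source_label = source_label),
    class = "eigenvector_matrix"
  )
}

#' @export
print.eigenvector_matrix <- function(x, ...) {
  cat(sprintf("<eigenvector_matrix> %s: %d genes x %d components\n",
              x$source_label, nrow(x$loadings), ncol(x$loadings)))
  invisible(x)
}

#' Choose how many components to keep
#'
#' Three policies: `fixed` returns `param` as-is (use this to reproduce a
#' published component count); `variance_fraction` returns the smallest k
#' whose cumulative squared singular values reach `param` of the total;
#' `parallel_analysis` keeps the leading components whose singular values
#' exceed the 95th percentile of singular values obtained after permuting each
#' gene's values independently (`n_permutations` permutations, seeded).
#'
#' @inheritParams compute_components
#' @param method One of `"fixed"`, `"variance_fraction"`, `"parallel_analysis"`.
#' @param param Method parameter: the fixed k, or the variance fraction.
#' @param seed Seed for the permutation null.
#' @param n_permutations Permutations for `parallel_analysis`.
#' @return A positive integer component count (possibly 0 for a pure-noise
#'   matrix under `parallel_analysis`).
#' @export
select_component_count <- function(expr, method = c("fixed", "variance_fraction",
                                                    "parallel_analysis"),
                                   param = NULL, seed = 1, n_permutations = 20) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_nephronet(
                       sprintf("unknown component-selection method '%s'", method[1]),
                       "nephronet_config_error"))
  if (method == "fixed") {
    if (!is_count_scalar(param)) {
      stop_nephronet("method 'fixed' needs a positive integer `param`",
                     "nephronet_config_error")
    }
    return(as.integer(param))
  }
  check_stage(expr, "log_corrected", "select_component_count()")
  z <- standardize_genes(expr_values(expr), "select_component_count()")
  d2 <- svd(z, nu = 0, nv = 0)$d^2
  if (method == "variance_fraction") {
    if (!is_prob_scalar(param)) {
      stop_nephronet("method 'variance_fraction' needs `param` in [0, 1]",
                     "nephronet_config_error")
    }
    return(as.integer(which(cumsum(d2) / sum(d2) >= param - 1e-12)[1]))
  }
  # parallel analysis
  perm_d <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      zp <- t(apply(z, 1, sample))
      svd(zp, nu = 0, nv = 0)$d
    }, numeric(length(d2)))
  })
  thresh <- apply(perm_d, 1, quantile, probs = 0.95, names = FALSE)
  above <- sqrt(d2) > thresh
  k <- if (!above[1]) 0L else if (all(above)) length(above) else which(!above)[1] - 1L
  as.integer(k)
}

#' Merge component loadings from two compendia
#'
#' Aligns genes per policy and places the columns of `a` before the columns of
#' `b`. Column provenance is kept in `block_labels` so the merged feature
#' matrix remembers which compendium each eigenvector came from.
#'
#' @param a,b `eigenvector_matrix` objects.
#' @param gene_policy `"intersection"` keeps shared genes;
#'   `"union_zero_fill"` keeps every gene, filling absent loadings with 0.
#' @return A `merged_components` object: `loadings` (gene x (K_a + K_b)),
#'   `block_labels` (source label per column), `sources`.
#' @export
merge_components <- function(a, b, gene_policy = c("intersection", "union_zero_fill")) {
  stopifnot(inherits(a, "eigenvector_matrix"), inherits(b, "eigenvector_matrix"))
  gene_policy <- match.arg(gene_policy)
  ga <- rownames(a$loadings); gb <- rownames(b$loadings)
  genes <- if (gene_policy == "intersection") intersect(ga, gb) else union(ga, gb)
  if (length(genes) == 0) {
    stop_nephronet("gene sets do not overlap; cannot merge under 'intersection'",
                   "nephronet_merge_error")
  }
  take <- function(e) {
    out <- matrix(0, length(genes), ncol(e$loadings),
                  dimnames = list(genes, colnames(e$loadings)))
    shared <- intersect(genes, rownames(e$loadings))
    out[shared, ] <- e$loadings[shared, , drop = FALSE]
    out
  }
  loadings <- cbind(take(a), take(b))
  colnames(loadings) <- c(paste(a$source_label, colnames(a$loadings), sep = "_"),
                          paste(b$source_label, colnames(b$loadings), sep = "_"))
  structure(
    list(loadings = loadings,
         block_labels = c(rep(a$source_label, ncol(a$loadings)),
                          rep(b$source_label, ncol(b$loadings))),
         sources = c(a$source_label, b$source_label)),
    class = "merged_components"
  )
}

#' @export
print.merged_components <- function(x, ...) {
  cat(sprintf("<merged_components> %d genes x %d components (%s)\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%s: %d", unique(x$block_labels),
                            table(x$block_labels)[unique(x$block_labels)]),
                    collapse = ", ")))
  invisible(x)
}

# Accept either an eigenvector_matrix or merged_components wherever a
# gene x component loading matrix is needed.
loading_matrix <- function(components) {
  if (inherits(components, "eigenvector_matrix")) return(components$loadings)
  if (inherits(components, "merged_components")) return(components$loadings)
  if (is.matrix(components) && !is.null(rownames(components))) return(components)
  stop_nephronet("expected an eigenvector_matrix, merged_components, or a gene-named matrix",
                 "nephronet_format_error")
}

#' Promote a single compendium's eigenvectors to a merged-feature object
#'
#' Useful to train a network on one compendium alone (e.g. the base-only
#' network in comparisons).
#'
#' @param a An `eigenvector_matrix`.
#' @return A `merged_components` with one block.
#' @export
as_merged_components <- function(a) {
  stopifnot(inherits(a, "eigenvector_matrix"))
  loadings <- a$loadings
  colnames(loadings) <- paste(a$source_label, colnames(loadings), sep = "_")
  structure(list(loadings = loadings,
                 block_labels = rep(a$source_label, ncol(loadings)),
                 sources = a$source_label),
            class = "merged_components")
}
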