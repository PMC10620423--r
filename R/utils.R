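#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols distinct rename pull n across all_of desc
#' @importFrom stats median sd cor rnorm rnbinom rlnorm rbinom plogis pnorm
#'   pwilcox qnorm quantile t.test fisher.test setNames complete.cases
#' @importFrom utils head modifyList
NULL

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific seed from a global seed; stays below 2^31 - 1.
# Small multipliers keep the product exact in double precision for any
# seed a caller is likely to pass.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

stop_nephronet <- function(msg, class) {
  abort(msg, class = c(class, "nephronet_error"))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob_scalar <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

# ---- expression tibbles -----------------------------------------------------
# An expression table is a wide tibble: first column `gene_id`, remaining
# columns one per sample, with a `stage` attribute in
# {"raw_counts", "normalized", "log_corrected"}.

#' Assemble an expression table from a gene-by-sample matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names become gene and sample identifiers.
#' @param stage Processing stage, one of `"raw_counts"`, `"normalized"`,
#'   `"log_corrected"`.
#' @return A wide tibble (`gene_id` + one column per sample) carrying a
#'   `stage` attribute; accepted by every preprocessing and decomposition
#'   function in the package.
#' @examples
#' m <- matrix(rpois(12, 10), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' expression_table(m)
#' @export
expression_table <- function(values, stage = "raw_counts") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_nephronet("`values` must have gene row names and sample column names",
                   "nephronet_format_error")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop_nephronet("duplicate gene or sample identifiers", "nephronet_format_error")
  }
  stage <- match.arg(stage, c("raw_counts", "normalized", "log_corrected"))
  if (stage == "raw_counts" &&
      (any(values < 0) || any(values != floor(values)))) {
    stop_nephronet("raw counts must be nonnegative integers", "nephronet_format_error")
  }
  out <- bind_cols(tibble(gene_id = rownames(values)),
                   as_tibble(values, .name_repair = "minimal"))
  attr(out, "stage") <- stage
  out
}

#' @rdname expression_table
#' @param x An expression table.
#' @export
expr_stage <- function(x) attr(x, "stage") %||% NA_character_

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  x
}

# Convert an expression table back to a dim-named numeric matrix.
expr_values <- function(x) {
  if (!is.data.frame(x) || !identical(names(x)[1], "gene_id")) {
    stop_nephronet("expected an expression table (first column `gene_id`)",
                   "nephronet_format_error")
  }
  if (anyDuplicated(x$gene_id)) {
    stop_nephronet("duplicate gene identifiers", "nephronet_format_error")
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

check_stage <- function(x, expected, what) {
  st <- expr_stage(x)
  if (!is.na(st) && !st %in% expected) {
    stop_nephronet(sprintf("%s expects a matrix at stage %s, got '%s'",
                           what, paste(sQuote(expected), collapse = " or "), st),
                   "nephronet_stage_error")
  }
  invisible(x)
}
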