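# Gene-phenotype annotation sets: parsing the tabular genes-to-phenotype
# dialect, provenance-based exclusion filters, term grouping, and the binary
# training matrix.

known_provenance_flags <- c("multigenic_syndrome", "susceptibility", "curated")

split_flags <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), "[;,]"), function(f) {
    f <- trimws(f)
    unique(f[nzchar(f)])
  })
}

join_flags <- function(fl) vapply(fl, paste, character(1), collapse = ";")

#' Construct an annotation set
#'
#' @param associations Tibble with columns `gene_id`, `term_id`, and
#'   optionally `term_name`, `provenance` (flags separated by `;` or `,`,
#'   e.g. `"multigenic_syndrome"`, `"susceptibility"`, `"curated"`) and
#'   `line` (source line number). Duplicate (gene, term) pairs are collapsed,
#'   with provenance flags merged.
#' @param terms Optional tibble `term_id`, `term_name`, `group_tags`
#'   (list-column of character tags); derived from `associations` if `NULL`.
#' @return An `annotation_set` with elements `terms` and `associations`.
#' @export
annotation_set <- function(associations, terms = NULL) {
  stopifnot(is.data.frame(associations),
            all(c("gene_id", "term_id") %in% names(associations)))
  assoc <- as_tibble(associations)
  if (!"term_name" %in% names(assoc)) assoc$term_name <- assoc$term_id
  if (!"provenance" %in% names(assoc)) assoc$provenance <- ""
  if (!"line" %in% names(assoc)) assoc$line <- seq_len(nrow(assoc))
  assoc$provenance <- join_flags(split_flags(assoc$provenance))
  # collapse duplicates, merging provenance flags; keep first line number
  assoc <- assoc |>
    group_by(.data$gene_id, .data$term_id) |>
    summarise(
      term_name = .data$term_name[1],
      provenance = paste(unique(unlist(split_flags(.data$provenance))), collapse = ";"),
      line = min(.data$line),
      .groups = "drop"
    ) |>
    select("gene_id", "term_id", "term_name", "provenance", "line")
  if (is.null(terms)) {
    terms <- assoc |>
      distinct(.data$term_id, .data$term_name) |>
      arrange(.data$term_id)
    terms$group_tags <- rep(list(character()), nrow(terms))
  }
  missing_terms <- setdiff(assoc$term_id, terms$term_id)
  if (length(missing_terms)) {
    stop_nephronet(sprintf("associations reference unknown term(s): %s",
                           paste(head(missing_terms, 5), collapse = ", ")),
                   "nephronet_format_error")
  }
  structure(list(terms = as_tibble(terms), associations = assoc),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d associations, %d genes, %d terms\n",
              nrow(x$associations), dplyr::n_distinct(x$associations$gene_id),
              nrow(x$terms)))
  invisible(x)
}

#' Parse a genes-to-phenotype annotation file
#'
#' Reads the tab-separated dialect `gene_id  term_id  [term_name]
#' [provenance]`. Unknown columns are ignored; duplicate (gene, term) rows are
#' collapsed with provenance flags merged; source line numbers are retained
#' for error reporting.
#'
#' @param path Path to the TSV file (header row required).
#' @param dialect Only `"genes_to_phenotype_tsv"` is currently implemented.
#' @return An [annotation_set()].
#' @export
parse_annotations <- function(path, dialect = "genes_to_phenotype_tsv") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_nephronet(sprintf("annotation file not found: %s", path), "nephronet_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    stop_nephronet(sprintf("annotation file is empty: %s", path),
                   "nephronet_empty_input_error")
  }
  required <- c("gene_id", "term_id")
  if (!all(required %in% names(raw))) {
    stop_nephronet(sprintf(
      "annotation file must have columns %s; found header: %s",
      paste(required, collapse = ", "), paste(names(raw), collapse = ", ")),
      "nephronet_format_error")
  }
  raw$line <- seq_len(nrow(raw)) + 1L  # +1 for the header row
  keep <- intersect(c("gene_id", "term_id", "term_name", "provenance", "line"),
                    names(raw))
  annotation_set(raw[, keep])
}

#' Write an annotation set in the genes-to-phenotype dialect
#'
#' @param anns An [annotation_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  stopifnot(inherits(anns, "annotation_set"))
  readr::write_tsv(anns$associations[, c("gene_id", "term_id", "term_name",
                                         "provenance")], path)
  invisible(path)
}

#' Apply provenance exclusions and a minimum-positives filter
#'
#' Drops every association carrying any excluded provenance flag (the training
#' exclusions for copy-number multigenic syndromes and mere susceptibility
#' genes), then drops terms left with fewer than `min_genes_per_term`
#' annotated genes. Idempotent.
#'
#' @param anns An [annotation_set()].
#' @param exclude_flags Provenance flags to exclude; subset of
#'   `c("multigenic_syndrome", "susceptibility", "curated")`.
#' @param min_genes_per_term Minimum surviving positives for a term to be kept.
#' @return A filtered [annotation_set()] (possibly empty, with a warning).
#' @export
filter_annotations <- function(anns,
                               exclude_flags = c("multigenic_syndrome", "susceptibility"),
                               min_genes_per_term = 10) {
  stopifnot(inherits(anns, "annotation_set"))
  unknown <- setdiff(exclude_flags, known_provenance_flags)
  if (length(unknown)) {
    stop_nephronet(sprintf("unknown provenance flag(s): %s",
                           paste(unknown, collapse = ", ")),
                   "nephronet_config_error")
  }
  flags <- split_flags(anns$associations$provenance)
  drop <- vapply(flags, function(f) any(f %in% exclude_flags), logical(1))
  assoc <- anns$associations[!drop, , drop = FALSE]
  counts <- table(assoc$term_id)
  keep_terms <- names(counts)[counts >= min_genes_per_term]
  assoc <- assoc[assoc$term_id %in% keep_terms, , drop = FALSE]
  if (nrow(assoc) == 0) {
    warn("filter_annotations(): no associations survive the filters")
    empty_terms <- anns$terms[0, , drop = FALSE]
    return(structure(list(terms = empty_terms, associations = assoc),
                     class = "annotation_set"))
  }
  terms <- anns$terms[anns$terms$term_id %in% keep_terms, , drop = FALSE]
  structure(list(terms = terms, associations = assoc), class = "annotation_set")
}

#' Tag a group of terms (e.g. the kidney-related set)
#'
#' @param anns An [annotation_set()].
#' @param group_name Tag to add (e.g. `"kidney_related"`).
#' @param term_ids Either a character vector of term IDs or a path to a file
#'   with one term ID per line (`#` comments and blank lines allowed).
#' @return The annotation set with `group_name` added to the tagged terms'
#'   `group_tags`. Unknown IDs produce a warning, not an error.
#' @export
tag_term_group <- function(anns, group_name, term_ids) {
  stopifnot(inherits(anns, "annotation_set"), is.character(group_name))
  if (length(term_ids) == 1 && !term_ids %in% anns$terms$term_id) {
    if (file.exists(term_ids)) {
      lines <- readLines(term_ids, warn = FALSE)
      lines <- trimws(sub("#.*$", "", lines))
      term_ids <- lines[nzchar(lines)]
    } else if (grepl("[/\\\\]", term_ids)) {
      stop_nephronet(sprintf("term-group file not readable: %s", term_ids),
                     "nephronet_io_error")
    }
  }
  if (length(term_ids) == 0) return(anns)
  unknown <- setdiff(term_ids, anns$terms$term_id)
  if (length(unknown)) {
    warn(sprintf("tag_term_group(): %d unknown term ID(s): %s",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  hit <- anns$terms$term_id %in% term_ids
  anns$terms$group_tags[hit] <- lapply(anns$terms$group_tags[hit],
                                       function(tags) union(tags, group_name))
  anns
}

#' Binary gene-by-term membership matrix
#'
#' @param anns An [annotation_set()].
#' @param genes Optional gene universe for the rows; defaults to the genes
#'   present in the associations. Genes outside the associations get all-zero
#'   rows (they are the negatives in training).
#' @return Integer matrix, genes x terms, 1 where the gene is annotated.
#' @export
annotation_matrix <- function(anns, genes = NULL) {
  stopifnot(inherits(anns, "annotation_set"))
  genes <- genes %||% sort(unique(anns$associations$gene_id))
  terms <- anns$terms$term_id
  m <- matrix(0L, length(genes), length(terms), dimnames = list(genes, terms))
  assoc <- anns$associations[anns$associations$gene_id %in% genes, , drop = FALSE]
  if (nrow(assoc)) m[cbind(assoc$gene_id, assoc$term_id)] <- 1L
  m
}

#' Group tags as a named list
#'
#' @param anns An [annotation_set()].
#' @return Named list term_id -> character vector of tags.
#' @export
term_groups <- function(anns) {
  setNames(anns$terms$group_tags, anns$terms$term_id)
}
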