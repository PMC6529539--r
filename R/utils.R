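#' The five CRCA colorectal-cancer subtypes, in canonical order
#'
#' Canonical order is used for deterministic tie-breaking throughout the
#' package (ties at a maximum weight or correlation resolve to the earliest
#' name in this vector).
#'
#' @return Character vector of the five subtype names.
#' @export
#' @examples
#' crca_subtypes()
crca_subtypes <- function() {
  c("goblet-like", "enterocyte", "stem-like", "inflammatory", "TA")
}

#' Probe classes recognised in a gene panel
#' @return Character vector of valid `probe_class` values.
#' @export
probe_classes <- function() {
  c("endogenous", "housekeeping", "positive_control", "negative_control")
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a genes-by-samples expression tibble
#'
#' An expression tibble has a `gene` character column followed by one numeric
#' column per sample. Gene and sample identifiers must be unique and all
#' values finite; raw or normalized counts must additionally be non-negative.
#'
#' @param x A data frame: `gene` column plus numeric sample columns.
#' @param units One of `"raw_counts"`, `"normalized_counts"`,
#'   `"log2_expression"`. Counts are checked for non-negativity.
#' @param min_samples Minimum number of sample columns (default 1).
#' @return `x` as a tibble, invisibly usable in a pipe.
#' @export
validate_expr <- function(x, units = c("log2_expression", "raw_counts", "normalized_counts"),
                          min_samples = 1L) {
  units <- match.arg(units)
  if (!is.data.frame(x) || ncol(x) < 1L || !("gene" %in% names(x)[1])) {
    stop("expression table must have `gene` as its first column", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) - 1L < min_samples) {
    stop("expression table must contain at least ", min_samples, " sample column(s)",
         call. = FALSE)
  }
  if (anyDuplicated(x$gene)) {
    dup <- unique(x$gene[duplicated(x$gene)])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  smp <- names(x)[-1]
  if (anyDuplicated(smp)) {
    stop("duplicate sample identifiers: ",
         paste(unique(smp[duplicated(smp)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
  if (any(!is.finite(vals))) stop("expression values must be finite", call. = FALSE)
  if (units != "log2_expression" && any(vals < 0)) {
    stop(units, " must be non-negative", call. = FALSE)
  }
  x
}

# genes-by-samples tibble -> numeric matrix with gene rownames
expr_to_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = NA) |>
    tibble::rownames_to_column("gene") |>
    tibble::as_tibble()
}

# centroid tibble (gene + subtype columns) -> matrix
centroids_to_matrix <- function(centroids) {
  validate_centroids(centroids)
  m <- as.matrix(centroids[-1])
  rownames(m) <- centroids$gene
  m
}

#' Validate a genes-by-subtypes centroid tibble
#'
#' @param x Data frame: `gene` column plus one numeric column per subtype.
#' @return `x` as a tibble.
#' @export
validate_centroids <- function(x) {
  if (!is.data.frame(x) || names(x)[1] != "gene") {
    stop("centroid table must have `gene` as its first column", call. = FALSE)
  }
  if (ncol(x) - 1L < 2L) stop("centroid table needs at least 2 subtypes", call. = FALSE)
  if (nrow(x) < 2L) stop("centroid table needs at least 2 genes", call. = FALSE)
  if (anyDuplicated(x$gene)) stop("duplicate gene ids in centroid table", call. = FALSE)
  if (anyDuplicated(names(x)[-1])) stop("duplicate subtype names", call. = FALSE)
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("centroid values must be finite numerics", call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Validate a gene-panel definition
#'
#' A panel maps each probe to a gene symbol, a probe class and (optionally) a
#' subtype association. Gene symbols are trimmed of surrounding whitespace and
#' must be unique: two probes with one symbol are an error rather than being
#' silently aggregated, because the assay is one probe per gene.
#'
#' @param panel Data frame with columns `gene`, `probe_class`, optionally
#'   `subtype`.
#' @param require_housekeeping If `TRUE`, error unless at least one
#'   housekeeping probe is present (a precondition for housekeeping
#'   normalization).
#' @return The panel as a tibble with trimmed gene symbols.
#' @export
validate_panel <- function(panel, require_housekeeping = FALSE) {
  if (!all(c("gene", "probe_class") %in% names(panel))) {
    stop("panel needs `gene` and `probe_class` columns", call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)
  panel$gene <- trimws(panel$gene)
  bad <- setdiff(unique(panel$probe_class), probe_classes())
  if (length(bad)) stop("unknown probe_class: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(panel$gene)) {
    stop("panel has colliding gene symbols: ",
         paste(unique(panel$gene[duplicated(panel$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (require_housekeeping && !any(panel$probe_class == "housekeeping")) {
    stop("panel contains no housekeeping probes; housekeeping normalization requires >= 1",
         call. = FALSE)
  }
  if (!"subtype" %in% names(panel)) panel$subtype <- NA_character_
  panel
}
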