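#' Read and write expression, centroid, panel and call tables
#'
#' All on-disk tables are tab-separated with a header row and a leading
#' `gene` (or `sample_id`) column. Lines starting with `#` are treated as
#' comments (provenance manifests written by the CLI live there). Numeric
#' round-trips are stable to at least 12 significant digits.
#'
#' @param path File path.
#' @param units Units the matrix is declared to carry (checked on read).
#' @return `read_expr_tsv()`: a validated expression tibble.
#' @name io_tsv
NULL

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE, name_repair = "minimal")
  pr <- readr::problems(x)
  if (nrow(pr)) {
    stop("format error in ", path, ": ", pr$expected[1], " vs ", pr$actual[1],
         " at line ", pr$row[1], call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) < 2L) {
    stop("format error in ", path, ": empty table", call. = FALSE)
  }
  x
}

manifest_header <- function(command = NULL, seed = NULL, inputs = NULL) {
  if (is.null(command)) return(character())
  paste0("# nanocrc ", as.character(utils::packageVersion("nanocrc")),
         " | command: ", command,
         if (!is.null(seed)) paste0(" | seed: ", seed) else "",
         if (length(inputs)) paste0(" | inputs: ", paste(inputs, collapse = ",")) else "")
}

write_tsv_manifest <- function(x, path, manifest = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(manifest)) writeLines(manifest, con)
  # format() at 15 significant digits keeps doubles round-trip stable
  xfmt <- x
  for (j in seq_along(xfmt)) {
    if (is.double(xfmt[[j]])) {
      xfmt[[j]] <- vapply(xfmt[[j]], function(v) format(v, digits = 15, scientific = TRUE),
                          "")
    }
  }
  utils::write.table(xfmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_expr_tsv <- function(path, units = c("log2_expression", "raw_counts", "normalized_counts")) {
  units <- match.arg(units)
  x <- read_tsv_strict(path)
  names(x)[1] <- "gene"
  for (j in 2:ncol(x)) x[[j]] <- as.numeric(x[[j]])
  validate_expr(x, units)
}

#' @rdname io_tsv
#' @param x Table to write.
#' @param manifest Optional character vector of `#`-prefixed comment lines.
#' @export
write_expr_tsv <- function(x, path, manifest = character()) {
  write_tsv_manifest(x, path, manifest)
}

#' @rdname io_tsv
#' @export
read_centroids_tsv <- function(path) {
  x <- read_tsv_strict(path)
  names(x)[1] <- "gene"
  for (j in 2:ncol(x)) x[[j]] <- as.numeric(x[[j]])
  validate_centroids(x)
}

#' @rdname io_tsv
#' @export
write_centroids_tsv <- function(x, path, manifest = character()) {
  write_tsv_manifest(validate_centroids(x), path, manifest)
}

#' @rdname io_tsv
#' @param require_housekeeping Passed to [validate_panel()].
#' @export
read_panel_tsv <- function(path, require_housekeeping = FALSE) {
  x <- read_tsv_strict(path)
  validate_panel(x, require_housekeeping = require_housekeeping)
}

#' @rdname io_tsv
#' @export
write_panel_tsv <- function(x, path, manifest = character()) {
  write_tsv_manifest(validate_panel(x), path, manifest)
}

#' @rdname io_tsv
#' @export
write_calls_tsv <- function(x, path, manifest = character()) {
  stopifnot(is.data.frame(x), all(c("sample_id", "assigned", "margin", "reason") %in% names(x)))
  write_tsv_manifest(x, path, manifest)
}

#' @rdname io_tsv
#' @export
read_calls_tsv <- function(path) {
  x <- read_tsv_strict(path)
  if (!all(c("sample_id", "assigned") %in% names(x))) {
    stop("format error in ", path, ": not a subtype-call table", call. = FALSE)
  }
  class(x) <- c("subtype_calls", class(x))
  x
}
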