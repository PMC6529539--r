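#' Read a NanoString RCC lane file
#'
#' RCC files are sectioned text: `<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>` and `<Code_Summary>` blocks of key,value or
#' CodeClass,Name,Accession,Count rows. Section tags are matched
#' case-insensitively and both comma- and tab-delimited bodies are accepted,
#' since files in the wild vary by instrument software version.
#'
#' @param path Path to an `.RCC` file.
#' @return An object of class `rcc_lane`: a list with
#'   `header`, `sample_attributes`, `lane_attributes` (named character
#'   vectors, values preserved verbatim), `lane_numeric` (the numeric
#'   interpretation of lane attributes where one exists) and `code_summary`,
#'   a tibble with columns `code_class`, `gene`, `accession`, `count`.
#' @export
#' @examples
#' sim <- simulate_counts(simulation_config(n_samples = 6, seed = 1))
#' f <- write_rcc_files(sim, tempdir())[1]
#' lane <- read_rcc(f)
#' lane$code_summary
read_rcc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  # locate <tag> ... </tag> blocks, case-insensitive
  open  <- grepl("^<[^/][^>]*>$", trimws(lines))
  sections <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^<[^/][^>]*>$", ln)) {
      tag <- tolower(gsub("[<>]", "", ln))
      close_pat <- paste0("^</", tag, ">$")
      j <- i + 1L
      body <- character()
      while (j <= length(lines) && !grepl(close_pat, trimws(lines[j]), ignore.case = TRUE)) {
        body <- c(body, lines[j])
        j <- j + 1L
      }
      sections[[tag]] <- body
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  if (is.null(sections[["code_summary"]])) {
    stop("RCC format error: missing Code_Summary section in ", path, call. = FALSE)
  }

  split_row <- function(ln) {
    if (grepl("\t", ln, fixed = TRUE)) strsplit(ln, "\t", fixed = TRUE)[[1]]
    else strsplit(ln, ",", fixed = TRUE)[[1]]
  }
  kv <- function(body) {
    if (is.null(body) || !length(body)) return(stats::setNames(character(), character()))
    parts <- lapply(body, split_row)
    stats::setNames(
      vapply(parts, function(p) if (length(p) >= 2) paste(p[-1], collapse = ",") else "", ""),
      vapply(parts, `[[`, "", 1L)
    )
  }

  cs_rows <- lapply(sections[["code_summary"]], split_row)
  hdr <- tolower(trimws(cs_rows[[1]]))
  if (identical(hdr[1:2], c("codeclass", "name"))) cs_rows <- cs_rows[-1]
  bad_len <- vapply(cs_rows, length, 0L) < 4L
  if (any(bad_len)) {
    stop("RCC format error: malformed Code_Summary row: ",
         paste(sections[["code_summary"]][which(bad_len)[1]]), call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(vapply(cs_rows, `[[`, "", 4L)))
  if (any(is.na(counts)) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0)[1]
    stop("RCC format error: non-numeric or negative Count in row for probe '",
         cs_rows[[bad]][2], "'", call. = FALSE)
  }
  code_summary <- tibble::tibble(
    code_class = vapply(cs_rows, `[[`, "", 1L),
    gene       = trimws(vapply(cs_rows, `[[`, "", 2L)),
    accession  = vapply(cs_rows, `[[`, "", 3L),
    count      = counts
  )

  lane_attr <- kv(sections[["lane_attributes"]])
  lane_num  <- suppressWarnings(as.numeric(lane_attr))
  names(lane_num) <- names(lane_attr)

  structure(
    list(
      header            = kv(sections[["header"]]),
      sample_attributes = kv(sections[["sample_attributes"]]),
      lane_attributes   = lane_attr,
      lane_numeric      = lane_num[!is.na(lane_num)],
      code_summary      = code_summary
    ),
    class = "rcc_lane"
  )
}

#' @export
print.rcc_lane <- function(x, ...) {
  id <- x$sample_attributes[["ID"]] %||% x$lane_attributes[["ID"]] %||% "?"
  cat("<rcc_lane> sample", id, "-", nrow(x$code_summary), "probes\n")
  print(utils::head(x$code_summary, 5))
  invisible(x)
}

#' Write an RCC lane file
#'
#' Inverse of [read_rcc()]: emits the four standard sections with
#' comma-delimited bodies. `write_rcc(read_rcc(f))` reproduces an equivalent
#' probe table.
#'
#' @param lane An `rcc_lane` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(lane, path) {
  stopifnot(inherits(lane, "rcc_lane"))
  kv_lines <- function(v) if (length(v)) paste(names(v), v, sep = ",") else character()
  cs <- lane$code_summary
  lines <- c(
    "<Header>", kv_lines(lane$header), "</Header>",
    "<Sample_Attributes>", kv_lines(lane$sample_attributes), "</Sample_Attributes>",
    "<Lane_Attributes>", kv_lines(lane$lane_attributes), "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(cs$code_class, cs$gene, cs$accession,
          format(cs$count, trim = TRUE, scientific = FALSE), sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a raw count matrix from RCC lanes
#'
#' Combines per-lane probe counts into a genes-by-samples table over the
#' endogenous and housekeeping probes, keeping positive/negative control
#' probes in a side table for QC. Probes are matched on gene symbol
#' (whitespace-trimmed, case-sensitive) against the panel; every lane must
#' report the same probe set, and sample order follows input lane order.
#'
#' @param lanes A list of `rcc_lane` objects (or a character vector of RCC
#'   file paths, which are read first).
#' @param panel A gene panel (see [validate_panel()]); when `NULL`, probe
#'   classes are taken from the RCC `CodeClass` column.
#' @return An object of class `nano_counts`: list with `counts` (tibble,
#'   `gene` + one column per sample, units raw counts), `controls` (same shape
#'   for control probes plus `code_class`), `lane_attributes` (tibble of
#'   per-lane ID/FovCount/FovCounted/BindingDensity), and `panel`.
#' @export
assemble_counts <- function(lanes, panel = NULL) {
  if (is.character(lanes)) lanes <- lapply(lanes, read_rcc)
  stopifnot(length(lanes) >= 1L, all(vapply(lanes, inherits, TRUE, "rcc_lane")))

  probe_sets <- lapply(lanes, function(l) sort(l$code_summary$gene))
  ref <- probe_sets[[1]]
  for (k in seq_along(probe_sets)) {
    if (!identical(probe_sets[[k]], ref)) {
      missing <- c(setdiff(ref, probe_sets[[k]]), setdiff(probe_sets[[k]], ref))
      stop("lane ", k, " probe set inconsistent with lane 1; differing probes: ",
           paste(unique(missing), collapse = ", "), call. = FALSE)
    }
  }

  ids <- vapply(seq_along(lanes), function(k) {
    l <- lanes[[k]]
    l$sample_attributes[["ID"]] %||% l$lane_attributes[["ID"]] %||% paste0("lane", k)
  }, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")

  first <- lanes[[1]]$code_summary
  if (is.null(panel)) {
    cc <- tolower(first$code_class)
    cls <- dplyr::case_when(
      grepl("^pos", cc) ~ "positive_control",
      grepl("^neg", cc) ~ "negative_control",
      grepl("^house", cc) ~ "housekeeping",
      TRUE ~ "endogenous"
    )
    panel <- tibble::tibble(gene = first$gene, probe_class = cls,
                            subtype = NA_character_)
  }
  panel <- validate_panel(panel)
  unknown <- setdiff(first$gene, panel$gene)
  if (length(unknown)) {
    stop("probes not resolvable against panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  count_col <- function(l) {
    cs <- l$code_summary
    stats::setNames(cs$count, cs$gene)[first$gene]
  }
  m <- vapply(lanes, count_col, numeric(nrow(first)))
  m <- matrix(m, nrow = nrow(first), dimnames = list(first$gene, ids))

  cls <- panel$probe_class[match(first$gene, panel$gene)]
  keep <- cls %in% c("endogenous", "housekeeping")

  counts <- matrix_to_expr(m[keep, , drop = FALSE])
  controls <- dplyr::bind_cols(
    tibble::tibble(code_class = cls[!keep]),
    matrix_to_expr(m[!keep, , drop = FALSE])
  )

  la <- lapply(seq_along(lanes), function(k) {
    n <- lanes[[k]]$lane_numeric
    tibble::tibble(
      sample_id = ids[k],
      fov_count = unname(n[["FovCount"]] %||% NA_real_),
      fov_counted = unname(n[["FovCounted"]] %||% NA_real_),
      binding_density = unname(n[["BindingDensity"]] %||% NA_real_)
    )
  })

  structure(
    list(counts = validate_expr(counts, "raw_counts"),
         controls = controls,
         lane_attributes = dplyr::bind_rows(la),
         panel = panel),
    class = "nano_counts"
  )
}

#' @export
print.nano_counts <- function(x, ...) {
  cat("<nano_counts>", nrow(x$counts), "probes x", ncol(x$counts) - 1L, "samples (raw counts),",
      nrow(x$controls), "control probes\n")
  invisible(x)
}
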