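# Shared in-code fixtures; everything is generated, nothing read from disk.

# genes-by-samples matrix -> expression tibble
as_expr <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)), as.data.frame(m)))
}

expr_mat <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  m
}

# minimal hand-written RCC text, configurable delimiter and section case
write_fixture_rcc <- function(path, delim = ",", counts = c(10, 0, 250),
                              genes = c("GA", "GB", "GC"),
                              tag_case = identity, drop_code_summary = FALSE) {
  j <- function(...) paste(..., sep = delim)
  lines <- c(
    paste0("<", tag_case("Header"), ">"),
    j("FileVersion", "1.7"),
    paste0("</", tag_case("Header"), ">"),
    paste0("<", tag_case("Sample_Attributes"), ">"),
    j("ID", "FIX1"),
    paste0("</", tag_case("Sample_Attributes"), ">"),
    paste0("<", tag_case("Lane_Attributes"), ">"),
    j("ID", "1"), j("FovCount", "280"), j("FovCounted", "270"),
    j("BindingDensity", "0.85"),
    paste0("</", tag_case("Lane_Attributes"), ">")
  )
  if (!drop_code_summary) {
    lines <- c(lines,
               paste0("<", tag_case("Code_Summary"), ">"),
               j("CodeClass", "Name", "Accession", "Count"),
               vapply(seq_along(genes),
                      function(i) j("Endogenous", genes[i], paste0("ACC_", i),
                                    as.character(counts[i])), ""),
               paste0("</", tag_case("Code_Summary"), ">"))
  }
  writeLines(lines, path)
  path
}

default_sim <- function(seed, ...) {
  simulate_counts(simulation_config(seed = seed, ...))
}
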