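#' Serialize DA results to TSV
#'
#' @param x `da_results` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_da_results <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0(name, ": ", conditionMessage(e)))
  })
}

#' Run the integrated analysis workflow
#'
#' Executes read -> (KO-to-KEGG conversion, when the table is KO and
#' `convert` is `TRUE`) -> differential abundance -> annotation -> error-bar
#' layer, writing every intermediate table, the figures and a YAML run
#' manifest into `output_dir`. Any stage failure is re-raised with the stage
#' name prefixed. Identical inputs and parameters give byte-identical
#' output tables.
#'
#' @param abundance_path,metadata_path Input file paths.
#' @param output_dir Output directory (created if needed).
#' @param sample_col,group_col,reference Metadata parsing, see
#'   [read_metadata()].
#' @param namespace Optional namespace override for the abundance table.
#' @param convert Convert a KO table to KEGG pathway abundances first
#'   (default `TRUE`; ignored for non-KO tables).
#' @param method,adjust,seed DA settings, see [pathway_daa()].
#' @param threshold Significance threshold for the error-bar layer.
#' @param formats Figure formats for [write_figure()].
#' @param ... Further method parameters forwarded to [pathway_daa()].
#' @return Named list of written paths, invisibly.
#' @export
run_workflow <- function(abundance_path, metadata_path, output_dir,
                         sample_col = "sample", group_col = "group",
                         reference = NULL, namespace = NULL, convert = TRUE,
                         method = "linda", adjust = "BH", seed = 42,
                         threshold = 0.05, formats = c("pdf", "png"), ...) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- stage("read_abundance", read_abundance(abundance_path, namespace))
  meta <- stage("read_metadata",
                read_metadata(metadata_path, sample_col, group_col, reference))
  ns <- abundance_namespace(tab)
  converted <- FALSE
  if (convert && identical(ns, "KO")) {
    tab <- stage("ko2kegg", ko2kegg_abundance(tab))
    ns <- "KEGG_PATHWAY"
    converted <- TRUE
  }
  paths <- list()
  paths$abundance <- file.path(output_dir, "abundance.tsv")
  write_abundance(tab, paths$abundance)
  da <- stage("pathway_daa",
              pathway_daa(tab, meta, method = method, adjust = adjust,
                          seed = seed, ...))
  paths$da_results <- file.path(output_dir, "da_results.tsv")
  write_da_results(da, paths$da_results)
  ann <- if (ns == "UNKNOWN") da else {
    stage("pathway_annotation", pathway_annotation(da, namespace = ns))
  }
  paths$annotated <- file.path(output_dir, "da_annotated.tsv")
  readr::write_tsv(as_tibble(ann), paths$annotated, progress = FALSE)
  eb <- stage("pathway_errorbar",
              pathway_errorbar(tab, meta, da, threshold = threshold))
  paths$errorbar_layer <- file.path(output_dir, "errorbar_layer.tsv")
  readr::write_tsv(tidy(eb), paths$errorbar_layer, progress = FALSE)
  fig <- stage("figure", write_figure(eb, file.path(output_dir, "errorbar"),
                                      formats = formats))
  paths$figures <- unname(fig)
  manifest <- list(
    package = "profda",
    version = as.character(utils::packageVersion("profda")),
    ref_map_version = load_reference_map()$version,
    parameters = list(method = method, adjust = adjust, seed = seed,
                      threshold = threshold, namespace = ns,
                      converted_ko2kegg = converted,
                      reference = reference %||% "first-sorted"),
    inputs = list(abundance = abundance_path, metadata = metadata_path),
    outputs = unlist(paths, use.names = FALSE))
  paths$manifest <- file.path(output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
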