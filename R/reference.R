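the_ref_cache <- new.env(parent = emptyenv())

#' Load a KO-to-KEGG-pathway reference map
#'
#' Without arguments, loads the reference snapshot packaged under
#' `inst/extdata/kegg_ref_synthetic/` (real KEGG pathway ids, names and
#' classes; synthetic KO memberships and feature descriptions — see the
#' methods vignette). With `path`, loads a user-supplied two-column TSV
#' (`pathway_id<TAB>ko_id`, no header required when the first row already
#' looks like a mapping).
#'
#' @param path Optional path to a two-column membership TSV.
#' @return A `reference_map`: list with tibbles `ko2pathway`, `pathway_info`
#'   (`id`, `name`, `description`, `class`, `map_link`), `ko_info`,
#'   `ec_info`, `metacyc_info` (`id`, `description`) and a `version` string.
#' @export
load_reference_map <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the_ref_cache$map)) the_ref_cache$map <- load_packaged_map()
    return(the_ref_cache$map)
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty reference map")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort(paste0("malformed map row (expected 2 tab-separated columns): ",
                 lines[which(lengths(parts) != 2)[1]]))
  }
  tab <- tibble(pathway = vapply(parts, `[[`, "", 1),
                ko = vapply(parts, `[[`, "", 2))
  if (identical(tolower(tab$pathway[1]), "pathway") ||
      identical(tolower(tab$pathway[1]), "pathway_id")) tab <- tab[-1, ]
  if (nrow(tab) == 0) abort("empty reference map")
  new_reference_map(
    ko2pathway = tab,
    pathway_info = tibble(id = unique(tab$pathway), name = NA_character_,
                          description = NA_character_, class = NA_character_,
                          map_link = NA_character_),
    version = paste0("user:", basename(path))
  )
}

new_reference_map <- function(ko2pathway, pathway_info,
                              ko_info = tibble(id = character(), description = character()),
                              ec_info = tibble(id = character(), description = character()),
                              metacyc_info = tibble(id = character(), description = character()),
                              version = "unversioned") {
  stopifnot(all(c("pathway", "ko") %in% names(ko2pathway)))
  ko2pathway <- dplyr::distinct(ko2pathway)
  missing_info <- setdiff(unique(ko2pathway$pathway), pathway_info$id)
  if (length(missing_info)) {
    abort(paste0("pathway(s) missing from pathway_info: ",
                 paste(head(missing_info, 5), collapse = ", ")))
  }
  structure(list(ko2pathway = ko2pathway, pathway_info = pathway_info,
                 ko_info = ko_info, ec_info = ec_info,
                 metacyc_info = metacyc_info, version = version),
            class = "reference_map")
}

load_packaged_map <- function() {
  dir <- system.file("extdata", "kegg_ref_synthetic", package = "profda",
                     mustWork = TRUE)
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  ver <- sub("^snapshot_version: *", "", readLines(file.path(dir, "VERSION"))[1])
  new_reference_map(
    ko2pathway = rd("ko2pathway_synthetic.tsv"),
    pathway_info = rd("pathway_info_synthetic.tsv"),
    ko_info = rd("ko_info_synthetic.tsv"),
    ec_info = rd("ec_info_synthetic.tsv"),
    metacyc_info = rd("metacyc_info_synthetic.tsv"),
    version = ver
  )
}

#' @export
print.reference_map <- function(x, ...) {
  cat("<reference_map> version", x$version, "\n",
      length(unique(x$ko2pathway$pathway)), "pathways,",
      length(unique(x$ko2pathway$ko)), "member KOs\n")
  invisible(x)
}

# pathway -> character vector of member KOs
map_members <- function(map) split(map$ko2pathway$ko, map$ko2pathway$pathway)
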