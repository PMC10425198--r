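#' Annotate features with descriptions from the packaged reference snapshot
#'
#' Left-joins feature ids against the matching offline annotation table:
#' KO/EC/MetaCyc ids gain a `description` column; KEGG pathway ids
#' additionally gain `pathway_name`, `pathway_class` and `pathway_map`.
#' Works on either a [pathway_daa()] result (joins on `feature`) or an
#' abundance table. Annotation never drops or reorders rows; unmatched ids
#' keep missing fields and a summary of matched/unmatched counts is logged.
#'
#' Live KEGG queries are deliberately not performed: `online = TRUE` is a
#' stub and errors. All annotation is served from the packaged snapshot.
#'
#' @param x A `da_results` tibble or an abundance tibble.
#' @param namespace Feature namespace; defaults to the abundance table's
#'   namespace attribute and must be given for DA results.
#' @param map A [load_reference_map()] result.
#' @param online Must be `FALSE`; reserved hook for a live KEGG client.
#' @return The input with annotation columns appended.
#' @export
pathway_annotation <- function(x, namespace = NULL, map = load_reference_map(),
                               online = FALSE) {
  if (isTRUE(online)) abort("online KEGG annotation is a stub; use the packaged snapshot")
  namespace <- namespace %||% abundance_namespace(x)
  if (is.null(namespace) || identical(namespace, "UNKNOWN")) {
    abort("cannot annotate namespace UNKNOWN; pass `namespace` explicitly")
  }
  namespace <- match.arg(namespace, c("KO", "EC", "METACYC", "KEGG_PATHWAY"))
  att <- attributes(x)
  ids <- x$feature %||% abort("input must have a `feature` column")
  if (namespace == "KEGG_PATHWAY") {
    info <- map$pathway_info |>
      select(feature = "id", pathway_name = "name", description = "description",
             pathway_class = "class", pathway_map = "map_link")
  } else {
    tabname <- c(KO = "ko_info", EC = "ec_info", METACYC = "metacyc_info")[[namespace]]
    info <- select(map[[tabname]], feature = "id", description = "description")
  }
  out <- left_join(as_tibble(x), info, by = "feature")
  n_match <- sum(ids %in% info$feature)
  inform(paste0("annotated ", n_match, "/", length(ids), " ", namespace,
                " id(s); ", length(ids) - n_match, " unmatched"))
  for (a in setdiff(names(att), c("names", "row.names", "class"))) {
    attr(out, a) <- att[[a]]
  }
  if (inherits(x, "da_results")) class(out) <- c("da_results", class(out))
  out
}
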