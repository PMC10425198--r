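#' Aggregate KO abundances into KEGG pathway abundances
#'
#' For each pathway and sample, the pathway abundance is the unweighted sum
#' of the abundances of its member KOs present in the table; member KOs
#' absent from the table contribute zero, and a KO belonging to several
#' pathways is counted fully in each (no fractional assignment). PICRUSt2
#' itself stopped emitting KEGG pathway abundances, so this is the bridge
#' from its KO table to pathway-level analysis.
#'
#' @param abundance KO abundance tibble (namespace `KO`).
#' @param map A [load_reference_map()] result; the packaged snapshot by
#'   default.
#' @param drop_zero Drop pathways whose abundance is zero in every sample
#'   (default `TRUE`).
#' @return A KEGG-pathway abundance tibble, features in sorted pathway-id
#'   order, same samples in the same order as the input; the map version is
#'   attached as the `ref_map_version` attribute.
#' @examples
#' tab <- as_abundance(data.frame(feature = c("K00001", "K00002"),
#'                                S1 = c(2, 5), S2 = c(3, 0)))
#' \dontrun{ko2kegg_abundance(tab)}
#' @export
ko2kegg_abundance <- function(abundance, map = load_reference_map(),
                              drop_zero = TRUE) {
  abundance <- as_abundance(abundance, abundance_namespace(abundance))
  if (!identical(abundance_namespace(abundance), "KO")) {
    abort(paste0("ko2kegg_abundance() needs a KO table; namespace is ",
                 abundance_namespace(abundance)))
  }
  if (!inherits(map, "reference_map")) abort("`map` must be a reference_map")
  m <- abd_matrix(abundance)
  members <- map_members(map)
  hit <- map$ko2pathway$ko %in% rownames(m)
  if (!any(hit)) abort("no KO in the table maps to any pathway in the map")
  out <- do.call(rbind, lapply(members, function(kos) {
    kos <- kos[kos %in% rownames(m)]
    if (length(kos) == 0) return(numeric(ncol(m)))
    colSums(m[kos, , drop = FALSE])
  }))
  rownames(out) <- names(members)
  colnames(out) <- colnames(m)
  out <- out[order(rownames(out)), , drop = FALSE]
  if (drop_zero) out <- out[rowSums(out) > 0, , drop = FALSE]
  if (nrow(out) == 0) abort("no pathway with nonzero abundance")
  res <- abd_from_matrix(out, "KEGG_PATHWAY")
  attr(res, "ref_map_version") <- map$version
  res
}
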