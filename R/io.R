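#' Feature abundance tables
#'
#' An abundance table is a tibble whose first column, `feature`, holds unique
#' feature identifiers (KO, EC, MetaCyc or KEGG pathway ids) and whose
#' remaining columns hold non-negative, finite abundances for uniquely named
#' samples — the layout PICRUSt2 writes to `pred_metagenome_unstrat.tsv`.
#' The feature namespace is carried as the `"namespace"` attribute.
#'
#' @param x A data frame: first column feature ids, other columns numeric.
#' @param namespace One of `"KO"`, `"EC"`, `"METACYC"`, `"KEGG_PATHWAY"`,
#'   `"UNKNOWN"`, or `NULL` to infer it from the id patterns.
#' @return A validated abundance tibble with a `namespace` attribute.
#' @examples
#' as_abundance(data.frame(feature = c("K00001", "K00002"), S1 = c(1, 2), S2 = c(3, 4)))
#' @export
as_abundance <- function(x, namespace = NULL) {
  x <- as_tibble(x)
  if (ncol(x) < 2 || nrow(x) < 1) {
    abort("abundance table must have at least one feature row and one sample column")
  }
  names(x)[1] <- "feature"
  x$feature <- as.character(x$feature)
  if (anyDuplicated(x$feature)) {
    abort(paste0("duplicate feature id(s): ",
                 paste(unique(x$feature[duplicated(x$feature)]), collapse = ", ")))
  }
  if (anyDuplicated(names(x)[-1])) abort("duplicate sample id(s) in header")
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("non-numeric abundance value(s)")
  if (anyNA(vals) || any(!is.finite(vals))) abort("missing or non-finite abundance value(s)")
  if (any(vals < 0)) abort("negative abundance value(s)")
  ns <- namespace %||% infer_namespace(x$feature)
  ns <- match.arg(ns, c("KO", "EC", "METACYC", "KEGG_PATHWAY", "UNKNOWN"))
  attr(x, "namespace") <- ns
  x
}

#' @rdname as_abundance
#' @export
abundance_namespace <- function(x) attr(x, "namespace") %||% "UNKNOWN"

infer_namespace <- function(ids) {
  if (all(grepl("^K\\d{5}$", ids))) return("KO")
  if (all(grepl("^ko\\d{5}$", ids))) return("KEGG_PATHWAY")
  if (all(grepl("^(EC:)?\\d+\\.\\d+\\.\\d+(\\.\\d+)?$", ids))) return("EC")
  metacyc <- load_reference_map()$metacyc_info$id
  if (any(ids %in% metacyc)) return("METACYC")
  "UNKNOWN"
}

# matrix view (features x samples) with feature rownames
abd_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$feature
  m
}

abd_from_matrix <- function(m, namespace = "UNKNOWN") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(feature = rownames(m)), out)
  as_abundance(out, namespace)
}

#' Read a PICRUSt2-style abundance table
#'
#' Reads the `pred_metagenome_unstrat.tsv` dialect without reformatting: a
#' header row, feature ids in the first column (whatever its header says —
#' PICRUSt2 writes `function`, QIIME exports `#OTU ID`), samples in the
#' remaining columns. The delimiter is inferred from the extension
#' (`.csv` comma; `.tsv`/`.txt` and anything else tab).
#'
#' @param path Path to a TSV/CSV/TXT abundance table.
#' @param namespace Optional namespace override; inferred from id patterns
#'   when absent (`K00001` style ids are KO, `ko00010` KEGG pathways,
#'   `EC:1.1.1.1` or dotted numbers EC, ids found in the packaged MetaCyc
#'   snapshot MetaCyc, anything else UNKNOWN).
#' @return An abundance tibble (see [as_abundance()]).
#' @export
read_abundance <- function(path, namespace = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # leading "# key: value" metadata lines (e.g. "# ref_map_version: ...") are
  # skipped; a "#OTU ID" header (no space after the hash) is not a comment
  top <- readLines(path, n = 10L)
  n_skip <- 0L
  while (n_skip < length(top) && grepl("^# ", top[n_skip + 1L])) n_skip <- n_skip + 1L
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, skip = n_skip,
                           name_repair = "minimal")
  if (nrow(raw) == 0) abort("empty abundance table")
  for (j in seq_along(raw)[-1]) {
    v <- raw[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num)) abort(paste0("non-numeric value(s) in column ", names(raw)[j]))
      raw[[j]] <- num
    }
  }
  as_abundance(raw, namespace)
}

#' Write an abundance table as TSV
#'
#' Writes the table in the PICRUSt2 output dialect: tab-separated, header
#' row, feature id column first (named `function`).
#'
#' @param x Abundance tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  ver <- attr(x, "ref_map_version")
  x <- as_abundance(x, abundance_namespace(x))
  names(x)[1] <- "function"
  if (!is.null(ver)) {
    writeLines(paste0("# ref_map_version: ", ver), path)
    readr::write_tsv(x, path, progress = FALSE, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Construct sample metadata
#'
#' Sample metadata maps each sample id to a group label (the DA contrast) and
#' optional covariate columns. The reference group is stored as the first
#' level of the `group` factor.
#'
#' @param x A data frame with at least sample-id and group columns.
#' @param sample_col,group_col Names of the sample-id and group columns.
#' @param reference Reference group level; defaults to the first level in
#'   sorted order.
#' @return A tibble with columns `sample`, `group` (factor, reference level
#'   first) and any covariate columns.
#' @export
as_metadata <- function(x, sample_col = "sample", group_col = "group",
                        reference = NULL) {
  x <- as_tibble(x)
  missing_cols <- setdiff(c(sample_col, group_col), names(x))
  if (length(missing_cols)) {
    abort(paste0("metadata column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::relocate(
    rename(x, sample = all_of(sample_col), group = all_of(group_col)),
    "sample", "group")
  out$sample <- as.character(out$sample)
  if (anyDuplicated(out$sample)) abort("duplicated sample id(s) in metadata")
  lev <- sort(unique(as.character(out$group)))
  reference <- reference %||% lev[1]
  if (!reference %in% lev) {
    abort(paste0("reference group '", reference, "' is not a group level (",
                 paste(lev, collapse = ", "), ")"))
  }
  out$group <- factor(as.character(out$group), levels = c(reference, setdiff(lev, reference)))
  out
}

#' Read sample metadata from a delimited file
#'
#' @param path Path to a TSV/CSV metadata file.
#' @inheritParams as_metadata
#' @return A metadata tibble (see [as_metadata()]).
#' @export
read_metadata <- function(path, sample_col = "sample", group_col = "group",
                          reference = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  as_metadata(raw, sample_col, group_col, reference)
}

#' @rdname as_metadata
#' @export
reference_group <- function(x) levels(x$group)[1]

# metadata must support a DA contrast: >=2 levels with >=2 samples each
check_da_metadata <- function(meta) {
  counts <- table(meta$group)
  if (length(counts) < 2) abort("differential abundance needs at least 2 groups")
  small <- names(counts)[counts < 2]
  if (length(small)) {
    abort(paste0("group(s) with fewer than 2 samples: ", paste(small, collapse = ", ")))
  }
  invisible(meta)
}

#' Align an abundance table and its metadata on shared samples
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' abundance table's sample order (the canonical order downstream), and warns
#' about samples dropped from either side.
#'
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble.
#' @return A list with elements `abundance` and `metadata`.
#' @export
align_samples <- function(abundance, metadata) {
  abundance <- as_abundance(abundance, abundance_namespace(abundance))
  tab_samples <- names(abundance)[-1]
  shared <- intersect(tab_samples, metadata$sample)
  if (length(shared) == 0) abort("no samples shared between abundance table and metadata")
  dropped_tab <- setdiff(tab_samples, shared)
  dropped_meta <- setdiff(metadata$sample, shared)
  if (length(dropped_tab) || length(dropped_meta)) {
    warn(paste0("dropping unmatched samples — abundance: [",
                paste(dropped_tab, collapse = ", "), "]; metadata: [",
                paste(dropped_meta, collapse = ", "), "]"))
  }
  abundance <- abundance[c("feature", shared)]
  metadata <- metadata[match(shared, metadata$sample), ]
  list(abundance = as_abundance(abundance, abundance_namespace(abundance)),
       metadata = metadata)
}
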