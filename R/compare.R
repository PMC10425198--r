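#' Cross-method consensus report
#'
#' Given the results of several DA methods on the same feature universe,
#' reports per-method significant-feature counts, the features significant in
#' all methods, the features unique to exactly one method, and pairwise
#' Jaccard similarities of the significant sets (defined as 1 when both sets
#' are empty).
#'
#' @param results Either a named list of `da_results` tibbles or a single
#'   tibble covering several methods.
#' @param threshold Adjusted-p significance threshold (default 0.05).
#' @return A `consensus_report`: list with `per_method` (tibble of counts),
#'   `common_features`, `unique_features` (tibble `method`, `feature`),
#'   `jaccard` (tibble `method1`, `method2`, `jaccard`) and `threshold`.
#' @export
compare_daa_results <- function(results, threshold = 0.05) {
  if (is.data.frame(results)) {
    results <- split(as_tibble(results), results$method)
  }
  if (length(results) < 2) abort("need results from at least 2 methods")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- vapply(results, function(r) r$method[1], "")
  }
  contrasts <- lapply(results, function(r) sort(unique(paste(r$group1, r$group2))))
  if (length(unique(contrasts)) > 1) abort("methods compare different contrasts")
  universes <- lapply(results, function(r) sort(unique(r$feature)))
  sig <- lapply(results, function(r) unique(r$feature[r$p_adjust < threshold]))
  methods <- names(results)
  per_method <- tibble(method = methods,
                       n_features = unname(lengths(universes)),
                       n_significant = unname(lengths(sig)))
  common <- Reduce(intersect, sig)
  unique_features <- purrr::map_dfr(methods, function(mth) {
    others <- unlist(sig[setdiff(methods, mth)], use.names = FALSE)
    tibble(method = mth, feature = setdiff(sig[[mth]], others))
  })
  pairs <- combn(methods, 2, simplify = FALSE)
  jaccard <- purrr::map_dfr(pairs, function(pr) {
    a <- sig[[pr[1]]]; b <- sig[[pr[2]]]
    j <- if (length(a) == 0 && length(b) == 0) 1 else
      length(intersect(a, b)) / length(union(a, b))
    tibble(method1 = pr[1], method2 = pr[2], jaccard = j)
  })
  structure(list(per_method = per_method, common_features = sort(common),
                 unique_features = unique_features, jaccard = jaccard,
                 threshold = threshold),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> threshold", x$threshold, "\n")
  print(x$per_method)
  cat("common to all methods:", length(x$common_features), "feature(s)\n")
  invisible(x)
}

#' @method tidy consensus_report
#' @export
tidy.consensus_report <- function(x, ...) x$jaccard

#' @method glance consensus_report
#' @export
glance.consensus_report <- function(x, ...) {
  tibble(n_methods = nrow(x$per_method),
         n_common = length(x$common_features),
         mean_jaccard = mean(x$jaccard$jaccard),
         threshold = x$threshold)
}

#' Compare metagenome predictions from different sources
#'
#' Restricts all tables to their shared feature set, concatenates the samples
#' with the source name as the group label (sample ids suffixed by source to
#' keep them unique), runs [pathway_daa()] on the concatenation, and for each
#' source pair computes the Spearman correlation (and t-approximation
#' p-value) across shared features between the two abundance vectors of every
#' sample name present in both sources.
#'
#' @param tables Named list of >= 2 abundance tibbles.
#' @param method,adjust DA method and p-adjustment passed to [pathway_daa()].
#' @param reference Reference source for the DA contrast; defaults to the
#'   first name in sorted order.
#' @param seed Seed forwarded to [pathway_daa()].
#' @return A `metagenome_comparison`: list with `da_results`, `pairwise`
#'   (tibble `source1`, `source2`, `sample`, `rho`, `p`) and `summary`
#'   (tibble `source1`, `source2`, `mean_rho`, `n_samples`).
#' @export
compare_metagenome_results <- function(tables, method = "linda", adjust = "BH",
                                       reference = NULL, seed = 42) {
  if (length(tables) < 2) abort("need at least 2 metagenome tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a named list")
  }
  feats <- Reduce(intersect, lapply(tables, function(t) t$feature))
  if (length(feats) == 0) abort("no feature shared across all tables")
  srcs <- names(tables)
  mats <- lapply(tables, function(t) abd_matrix(as_abundance(t))[feats, , drop = FALSE])
  concat <- do.call(cbind, purrr::imap(mats, function(m, nm) {
    colnames(m) <- paste(colnames(m), nm, sep = "__")
    m
  }))
  meta <- as_metadata(
    tibble(sample = colnames(concat),
           group = rep(srcs, vapply(mats, ncol, 0L))),
    reference = reference)
  da <- pathway_daa(abd_from_matrix(concat, "UNKNOWN"), meta,
                    method = method, adjust = adjust, seed = seed)
  pairs <- combn(srcs, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    shared <- intersect(colnames(mats[[pr[1]]]), colnames(mats[[pr[2]]]))
    if (length(shared) == 0) {
      warn(paste0("sources ", pr[1], " and ", pr[2],
                  " share no sample names; correlations missing"))
      return(tibble(source1 = pr[1], source2 = pr[2], sample = NA_character_,
                    rho = NA_real_, p = NA_real_))
    }
    purrr::map_dfr(shared, function(s) {
      sc <- spearman_cor(mats[[pr[1]]][, s], mats[[pr[2]]][, s])
      tibble(source1 = pr[1], source2 = pr[2], sample = s,
             rho = sc$rho, p = sc$p)
    })
  })
  summary <- pairwise |>
    group_by(.data$source1, .data$source2) |>
    summarise(mean_rho = mean(.data$rho), n_samples = sum(!is.na(.data$rho)),
              .groups = "drop")
  structure(list(da_results = da, pairwise = pairwise, summary = summary),
            class = "metagenome_comparison")
}

#' @export
print.metagenome_comparison <- function(x, ...) {
  cat("<metagenome_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy metagenome_comparison
#' @export
tidy.metagenome_comparison <- function(x, ...) x$pairwise

#' @method glance metagenome_comparison
#' @export
glance.metagenome_comparison <- function(x, ...) x$summary
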