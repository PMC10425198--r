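#' Total-sum scaling (relative abundance)
#'
#' Divides every sample column by its total so columns sum to one.
#'
#' @param abundance Abundance tibble.
#' @return Abundance tibble of per-sample relative abundances.
#' @export
tss_normalize <- function(abundance) {
  abundance <- as_abundance(abundance, abundance_namespace(abundance))
  m <- abd_matrix(abundance)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  abd_from_matrix(sweep(m, 2, tot, "/"), abundance_namespace(abundance))
}

#' Centered log-ratio transform
#'
#' Per sample, `y_i = ln(x_i + pseudocount) - mean_j ln(x_j + pseudocount)`:
#' the standard compositional transform shared by the ALDEx2- and LinDA-style
#' methods. Each transformed sample sums to zero.
#'
#' @param abundance Abundance tibble.
#' @param pseudocount Positive offset added before taking logs (default 0.5);
#'   may be 0 when all abundances are strictly positive.
#' @return A tibble with the same shape as the input (`feature` column plus
#'   one column per sample) holding CLR values.
#' @export
clr_transform <- function(abundance, pseudocount = 0.5) {
  abundance <- as_abundance(abundance, abundance_namespace(abundance))
  m <- abd_matrix(abundance)
  if (pseudocount < 0 || (pseudocount == 0 && any(m <= 0))) {
    abort("pseudocount must be > 0 (or 0 on strictly positive data)")
  }
  y <- clr_matrix(m + pseudocount)
  out <- as_tibble(y, .name_repair = "minimal")
  dplyr::bind_cols(tibble(feature = rownames(m)), out)
}

# CLR of a strictly positive matrix (features x samples)
clr_matrix <- function(m) {
  lm_ <- log(m)
  sweep(lm_, 2, colMeans(lm_), "-")
}

# log2 counts-per-million with prior count, limma-voom style offset in the
# library size
log2_cpm <- function(m, prior_count = 0.5) {
  lib <- colSums(m) + 2 * prior_count
  log2(sweep(m + prior_count, 2, lib, "/") * 1e6)
}

# cumulative-sum scaling factors: per sample, sum of values at or below the
# sample's `quantile`-quantile of nonzero values
css_factors <- function(m, quantile = 0.5) {
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- x[x > 0]
    if (length(nz) == 0) return(0)
    q <- stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
    sum(x[x <= q])
  }, numeric(1))
}

#' Adjust p-values for multiple testing
#'
#' Thin, validated wrapper over [stats::p.adjust()] restricted to the
#' procedures the DA registry reports: Benjamini-Hochberg (`"BH"`),
#' `"bonferroni"`, `"holm"`, `"BY"` and `"none"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method Adjustment procedure.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm", "BY", "none")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}
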