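#' Differential-abundance method registry
#'
#' Eight natively implemented statistics share one input/output contract.
#' `welch_t` and `kruskal_wallis` are the classical baselines; the remaining
#' six are documented, simplified analogues of the tools commonly wrapped for
#' predicted functional profiles (ALDEx2, LinDA, limma-voom, metagenomeSeq
#' CSS, Maaslin2, LEfSe). `deseq2` and `edger` are reserved registry slots
#' and error as not implemented; ANCOM/ANCOM-BC are deliberately excluded.
#'
#' @return Character vector of available method names.
#' @export
da_methods <- function() {
  c("welch_t", "kruskal_wallis", "aldex2", "linda", "limma", "css",
    "maaslin2", "lefse")
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# half the smallest nonzero value, the pseudo used on relative-abundance scales
half_min_nonzero <- function(m) {
  nz <- m[m > 0]
  if (length(nz) == 0) abort("all-zero table")
  min(nz) / 2
}

group_indices <- function(meta) {
  g <- droplevels(meta$group)
  list(i1 = which(g == levels(g)[1]), i2 = which(g == levels(g)[2]),
       g1 = levels(g)[1], g2 = levels(g)[2])
}

# ---- two-group workers: m is the raw features x samples matrix, meta has
# exactly two group levels (reference first). Each returns a tibble with
# feature, effect, p_value and optionally p_adjust. ----

da_welch_t <- function(m, meta, ...) {
  gi <- group_indices(meta)
  rel <- sweep(m, 2, colSums(m), "/")
  w <- row_welch(rel, gi$i1, gi$i2)
  eps <- half_min_nonzero(rel)
  m1 <- rowMeans(rel[, gi$i1, drop = FALSE])
  m2 <- rowMeans(rel[, gi$i2, drop = FALSE])
  tibble(feature = rownames(m), effect = log2((m2 + eps) / (m1 + eps)),
         p_value = w$p)
}

da_kruskal <- function(m, meta, ...) {
  rel <- sweep(m, 2, colSums(m), "/")
  g <- droplevels(meta$group)
  kw <- row_kw(rel, g)
  eff <- rep(NA_real_, nrow(m))
  if (nlevels(g) == 2) {
    gi <- group_indices(meta)
    eps <- half_min_nonzero(rel)
    eff <- log2((rowMeans(rel[, gi$i2, drop = FALSE]) + eps) /
                (rowMeans(rel[, gi$i1, drop = FALSE]) + eps))
  }
  tibble(feature = rownames(m), effect = eff, p_value = kw$p)
}

da_aldex2 <- function(m, meta, M = 128, seed = 42, test = c("welch", "wilcoxon"),
                      ...) {
  test <- match.arg(test)
  if (M < 2) abort("aldex2 needs M >= 2 Monte-Carlo instances")
  counts <- round(m)
  off <- abs(m - counts) > 0.01
  if (mean(off) > 0.01) {
    warn(sprintf("aldex2: %.1f%% of cells rounded to integers for the Dirichlet draws",
                 100 * mean(off)))
  }
  g <- droplevels(meta$group)
  multi <- nlevels(g) > 2
  gi <- if (!multi) group_indices(meta)
  G <- nrow(m); S <- ncol(m)
  p_sum <- bh_sum <- numeric(G)
  eff <- matrix(NA_real_, G, M)
  with_seed(seed, {
    for (inst in seq_len(M)) {
      draws <- matrix(rgamma(G * S, shape = counts + 0.5), G, S)
      comp <- sweep(draws, 2, colSums(draws), "/")
      y <- clr_matrix(comp) / log(2)  # log2-scale CLR
      if (multi) {
        p <- row_kw(y, g)$p
      } else if (test == "welch") {
        p <- row_welch(y, gi$i1, gi$i2)$p
      } else {
        p <- row_kw(y, g)$p  # 2-group KW == tie-corrected Wilcoxon (normal approx)
      }
      p_sum <- p_sum + p
      bh_sum <- bh_sum + p.adjust(p, "BH")
      if (!multi) {
        eff[, inst] <- apply(y[, gi$i2, drop = FALSE], 1, median) -
          apply(y[, gi$i1, drop = FALSE], 1, median)
      }
    }
  })
  tibble(feature = rownames(m),
         effect = if (multi) NA_real_ else apply(eff, 1, median),
         p_value = p_sum / M, p_adjust = pmin(1, bh_sum / M))
}

# per-feature OLS of a response matrix on a two-level group: slope (group2 -
# group1), pooled-residual se and df
ols_two_group <- function(Y, gi) {
  n1 <- length(gi$i1); n2 <- length(gi$i2)
  m1 <- rowMeans(Y[, gi$i1, drop = FALSE])
  m2 <- rowMeans(Y[, gi$i2, drop = FALSE])
  ss <- rowSums((Y[, gi$i1, drop = FALSE] - m1)^2) +
        rowSums((Y[, gi$i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  list(b = m2 - m1, se = sqrt(s2 * (1 / n1 + 1 / n2)), s2 = s2, df = df)
}

# argmax of a Gaussian KDE (Silverman's rule-of-thumb bandwidth, 512-point
# grid spanning the data range); grid ties resolve to the smallest value
kde_mode <- function(x) {
  if (length(unique(x)) < 2) return(x[1])
  d <- density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

da_linda <- function(m, meta, pseudocount = 0.5, ...) {
  gi <- group_indices(meta)
  Y <- clr_matrix(m + pseudocount)
  fit <- ols_two_group(Y, gi)
  bstar <- fit$b - kde_mode(fit$b)
  zero_var <- fit$se == 0
  if (any(zero_var)) warn(paste0("linda: ", sum(zero_var),
                                 " zero-variance feature(s); p = 1 by convention"))
  p <- ifelse(zero_var, 1, 2 * pt(-abs(bstar / fit$se), df = fit$df))
  tibble(feature = rownames(m), effect = bstar / log(2), p_value = p)
}

# Newton inversion of the trigamma function (for the method-of-moments prior
# df of the variance shrinkage)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

da_limma <- function(m, meta, prior_count = 0.5, ...) {
  if (ncol(m) < 3) abort("limma analogue needs at least 3 samples")
  gi <- group_indices(meta)
  E <- log2_cpm(m, prior_count)
  fit <- ols_two_group(E, gi)
  ok <- fit$s2 > 0
  z <- log(fit$s2[ok])
  d <- fit$df
  evar <- var(z) - trigamma(d / 2)
  moderated <- TRUE
  if (!length(z) || !is.finite(evar)) {
    warn("limma analogue: variance-prior estimate non-finite; ordinary t used")
    moderated <- FALSE
  } else if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  }
  if (moderated && (!is.finite(s0_2) || is.nan(d0))) {
    warn("limma analogue: variance-prior estimate non-finite; ordinary t used")
    moderated <- FALSE
  }
  if (moderated) {
    s2_post <- if (is.finite(d0)) (d0 * s0_2 + d * fit$s2) / (d0 + d) else rep(s0_2, length(fit$s2))
    df_post <- d0 + d
  } else {
    s2_post <- fit$s2
    df_post <- d
  }
  n1 <- length(gi$i1); n2 <- length(gi$i2)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- ifelse(se > 0, 2 * pt(-abs(fit$b / se), df = df_post),
              ifelse(fit$b == 0, 1, 0))
  tibble(feature = rownames(m), effect = fit$b, p_value = p)
}

da_css <- function(m, meta, quantile = 0.5, ...) {
  gi <- group_indices(meta)
  s <- css_factors(m, quantile)
  if (any(s == 0)) {
    abort(paste0("css: zero scaling factor for sample(s) ",
                 paste(colnames(m)[s == 0], collapse = ", ")))
  }
  L <- log2(sweep(m, 2, s, "/") * 1000 + 1)
  w <- row_welch(L, gi$i1, gi$i2)
  tibble(feature = rownames(m), effect = w$diff, p_value = w$p)
}

da_maaslin2 <- function(m, meta, ...) {
  gi <- group_indices(meta)
  rel <- sweep(m, 2, colSums(m), "/")
  L <- log2(rel + half_min_nonzero(rel))
  covars <- setdiff(names(meta), c("sample", "group"))
  form <- if (length(covars)) {
    stats::as.formula(paste("~ group +", paste(covars, collapse = " + ")))
  } else ~group
  X <- stats::model.matrix(form, data = meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("collinear model column(s): ", paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, t(L))
  coefs <- t(fit$coefficients)
  gcol <- paste0("group", gi$g2)
  b <- coefs[, gcol]
  res <- t(fit$residuals)
  df <- ncol(m) - ncol(X)
  s2 <- rowSums(res^2) / df
  xtxinv <- solve(crossprod(X))
  se <- sqrt(s2 * xtxinv[gcol, gcol])
  p <- ifelse(se > 0, 2 * pt(-abs(b / se), df = df), ifelse(b == 0, 1, 0))
  tibble(feature = rownames(m), effect = unname(b), p_value = p)
}

da_lefse <- function(m, meta, alpha_screen = 0.05, lda_threshold = 2.0, ...) {
  g <- droplevels(meta$group)
  if (nlevels(g) != 2) abort("lefse analogue supports exactly 2 groups")
  gi <- group_indices(meta)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  p <- row_kw(cpm, g)$p
  m1 <- rowMeans(cpm[, gi$i1, drop = FALSE])
  m2 <- rowMeans(cpm[, gi$i2, drop = FALSE])
  score <- ifelse(p < alpha_screen, sign(m2 - m1) * log10(1 + abs(m2 - m1)), 0)
  out <- tibble(feature = rownames(m), effect = score, p_value = p)
  attr(out, "lda_threshold") <- lda_threshold
  out
}

da_registry <- function() {
  list(welch_t = da_welch_t, kruskal_wallis = da_kruskal, aldex2 = da_aldex2,
       linda = da_linda, limma = da_limma, css = da_css,
       maaslin2 = da_maaslin2, lefse = da_lefse)
}

#' Run a differential-abundance method on a feature table
#'
#' Aligns the table and metadata, drops features with zero total abundance,
#' dispatches to the requested method and returns one tidy record per
#' (feature, contrast). With more than two groups, two-group methods are run
#' pairwise against the reference group and the p-value adjustment is pooled
#' across the full feature-by-contrast set; `kruskal_wallis` is the omnibus
#' exception (`group2 = "(all)"`). The `aldex2` method reports its own
#' Monte-Carlo-averaged Benjamini-Hochberg q-values.
#'
#' @param abundance Abundance tibble (features x samples).
#' @param metadata Metadata tibble from [as_metadata()]/[read_metadata()].
#' @param method One of [da_methods()].
#' @param adjust Multiple-testing procedure, see [adjust_pvalues()].
#' @param seed Integer seed for the Monte-Carlo method (`aldex2`).
#' @param ... Method-specific parameters (`M`, `test`, `pseudocount`,
#'   `prior_count`, `quantile`, `alpha_screen`, `lda_threshold`).
#' @return A `da_results` tibble with columns `feature`, `method`, `group1`
#'   (reference), `group2`, `effect` (log2 scale, method-specific
#'   definition), `p_value`, `p_adjust`, `adjust_method`.
#' @export
pathway_daa <- function(abundance, metadata, method = "linda", adjust = "BH",
                        seed = 42, ...) {
  known <- c(da_methods(), "deseq2", "edger")
  if (!method %in% known) {
    abort(paste0("unknown method '", method, "' (available: ",
                 paste(da_methods(), collapse = ", "), ")"))
  }
  if (method %in% c("deseq2", "edger")) {
    abort(paste0("method '", method, "' is a reserved registry slot, not implemented"))
  }
  al <- align_samples(abundance, metadata)
  meta <- al$metadata
  check_da_metadata(meta)
  m <- abd_matrix(al$abundance)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn(paste0("dropping ", sum(zero), " zero-total feature(s) before testing"))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no nonzero feature to test")
  fn <- da_registry()[[method]]
  g <- droplevels(meta$group)
  ref <- levels(g)[1]
  if (method == "kruskal_wallis" || nlevels(g) == 2) {
    res <- fn(m, meta, seed = seed, ...)
    g2 <- if (method == "kruskal_wallis" && nlevels(g) > 2) "(all)" else levels(g)[2]
    res$group1 <- ref
    res$group2 <- g2
  } else {
    others <- levels(g)[-1]
    res <- purrr::map_dfr(others, function(lv) {
      keep <- g %in% c(ref, lv)
      sub_meta <- meta[keep, , drop = FALSE]
      sub_meta$group <- factor(as.character(sub_meta$group), levels = c(ref, lv))
      out <- fn(m[, keep, drop = FALSE], sub_meta, seed = seed, ...)
      out$group1 <- ref
      out$group2 <- lv
      out
    })
  }
  if (!"p_adjust" %in% names(res)) {
    res$p_adjust <- adjust_pvalues(res$p_value, adjust)
  } else {
    adjust <- "BH"  # aldex2 carries its instance-averaged BH q-values
  }
  res$method <- method
  res$adjust_method <- adjust
  for (col in c("effect", "p_value", "p_adjust")) res[[col]] <- unname(res[[col]])
  out <- select(res, "feature", "method", "group1", "group2", "effect",
                "p_value", "p_adjust", "adjust_method")
  class(out) <- c("da_results", class(out))
  out
}

#' @method glance da_results
#' @export
glance.da_results <- function(x, threshold = 0.05, ...) {
  x |>
    group_by(.data$method, .data$group1, .data$group2) |>
    summarise(n_features = n(),
              n_significant = sum(.data$p_value < threshold, na.rm = TRUE),
              n_significant_adj = sum(.data$p_adjust < threshold, na.rm = TRUE),
              .groups = "drop")
}
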