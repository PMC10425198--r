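# small in-code fixtures and independent oracles shared across test files

tiny_abundance <- function(values = NULL, features = c("K00001", "K00002", "K00003"),
                           samples = c("S1", "S2", "S3", "S4")) {
  if (is.null(values)) {
    values <- matrix(c(10, 20, 30, 40,
                       5, 5, 50, 50,
                       1, 0, 2, 0), nrow = 3, byrow = TRUE)
  }
  dimnames(values) <- list(features, samples)
  as_abundance(dplyr::bind_cols(tibble::tibble(feature = features),
                                tibble::as_tibble(values, .name_repair = "minimal")))
}

tiny_metadata <- function(samples = c("S1", "S2", "S3", "S4"),
                          groups = c("A", "A", "B", "B"), reference = "A") {
  as_metadata(tibble::tibble(sample = samples, group = groups), reference = reference)
}

# independent step-up Benjamini-Hochberg oracle (literal definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  # step-up: running minimum from the largest rank down
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# brute-force KO->pathway aggregation oracle: literal per-cell sum
ko2kegg_oracle <- function(tab, map) {
  m <- as.matrix(tab[-1])
  rownames(m) <- tab$feature
  pws <- sort(unique(map$pathway))
  out <- matrix(0, length(pws), ncol(m), dimnames = list(pws, colnames(m)))
  for (p in pws) {
    for (s in colnames(m)) {
      tot <- 0
      for (k in map$ko[map$pathway == p]) {
        if (k %in% rownames(m)) tot <- tot + m[k, s]
      }
      out[p, s] <- tot
    }
  }
  out
}

random_abundance <- function(n_feat, n_samp, prefix = "K", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, 20), n_feat, n_samp)
  feats <- sprintf("%s%05d", prefix, sample(99999, n_feat))
  dimnames(m) <- list(feats, paste0("S", seq_len(n_samp)))
  as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                tibble::as_tibble(m, .name_repair = "minimal")),
               namespace = "KO")
}

# shared cache so the expensive spiked/null fixtures are computed once per run
fixture_cache <- new.env(parent = emptyenv())

cached_daa <- function(kind = c("null", "spiked"), method, seed, M = 64) {
  kind <- match.arg(kind)
  key <- paste(kind, method, seed, M, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    sim <- if (kind == "null") {
      simulate_profile(prop_da = 0, effect_log2 = 0, seed = seed)
    } else {
      simulate_profile(seed = seed)
    }
    res <- suppressWarnings(
      pathway_daa(sim$abundance, sim$metadata, method = method, seed = seed, M = M))
    fixture_cache[[key]] <- dplyr::left_join(tibble::as_tibble(res), sim$truth,
                                             by = "feature")
  }
  fixture_cache[[key]]
}
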