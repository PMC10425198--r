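#' Simulate a KO abundance table with known differential-abundance truth
#'
#' Generates a spike-in benchmark dataset: a baseline composition is drawn
#' log-normal(0, 1) over features and normalized; in every non-reference
#' group the spiked features are multiplied by `2^effect_log2` and the
#' composition renormalized (so non-spiked features carry the small induced
#' compositional bias that CLR-based bias correction is meant to absorb);
#' per-sample sequencing depths are Poisson(`depth_mean`); counts are drawn
#' multinomially at `dispersion = 0`, otherwise from a gamma-Poisson mixture
#' whose gamma multiplier has unit mean and variance `dispersion`. Feature
#' ids are sampled from the packaged reference map's KO universe so the
#' KO-to-pathway aggregation is exercisable end to end.
#'
#' @param n_features Number of KO features.
#' @param n_per_group Samples per group.
#' @param n_groups Number of groups (first group, "A", is the reference).
#' @param prop_da Proportion of features spiked.
#' @param effect_log2 log2 fold change of spiked features (non-reference vs
#'   reference group).
#' @param depth_mean Mean per-sample sequencing depth.
#' @param dispersion Variance of the unit-mean gamma multiplier; 0 gives
#'   exact multinomial sampling. Default 0.5, a moderate level of
#'   between-sample biological overdispersion.
#' @param seed Integer seed; the result is bit-reproducible.
#' @return A `sim_profile`: list with `abundance` (KO abundance tibble),
#'   `metadata`, `truth` (tibble: feature, is_da, true_log2_effect) and the
#'   call's `config`.
#' @export
simulate_profile <- function(n_features = 500, n_per_group = 20, n_groups = 2,
                             prop_da = 0.1, effect_log2 = 2, depth_mean = 5e4,
                             dispersion = 0.5, seed = 1) {
  stopifnot(n_features >= 2, n_per_group >= 2, n_groups >= 2,
            prop_da >= 0, prop_da <= 1, depth_mean > 0, dispersion >= 0)
  n_da <- round(prop_da * n_features)
  ko_universe <- load_reference_map()$ko_info$id
  with_seed(seed, {
    feats <- sort(sample(ko_universe, n_features,
                         replace = n_features > length(ko_universe)))
    if (anyDuplicated(feats)) feats <- make.unique(feats)
    base <- exp(rnorm(n_features))
    base <- base / sum(base)
    spiked <- sort(sample(seq_len(n_features), n_da))
    groups <- LETTERS[seq_len(n_groups)]
    probs <- lapply(groups, function(g) {
      p <- base
      if (g != groups[1] && n_da > 0) p[spiked] <- p[spiked] * 2^effect_log2
      p / sum(p)
    })
    names(probs) <- groups
    n_samples <- n_per_group * n_groups
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    group_of <- rep(groups, each = n_per_group)
    counts <- matrix(0, n_features, n_samples,
                     dimnames = list(feats, sample_ids))
    for (j in seq_len(n_samples)) {
      depth <- rpois(1, depth_mean)
      p <- probs[[group_of[j]]]
      if (dispersion == 0) {
        counts[, j] <- rmultinom(1, depth, p)
      } else {
        mult <- rgamma(n_features, shape = 1 / dispersion, rate = 1 / dispersion)
        counts[, j] <- rpois(n_features, depth * p * mult)
      }
    }
    truth <- tibble(feature = feats,
                    is_da = seq_len(n_features) %in% spiked,
                    true_log2_effect = ifelse(seq_len(n_features) %in% spiked,
                                              effect_log2, 0))
    metadata <- as_metadata(tibble(sample = sample_ids, group = group_of),
                            reference = groups[1])
    structure(list(abundance = abd_from_matrix(counts, "KO"),
                   metadata = metadata, truth = truth,
                   config = list(n_features = n_features,
                                 n_per_group = n_per_group,
                                 n_groups = n_groups, prop_da = prop_da,
                                 effect_log2 = effect_log2,
                                 depth_mean = depth_mean,
                                 dispersion = dispersion, seed = seed)),
              class = "sim_profile")
  })
}

#' @export
print.sim_profile <- function(x, ...) {
  cfg <- x$config
  cat("<sim_profile>", cfg$n_features, "features x",
      cfg$n_per_group * cfg$n_groups, "samples;",
      sum(x$truth$is_da), "spiked (log2 effect", cfg$effect_log2, ")\n")
  invisible(x)
}
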