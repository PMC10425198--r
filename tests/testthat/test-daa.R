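da_fixture <- function(seed = 9, n_feat = 30, n = 6) {
  set.seed(seed)
  tab <- random_abundance(n_feat, 2 * n)
  meta <- tiny_metadata(samples = names(tab)[-1],
                        groups = rep(c("A", "B"), each = n))
  list(tab = tab, meta = meta)
}

test_that("pathway_daa returns one tidy record per feature and contrast", {
  fx <- da_fixture()
  res <- pathway_daa(fx$tab, fx$meta, method = "welch_t")
  expect_s3_class(res, "da_results")
  expect_identical(names(res), c("feature", "method", "group1", "group2",
                                 "effect", "p_value", "p_adjust", "adjust_method"))
  expect_setequal(res$feature, fx$tab$feature)
  expect_true(all(res$group1 == "A" & res$group2 == "B"))
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
  expect_equal(res$p_adjust, adjust_pvalues(res$p_value, "BH"))
})

test_that("unknown and reserved methods are refused", {
  fx <- da_fixture()
  expect_error(pathway_daa(fx$tab, fx$meta, method = "ancombc"), "unknown method")
  expect_error(pathway_daa(fx$tab, fx$meta, method = "ancom"), "unknown method")
  expect_error(pathway_daa(fx$tab, fx$meta, method = "deseq2"), "reserved")
  expect_error(pathway_daa(fx$tab, fx$meta, method = "edger"), "reserved")
})

test_that("zero-total features are dropped with a warning before testing", {
  fx <- da_fixture()
  tab <- fx$tab
  tab[2, -1] <- as.list(rep(0, ncol(tab) - 1))
  expect_warning(res <- pathway_daa(tab, fx$meta, method = "welch_t"),
                 "zero-total")
  expect_false(tab$feature[2] %in% res$feature)
})

test_that("three groups give pairwise contrasts against the reference only", {
  set.seed(10)
  tab <- random_abundance(20, 9)
  meta <- tiny_metadata(samples = names(tab)[-1],
                        groups = rep(c("A", "B", "C"), each = 3))
  res <- pathway_daa(tab, meta, method = "welch_t")
  expect_setequal(unique(res$group2), c("B", "C"))
  expect_true(all(res$group1 == "A"))
  expect_equal(nrow(res), 2 * 20)
  # adjustment pooled over the full feature x contrast set
  expect_equal(res$p_adjust, adjust_pvalues(res$p_value, "BH"))
  # kruskal_wallis stays omnibus
  omni <- pathway_daa(tab, meta, method = "kruskal_wallis")
  expect_true(all(omni$group2 == "(all)"))
  expect_equal(nrow(omni), 20)
})

test_that("groups with fewer than two samples are rejected", {
  set.seed(11)
  tab <- random_abundance(10, 3)
  meta <- tiny_metadata(samples = names(tab)[-1], groups = c("A", "A", "B"))
  expect_error(pathway_daa(tab, meta, method = "welch_t"), "fewer than 2")
})

test_that("aldex2 analogue is bit-reproducible for a fixed seed", {
  fx <- da_fixture(n_feat = 15, n = 4)
  r1 <- pathway_daa(fx$tab, fx$meta, method = "aldex2", seed = 3, M = 8)
  r2 <- pathway_daa(fx$tab, fx$meta, method = "aldex2", seed = 3, M = 8)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- pathway_daa(fx$tab, fx$meta, method = "aldex2", seed = 4, M = 8)
  expect_false(identical(r1$p_value, r3$p_value))
})

test_that("aldex2 Monte-Carlo compositions have the Dirichlet posterior mean", {
  # counts [0, 10] with +0.5 prior -> posterior mean (0.5, 10.5)/11.5
  set.seed(1)
  counts <- c(0, 10)
  M <- 5000
  draws <- matrix(rgamma(2 * M, shape = counts + 0.5), 2, M)
  comp <- sweep(draws, 2, colSums(draws), "/")
  expect_equal(rowMeans(comp), (counts + 0.5) / sum(counts + 0.5),
               tolerance = 0.02)
})

test_that("aldex2 effect direction follows the group contrast", {
  set.seed(12)
  m <- matrix(rpois(20 * 8, 50), 20, 8)
  m[1, 5:8] <- m[1, 5:8] * 8  # strongly up in group B
  feats <- sprintf("K%05d", 1:20)
  dimnames(m) <- list(feats, paste0("S", 1:8))
  tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                       tibble::as_tibble(m, .name_repair = "minimal")), "KO")
  meta <- tiny_metadata(samples = paste0("S", 1:8), groups = rep(c("A", "B"), each = 4))
  res <- pathway_daa(tab, meta, method = "aldex2", seed = 1, M = 32)
  expect_gt(res$effect[res$feature == "K00001"], 1)
  expect_lt(res$p_value[res$feature == "K00001"], 0.05)
})

test_that("linda mode correction recenters slopes on the dominant cluster", {
  mode_est <- profda:::kde_mode(c(1.00, 1.02, 0.98, 5.00))
  expect_equal(mode_est, 1.00, tolerance = 0.05)

  # flipping the contrast negates corrected effects
  fx <- da_fixture(n_feat = 25, n = 5)
  res_ab <- pathway_daa(fx$tab, fx$meta, method = "linda")
  meta_flip <- as_metadata(fx$meta, reference = "B")
  res_ba <- pathway_daa(fx$tab, meta_flip, method = "linda")
  expect_equal(res_ba$effect, -res_ab$effect, tolerance = 1e-9)
  expect_equal(res_ba$p_value, res_ab$p_value, tolerance = 1e-9)
})

test_that("linda corrected null slopes center on zero", {
  sim <- simulate_profile(n_features = 500, n_per_group = 50, prop_da = 0,
                          effect_log2 = 0, seed = 21)
  res <- pathway_daa(sim$abundance, sim$metadata, method = "linda")
  # mean corrected CLR slope (natural-log scale) stays near zero
  expect_lt(abs(mean(res$effect * log(2))), 0.05)
})

test_that("limma analogue shrinks feature variances toward the prior", {
  fx <- da_fixture(n_feat = 40, n = 5)
  m <- as.matrix(fx$tab[-1]); rownames(m) <- fx$tab$feature
  res <- pathway_daa(fx$tab, fx$meta, method = "limma")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # ordinary-t limit: d0 = 0 leaves the t statistic unmoderated
  E <- profda:::log2_cpm(m)
  gi <- profda:::group_indices(fx$meta)
  fit <- profda:::ols_two_group(E, gi)
  t_ord <- fit$b / fit$se
  s0_2 <- exp(mean(log(fit$s2)))
  d0 <- 8
  s2_post <- (d0 * s0_2 + fit$df * fit$s2) / (d0 + fit$df)
  # moderated variances lie between the per-feature and prior variances
  expect_true(all((s2_post - pmin(fit$s2, s0_2)) > -1e-12 &
                  (pmax(fit$s2, s0_2) - s2_post) > -1e-12))
  expect_equal(res$effect, unname(fit$b))  # effects are the OLS log2FC
})

test_that("css scaling uses the cumulative sum below the sample quantile", {
  expect_equal(profda:::css_factors(matrix(c(1, 2, 3, 100), 4, 1)), 3)
  # doubling a sample's counts doubles its factor, leaving normalized values fixed
  m <- matrix(c(1, 2, 3, 100), 4, 1)
  expect_equal(profda:::css_factors(2 * m), 6)
  expect_equal(2 * m / profda:::css_factors(2 * m), m / profda:::css_factors(m))
})

test_that("css on identical groups returns null effects and p-values", {
  m <- matrix(rep(c(5, 10, 20, 40), 8), 4, 8)
  feats <- paste0("K0000", 1:4)
  dimnames(m) <- list(feats, paste0("S", 1:8))
  tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                       tibble::as_tibble(m, .name_repair = "minimal")), "KO")
  meta <- tiny_metadata(samples = paste0("S", 1:8), groups = rep(c("A", "B"), each = 4))
  res <- pathway_daa(tab, meta, method = "css")
  expect_true(all(res$effect == 0))
  expect_true(all(res$p_value == 1))
})

test_that("maaslin2 analogue handles covariates and rejects collinearity", {
  fx <- da_fixture(n_feat = 15, n = 6)
  res_plain <- pathway_daa(fx$tab, fx$meta, method = "maaslin2")
  # covariate orthogonal to the group indicator leaves the group effect unchanged
  meta_cov <- fx$meta
  meta_cov$batch <- rep(c(-1, 1), times = 6)  # balanced within both groups
  res_cov <- pathway_daa(fx$tab, meta_cov, method = "maaslin2")
  expect_equal(res_cov$effect, res_plain$effect, tolerance = 1e-9)

  meta_bad <- fx$meta
  meta_bad$dupgroup <- as.numeric(meta_bad$group == "B")
  expect_error(pathway_daa(fx$tab, meta_bad, method = "maaslin2"), "collinear.*dupgroup")
})

test_that("lefse score is the signed log10 CPM difference past the screen", {
  m <- matrix(1e6 / 3, 3, 8)
  m[1, ] <- c(0, 0, 0, 0, 99, 99, 99, 99)
  feats <- c("K00001", "K00002", "K00003")
  dimnames(m) <- list(feats, paste0("S", 1:8))
  # make columns sum exactly to 1e6 so CPM equals the raw values
  m[3, ] <- 1e6 - colSums(m[1:2, , drop = FALSE])
  tab <- as_abundance(dplyr::bind_cols(tibble::tibble(feature = feats),
                                       tibble::as_tibble(m, .name_repair = "minimal")), "KO")
  meta <- tiny_metadata(samples = paste0("S", 1:8), groups = rep(c("A", "B"), each = 4))
  res <- pathway_daa(tab, meta, method = "lefse")
  expect_equal(res$effect[res$feature == "K00001"], 2)  # log10(1 + 99) exactly
  # swapping groups negates the score
  res_flip <- pathway_daa(tab, as_metadata(meta, reference = "B"), method = "lefse")
  expect_equal(res_flip$effect, -res$effect)
  # a feature with equal means scores zero
  expect_equal(res$effect[res$feature == "K00002"], 0)
})

test_that("the lefse worker itself refuses more than two groups", {
  set.seed(13)
  tab <- random_abundance(10, 9)
  meta <- tiny_metadata(samples = names(tab)[-1],
                        groups = rep(c("A", "B", "C"), each = 3))
  m <- as.matrix(tab[-1]); rownames(m) <- tab$feature
  expect_error(profda:::da_lefse(m, meta), "2 groups")
  # via the dispatcher, two-group-only methods fall back to pairwise contrasts
  res <- pathway_daa(tab, meta, method = "lefse")
  expect_setequal(unique(res$group2), c("B", "C"))
})
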