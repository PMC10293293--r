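# condition-mean matrices built directly over the 27 light cells + dark
make_cm <- function(values_by_site) {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  qm <- tibble::tibble(site_id = names(values_by_site))
  m <- do.call(rbind, values_by_site)
  colnames(m) <- conds
  dplyr::bind_cols(qm, tibble::as_tibble(m))
}

light_cells <- function(cm) grep("^(Su|Pe|Pu)0", names(cm), value = TRUE)

test_that("identical intensity-group profiles give t = 0, p = 1", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  v <- setNames(rep(3, length(conds)), conds)
  cm <- make_cm(list(s1 = v))
  res <- paired_intensity_tests(cm)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
})

test_that("a constant shift across all pairs hits the epsilon guard", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  v <- setNames(rep(0, length(conds)), conds)
  v[grep("025", conds)] <- 1 # exact +1 in every 025 cell
  cm <- make_cm(list(s1 = v))
  res <- paired_intensity_tests(cm)
  r <- res[res$comparison == "025vs005", ]
  expect_equal(r$mean_log2fc, 1)
  expect_lt(r$p, 1e-12)
})

test_that("the paired t equals the one-sample t on differences", {
  set.seed(3)
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  cm <- make_cm(lapply(setNames(1:25, paste0("s", 1:25)), function(i) {
    setNames(rnorm(length(conds)), conds)
  }))
  res <- paired_intensity_tests(cm)
  cells005 <- sort(grep("005", light_cells(cm), value = TRUE))
  cells010 <- sort(grep("010", light_cells(cm), value = TRUE))
  for (i in 1:25) {
    hi <- as.numeric(cm[i, cells010])
    lo <- as.numeric(cm[i, cells005])
    oracle <- stats::t.test(hi, lo, paired = TRUE)
    ours <- res[res$site_id == paste0("s", i) & res$comparison == "010vs005", ]
    expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
    expect_equal(ours$df, 8)
  }
})

test_that("missing cells exclude pairs and small comparisons are unscored", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  v <- setNames(rnorm(length(conds)), conds)
  v[grep("^Su005", names(v))] <- NA # 3 of 9 pairs lost for 0x5 comparisons
  cm <- make_cm(list(s1 = v))
  res <- paired_intensity_tests(cm)
  expect_equal(res$n_pairs[res$comparison == "010vs005"], 6)
  expect_equal(res$n_pairs[res$comparison == "025vs010"], 9)
  expect_equal(res$df[res$comparison == "010vs005"], 5)
})

test_that("the gate requires both p-values and both fold changes", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  base <- setNames(rep(0, length(conds)), conds)
  up <- base
  up[grep("010", conds)] <- 0.7
  up[grep("025", conds)] <- 1.4
  weak <- base
  weak[grep("010", conds)] <- 0.3 # fails the 1.5-fold gate in 010vs005
  weak[grep("025", conds)] <- 1.4
  down <- base
  down[grep("010", conds)] <- -0.7 # two-sided gate admits dephosphorylation
  down[grep("025", conds)] <- -1.4
  cm <- make_cm(list(up = up, weak = weak, down = down))
  res <- paired_intensity_tests(cm)
  expect_equal(
    sort(intensity_regulated_sites(res, alpha = 0.01, fold = 1.5)),
    c("down", "up")
  )
  # the stricter gate additionally requires 025 vs 010 significance
  expect_equal(
    sort(intensity_regulated_sites(res, gate = "all-three")),
    c("down", "up")
  )
})

test_that("anti-correlated profile families separate perfectly at k = 2", {
  set.seed(5)
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  shape <- rnorm(length(conds))
  fam <- c(rep(1, 10), rep(2, 10))
  vals <- lapply(seq_along(fam), function(i) {
    s <- if (fam[i] == 1) shape else -shape
    setNames(s + rnorm(length(conds), 0, 0.01), conds)
  })
  names(vals) <- paste0("s", seq_along(fam))
  cm <- make_cm(vals)
  cl <- cluster_intensity_profiles(cm, cm$site_id, k = 2)
  expect_equal(match_accuracy(cl$cluster, as.character(fam)), 1)
})

test_that("duplicated rows always co-cluster", {
  set.seed(6)
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  vals <- lapply(1:6, function(i) setNames(rnorm(length(conds)), conds))
  vals <- c(vals, vals[1]) # duplicate of the first profile
  names(vals) <- paste0("s", 1:7)
  cm <- make_cm(vals)
  cl <- cluster_intensity_profiles(cm, cm$site_id, k = 3)
  expect_equal(cl$cluster[cl$site_id == "s1"], cl$cluster[cl$site_id == "s7"])
})

test_that("fewer passing sites than clusters is an informative error", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  cm <- make_cm(list(s1 = setNames(rnorm(length(conds)), conds)))
  expect_error(
    cluster_intensity_profiles(cm, "s1", k = 5),
    "smaller k",
    class = "optophos_validation_error"
  )
})

test_that("up-regulated and suppressed planted classes separate (ARI >= 0.9)", {
  sim <- simulate_phospho_experiment(seed = 4)
  cm <- condition_means(sim$quant, sim$design)
  sites <- sim$truth$site_id[sim$truth$class %in% c("direct_fast", "suppressed")]
  cl <- cluster_intensity_profiles(cm, sites, k = 2)
  truth <- sim$truth$class[match(cl$site_id, sim$truth$site_id)]
  ari <- mclust::adjustedRandIndex(cl$cluster, truth)
  expect_gte(ari, 0.9)
})

test_that("planted signal sites pass the gate and null sites do not", {
  pass_rates <- sapply(1:3, function(s) {
    sim <- simulate_phospho_experiment(quick_sim_config(), seed = s)
    cm <- condition_means(sim$quant, sim$design)
    pass <- intensity_regulated_sites(paired_intensity_tests(cm))
    df_sites <- sim$truth$site_id[sim$truth$class == "direct_fast"]
    null_sites <- sim$truth$site_id[sim$truth$class == "null"]
    c(mean(df_sites %in% pass), mean(null_sites %in% pass))
  })
  expect_gte(mean(pass_rates[1, ]), 0.8)
  expect_lte(mean(pass_rates[2, ]), 0.02)
})
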