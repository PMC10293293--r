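make_cm2 <- function(rows) {
  n <- length(rows[[1]])
  qm <- tibble::tibble(site_id = names(rows))
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("c", seq_len(n))
  dplyr::bind_cols(qm, tibble::as_tibble(m))
}

test_that("self, anti and affine-transformed profiles give the expected R", {
  set.seed(20)
  ref <- rnorm(20)
  cm <- make_cm2(list(
    ref = ref, same = ref, anti = -ref, affine = 2 * ref + 3,
    noise = rnorm(20)
  ))
  cv <- correlate_to_reference(cm, "ref")
  expect_equal(cv$r[cv$site_id == "ref"], 1)
  expect_equal(cv$r[cv$site_id == "same"], 1)
  expect_equal(cv$r[cv$site_id == "anti"], -1)
  expect_equal(cv$r[cv$site_id == "affine"], 1)
  expect_true(all(abs(cv$r) <= 1))
  expect_error(correlate_to_reference(cm, "ghost"), class = "optophos_validation_error")
})

test_that("sites with too few complete pairs are unscored", {
  set.seed(21)
  ref <- rnorm(20)
  sparse <- ref
  sparse[1:12] <- NA
  cm <- make_cm2(list(ref = ref, sparse = sparse))
  cv <- correlate_to_reference(cm, "ref", min_n = 10)
  expect_false(cv$scored[cv$site_id == "sparse"])
  expect_true(is.na(cv$r[cv$site_id == "sparse"]))
})

test_that("the flagged set shrinks monotonically with the threshold", {
  set.seed(22)
  ref <- rnorm(30)
  rows <- c(list(ref = ref), lapply(setNames(1:40, paste0("s", 1:40)), function(i) {
    ref + rnorm(30, 0, runif(1, 0.1, 2))
  }))
  cm <- make_cm2(rows)
  sets <- lapply(c(0.5, 0.7, 0.85, 0.95), function(thr) {
    cv <- correlate_to_reference(cm, "ref", threshold = thr)
    cv$site_id[cv$covaries]
  })
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("rank-sum benchmarking matches an exhaustive permutation oracle", {
  set.seed(23)
  for (rep in 1:10) {
    r_in <- runif(5, -1, 1)
    r_out <- runif(5, -1, 1)
    cv <- tibble::tibble(
      site_id = paste0("s", 1:10), r = c(r_in, r_out),
      n_used = 20, scored = TRUE, covaries = FALSE
    )
    ann <- tibble::tibble(
      site_id = cv$site_id, in_list = rep(c(TRUE, FALSE), each = 5)
    )
    bench <- benchmark_lists(cv, ann, lists = "in_list")
    expect_equal(bench$p, wilcox_perm_oracle(r_in, r_out), tolerance = 1e-12)
  }
})

test_that("an extreme list separates with a near-zero p-value", {
  set.seed(24)
  r <- sort(runif(200, -1, 1), decreasing = TRUE)
  cv <- tibble::tibble(
    site_id = paste0("s", 1:200), r = r, n_used = 30, scored = TRUE,
    covaries = r > 0.85
  )
  ann <- tibble::tibble(site_id = cv$site_id, top = seq_along(r) <= 30)
  bench <- benchmark_lists(cv, ann, lists = "top")
  expect_lt(bench$p, 1e-15)
  wf <- waterfall_table(cv, ann, lists = "top")
  expect_equal(wf$r, sort(r, decreasing = TRUE))
  expect_true(all(wf$top[1:30]))
})

test_that("a random list gives calibrated type-I behaviour", {
  set.seed(25)
  pvals <- replicate(200, {
    r <- rnorm(60)
    cv <- tibble::tibble(
      site_id = paste0("s", 1:60), r = r, n_used = 30,
      scored = TRUE, covaries = FALSE
    )
    ann <- tibble::tibble(site_id = cv$site_id, rand = sample(c(TRUE, FALSE), 60, TRUE))
    benchmark_lists(cv, ann, lists = "rand")$p
  })
  level <- mean(pvals < 0.05)
  expect_lt(abs(level - 0.05), 3.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("mutual support reproduces constructed overlap arithmetic", {
  ident <- list(a = c("x", "y"), b = c("x", "y"))
  ms <- mutual_support(ident)
  expect_equal(ms$support$pct_ge1, c(100, 100))
  disj <- list(a = c("x", "y"), b = c("u", "v"))
  expect_equal(mutual_support(disj)$support$pct_ge1, c(0, 0))

  lists <- list(
    L1 = c("a", "b", "c", "d"),
    L2 = c("a", "b", "e"),
    L3 = c("a", "f"),
    L4 = c("g"),
    L5 = c("b", "g")
  )
  ms <- mutual_support(lists)
  # L1: a in L2+L3, b in L2+L5, c/d nowhere -> 50% >=1; a,b supported twice -> 50% >=2
  s1 <- ms$support[ms$support$list == "L1", ]
  expect_equal(s1$pct_ge1, 50)
  expect_equal(s1$pct_ge2, 50)
  s4 <- ms$support[ms$support$list == "L4", ]
  expect_equal(s4$pct_ge1, 100) # g in L5
  expect_equal(s4$pct_ge2, 0)
  ov <- ms$pairwise
  expect_equal(ov$overlap[ov$list1 == "L1" & ov$list2 == "L2"], 2)
  expect_error(mutual_support(lists[1]), class = "optophos_validation_error")
})

test_that("reference-tracking planted sites covary and nulls do not", {
  sim <- simulate_phospho_experiment(quick_sim_config(), seed = 14)
  cm <- condition_means(sim$quant, sim$design)
  cv <- correlate_to_reference(cm, "AKT1_T308")
  j <- dplyr::left_join(cv, sim$truth[, c("site_id", "class")], by = "site_id")
  expect_gt(
    stats::median(j$r[j$class == "direct_fast"], na.rm = TRUE),
    stats::median(j$r[j$class == "null"], na.rm = TRUE)
  )
  expect_lte(mean(j$covaries[j$class == "null"]), 0.05)
})
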