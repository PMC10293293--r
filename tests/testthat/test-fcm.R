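two_blobs <- function(n_per = 20, sep = 6, sd = 0.2, p = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0, sd), n_per, p),
    matrix(rnorm(n_per * p, sep, sd), n_per, p)
  )
  rownames(x) <- paste0("s", seq_len(2 * n_per))
  x
}

test_that("well-separated blobs yield near-hard memberships and true centers", {
  x <- two_blobs()
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.25, seed = 1)
  mx <- apply(fit$membership, 1, max)
  expect_true(all(mx > 0.99))
  got <- fit$centers[order(fit$centers[, 1]), ]
  expect_lt(max(abs(got[1, ] - 0)), 0.05)
  expect_lt(max(abs(got[2, ] - 6)), 0.05)
})

test_that("memberships sum to one and the objective never increases", {
  x <- two_blobs(sep = 2, sd = 1, seed = 2)
  fit <- fuzzy_cmeans(x, centers = 3, m = 1.6, seed = 3)
  expect_lt(max(abs(rowSums(fit$membership) - 1)), 1e-9)
  expect_true(all(diff(fit$objective) <= 1e-8 * max(1, fit$objective[1])))
})

test_that("a single cluster reduces to the grand mean in closed form", {
  x <- two_blobs(seed = 4)
  fit <- fuzzy_cmeans(x, centers = 1)
  expect_equal(as.numeric(fit$centers), unname(colMeans(x)))
  expect_true(all(fit$membership == 1))
})

test_that("appending a duplicate of the data leaves the solution unchanged", {
  x <- two_blobs(seed = 5)
  f1 <- fuzzy_cmeans(x, centers = 2, seed = 1)
  f2 <- fuzzy_cmeans(rbind(x, x), centers = 2, seed = 1)
  o1 <- f1$centers[order(f1$centers[, 1]), ]
  o2 <- f2$centers[order(f2$centers[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-4)
})

test_that("a point exactly on a centre takes membership one", {
  x <- rbind(c(0, 0), c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(5, 5))
  rownames(x) <- paste0("s", 1:6)
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.25, seed = 1)
  expect_true(all(apply(fit$membership, 1, max) == 1))
})

test_that("the fit agrees with an independent alternating-optimisation
           implementation on a toy instance", {
  x <- two_blobs(sep = 4, sd = 0.5, seed = 6)
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.5, tol = 1e-10, seed = 1)
  set.seed(9)
  ref <- e1071::cmeans(x, centers = 2, m = 1.5, iter.max = 500)
  ours <- fit$centers[order(fit$centers[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-4)
  expect_equal(
    sort(apply(fit$membership, 1, max)),
    sort(apply(ref$membership, 1, max)),
    tolerance = 1e-3
  )
})

test_that("as m approaches 1 the labels approach hard k-means", {
  x <- two_blobs(sep = 5, sd = 0.6, seed = 7)
  fit <- fuzzy_cmeans(x, centers = 2, m = 1.01, seed = 1)
  lab <- assign_clusters(fit)
  set.seed(1)
  km <- kmeans(x, centers = 2, nstart = 10)
  expect_equal(match_accuracy(lab$cluster, as.character(km$cluster)), 1)
})

test_that("hard assignment breaks exact ties towards the lowest cluster", {
  model <- structure(
    list(membership = matrix(c(0.5, 0.7, 0.5, 0.3), 2, 2,
      dimnames = list(c("a", "b"), NULL)
    )),
    class = "optophos_fcm"
  )
  lab <- assign_clusters(model)
  expect_equal(lab$cluster, c(1L, 1L))
  lab_thr <- assign_clusters(model, threshold = 0.6)
  expect_true(is.na(lab_thr$cluster[1]))
  expect_equal(lab_thr$cluster[2], 1L)
})

test_that("normalisation shifts to the first timepoint then standardises", {
  prof <- tibble::tibble(site_id = c("a", "b", "c"),
    t0 = c(5, 1, 2), t10 = c(6, 2, 2), t20 = c(7, 3, 2)
  )
  feats <- normalize_profiles(prof)
  shifted <- c(0, 1, 2)
  z <- (shifted - mean(shifted)) / sqrt(mean((shifted - mean(shifted))^2))
  expect_equal(as.numeric(feats[feats$site_id == "a", -1]), z)
  # proportional rows normalise identically
  expect_equal(
    as.numeric(feats[feats$site_id == "b", -1]),
    as.numeric(feats[feats$site_id == "a", -1])
  )
  expect_equal(attr(feats, "dropped"), "c")
  expect_error(
    normalize_profiles(prof[3, ]),
    class = "optophos_validation_error"
  )
})

test_that("validation errors cover bad feature matrices and cluster counts", {
  x <- two_blobs(seed = 8)
  expect_error(fuzzy_cmeans(x, centers = 1000), class = "optophos_validation_error")
  expect_error(fuzzy_cmeans(x, centers = 2, m = 1), class = "optophos_validation_error")
  x[1, 1] <- NA
  expect_error(fuzzy_cmeans(x, centers = 2), class = "optophos_validation_error")
})

test_that("the activation filter uses all-of fold semantics", {
  design <- make_design(replicates = 1)
  conds <- canonical_conditions(design)
  base <- setNames(rep(0, length(conds)), conds)
  always <- partial <- base
  always[paste0("Pe025_", c(10, 20, 30))] <- log2(1.6)
  partial[paste0("Pe025_", c(10, 20))] <- log2(1.6)
  partial["Pe025_30"] <- log2(1.4)
  qm <- tibble::tibble(site_id = c("always", "partial"))
  m <- rbind(always, partial)
  cm <- dplyr::bind_cols(qm, tibble::as_tibble(m))
  expect_equal(akt_activated_sites(cm), "always")
  expect_error(akt_activated_sites(cm, group = "Xx999"), class = "optophos_validation_error")
})

test_that("the simulated reference site always passes the activation filter", {
  for (s in 1:3) {
    sim <- simulate_phospho_experiment(quick_sim_config(), seed = s)
    cm <- condition_means(sim$quant, sim$design)
    expect_true("AKT1_T308" %in% akt_activated_sites(cm))
  }
})

test_that("tidy and glance expose memberships and fit statistics", {
  x <- two_blobs(seed = 9)
  fit <- fuzzy_cmeans(x, centers = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(x) * 2)
  expect_equal(sum(td$membership), nrow(x), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 2)
  expect_true(gl$converged)
})
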