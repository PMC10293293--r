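# shared helpers: small simulated studies, label matching, oracles

# a reduced study for fast tests (same structure, fewer sites)
quick_sim_config <- function(missing_rate = 0.03, sigma = NULL, growth_factor = TRUE) {
  cls <- substrate_classes()
  cls$n_sites <- c(25L, 20L, 20L, 6L, 10L, 60L)
  noise <- list(
    sigma_log2 = sigma %||% sim_config()$noise$sigma_log2,
    missing_rate = missing_rate
  )
  sim_config(
    classes = cls, noise = noise,
    design = list(times = c(10, 20, 30), replicates = 2, growth_factor = growth_factor)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full factorial light + dark design without running the generator
make_design <- function(replicates = 2, growth_factor = FALSE) {
  light <- expand.grid(
    intensity = light_intensities(), pattern = light_patterns(),
    time_min = c(10, 20, 30), replicate = seq_len(replicates),
    stringsAsFactors = FALSE
  )
  light$stimulus <- "light"
  dark <- data.frame(
    intensity = "none", pattern = "none", time_min = 0,
    replicate = seq_len(replicates), stimulus = "dark"
  )
  d <- dplyr::bind_rows(dark, light)
  if (growth_factor) {
    gf <- expand.grid(
      time_min = c(10, 20, 30), replicate = seq_len(replicates),
      stringsAsFactors = FALSE
    )
    gf$intensity <- "none"
    gf$pattern <- "none"
    gf$stimulus <- "growth_factor"
    d <- dplyr::bind_rows(d, gf)
  }
  d <- tibble::as_tibble(d)
  d$sample_id <- paste0(condition_id(d), "_r", d$replicate)
  d[, c("sample_id", "intensity", "pattern", "time_min", "replicate", "stimulus")]
}

# all permutations of 1..n (tiny n)
perms <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perms(n - 1L), function(p) c(i, ifelse(p >= i, p + 1L, p)))
  }))
}

# best label-matching accuracy of integer cluster labels against true classes
match_accuracy <- function(cluster, truth, classes = sort(unique(truth))) {
  stopifnot(length(cluster) == length(truth))
  max(vapply(perms(length(classes)), function(pm) {
    mean(classes[pm][cluster] == truth)
  }, numeric(1)))
}

# brute-force one-sided hypergeometric tail for a 2x2 enrichment table
hyper_tail_oracle <- function(a, b, c, d) {
  n_draw <- a + b
  k_total <- a + c
  n_total <- a + b + c + d
  hi <- min(n_draw, k_total)
  if (a > hi) {
    return(0)
  }
  sum(vapply(a:hi, function(j) {
    stats::dhyper(j, k_total, n_total - k_total, n_draw)
  }, numeric(1)))
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
wilcox_perm_oracle <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  r <- rank(all_v)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(n, length(x))
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-12)
}
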