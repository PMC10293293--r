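# Matched paired t-tests across the three intensity groups. Under the
# factorial design the nine (pattern, time) cells are exactly matched between
# intensity groups, so intensity contrasts are paired over cells of the
# condition-level (replicate-averaged) matrix.

#' Paired t-tests between intensity groups
#'
#' For each comparison (`010vs005`, `025vs005`, `025vs010`) computes, per
#' site, the paired t statistic over the nine matched (pattern, time) cells:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`. Cells missing in
#' either group exclude that pair from the comparison; a comparison with
#' fewer than 2 complete pairs is reported unscored. Degenerate difference
#' vectors with zero spread are guarded with a small epsilon on the standard
#' deviation (a constant non-zero shift then yields p ~ 0; an all-zero
#' difference yields t = 0, p = 1).
#'
#' @param cond_means Condition-level matrix from [condition_means()].
#' @param sd_epsilon Guard added to a zero standard deviation.
#' @return Tibble with `site_id`, `comparison`, `n_pairs`, `t`, `df`, `p`,
#'   `mean_log2fc`, `fold_change`.
#' @export
paired_intensity_tests <- function(cond_means, sd_epsilon = 1e-8) {
  cells <- intensity_cells(cond_means)
  comparisons <- list(
    "010vs005" = c("010", "005"),
    "025vs005" = c("025", "005"),
    "025vs010" = c("025", "010")
  )
  out <- purrr::imap(comparisons, function(pair, nm) {
    hi <- as.matrix(cond_means[, cells[[pair[1]]], drop = FALSE])
    lo <- as.matrix(cond_means[, cells[[pair[2]]], drop = FALSE])
    d <- hi - lo
    n_pairs <- rowSums(!is.na(d))
    m <- rowMeans(d, na.rm = TRUE)
    s <- apply(d, 1, sd, na.rm = TRUE)
    s[!is.na(s) & s < sd_epsilon] <- sd_epsilon
    tt <- m / (s / sqrt(n_pairs))
    df <- n_pairs - 1
    pp <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    ok <- n_pairs >= 2
    tibble(
      site_id = cond_means$site_id, comparison = nm,
      n_pairs = n_pairs,
      t = ifelse(ok, tt, NA_real_), df = ifelse(ok, df, NA_real_),
      p = ifelse(ok, pp, NA_real_),
      mean_log2fc = ifelse(ok, m, NA_real_),
      fold_change = ifelse(ok, 2^m, NA_real_)
    )
  })
  bind_rows(out)
}

# matched (pattern, time) condition columns per intensity group
intensity_cells <- function(cond_means) {
  light_cols <- grep("^(Su|Pe|Pu)0", names(cond_means), value = TRUE)
  cells <- list()
  for (int in light_intensities()) {
    cells[[int]] <- sort(grep(int, light_cols, value = TRUE, fixed = TRUE))
  }
  ns <- lengths(cells)
  if (length(unique(ns)) != 1 || any(ns == 0)) {
    abort("condition matrix lacks matched intensity cells",
      class = "optophos_validation_error"
    )
  }
  # verify the (pattern, time) cells line up across groups
  strip <- function(x) sub("0(05|10|25)", "", x)
  keys <- lapply(cells, strip)
  if (!all(vapply(keys, identical, logical(1), keys[[1]]))) {
    abort(
      paste0(
        "intensity groups are not matched; cells: ",
        paste(unlist(keys), collapse = ", ")
      ),
      class = "optophos_validation_error"
    )
  }
  cells
}

#' Gate intensity-regulated sites
#'
#' Applies the selection gate to paired-test results: unadjusted p below
#' `alpha` in the `010vs005` and `025vs005` comparisons (`gate = "both"`) or
#' additionally in `025vs010` (`gate = "all-three"`), together with a
#' two-sided fold gate `|log2 FC| > log2(fold)` in the `010vs005` and
#' `025vs005` comparisons (two-sided so that dephosphorylated sites pass).
#'
#' @param tests Output of [paired_intensity_tests()].
#' @param alpha P-value threshold.
#' @param fold Linear fold-change threshold.
#' @param gate Which comparisons carry the p-value gate.
#' @return Character vector of passing site ids.
#' @export
intensity_regulated_sites <- function(tests, alpha = 0.01, fold = 1.5,
                                      gate = c("both", "all-three")) {
  gate <- match.arg(gate)
  gated_p <- c("010vs005", "025vs005")
  if (gate == "all-three") gated_p <- c(gated_p, "025vs010")
  wide <- tests %>%
    select("site_id", "comparison", "p", "mean_log2fc") %>%
    tidyr::pivot_wider(
      names_from = "comparison", values_from = c("p", "mean_log2fc")
    )
  pass <- rep(TRUE, nrow(wide))
  for (cmp in gated_p) {
    pc <- wide[[paste0("p_", cmp)]]
    pass <- pass & !is.na(pc) & pc < alpha
  }
  for (cmp in c("010vs005", "025vs005")) {
    fc <- wide[[paste0("mean_log2fc_", cmp)]]
    pass <- pass & !is.na(fc) & abs(fc) > log2(fold)
  }
  wide$site_id[pass]
}

#' Hierarchical clustering of intensity-regulated profiles
#'
#' Row-centres each selected site's condition-level profile over all light
#' conditions, clusters with correlation distance (`1 - Pearson`) and average
#' linkage, and cuts the tree into `k` groups. `hclust` resolves equal-height
#' merges by lowest merge index, so the result is deterministic for a given
#' input order.
#'
#' @param cond_means Condition-level matrix.
#' @param sites Site ids to cluster (e.g. from
#'   [intensity_regulated_sites()]); sites with missing light cells are
#'   dropped and reported via the `dropped` attribute.
#' @param k Number of clusters.
#' @return Object of class `optophos_hclust`: tibble (`site_id`, `cluster`)
#'   with the `hclust` tree in attribute `tree` and the centred profile
#'   matrix in attribute `profiles`.
#' @export
cluster_intensity_profiles <- function(cond_means, sites, k = 5) {
  light_cols <- grep("^(Su|Pe|Pu)0", names(cond_means), value = TRUE)
  m <- as.matrix(cond_means[match(sites, cond_means$site_id), light_cols, drop = FALSE])
  rownames(m) <- sites
  ok <- !apply(m, 1, anyNA)
  dropped <- sites[!ok]
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < k) {
    abort(sprintf(
      "only %d usable sites for k = %d clusters; choose a smaller k",
      nrow(m), k
    ), class = "optophos_validation_error")
  }
  centred <- m - rowMeans(m)
  cc <- suppressWarnings(cor(t(centred)))
  cc[!is.finite(cc)] <- 0 # zero-variance rows carry no shape information
  tree <- hclust(as.dist(1 - cc), method = "average")
  labels <- cutree(tree, k = k)
  out <- tibble(site_id = rownames(m), cluster = unname(labels))
  structure(out,
    class = c("optophos_hclust", class(out)),
    tree = tree, profiles = centred, dropped = dropped
  )
}
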