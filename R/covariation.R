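# Covariation-based substrate discovery: per-site Pearson correlation to the
# reference activation site across condition-level profiles, thresholding
# into the high-covariation ("OptoCore"-style) set, benchmark-list rank
# comparisons and mutual-support arithmetic between candidate lists.

#' Correlate every site to the reference activation site
#'
#' Computes, per site, the Pearson correlation of its condition-level profile
#' with the reference site's profile over pairwise-complete conditions
#' (missing cells drop that condition for that site only). Sites with fewer
#' than `min_n` complete pairs are reported unscored.
#'
#' @param cond_means Condition-level matrix from [condition_means()]
#'   (all conditions, replicates averaged).
#' @param reference_site Site id of the reference activation site.
#' @param threshold Correlation threshold for the high-covariation flag.
#' @param min_n Minimum number of complete condition pairs.
#' @return Tibble `site_id`, `r`, `n_used`, `scored`, `covaries`
#'   (`r > threshold`).
#' @export
correlate_to_reference <- function(cond_means, reference_site,
                                   threshold = 0.85, min_n = 10) {
  if (!reference_site %in% cond_means$site_id) {
    abort(paste0("reference site not found: ", reference_site),
      class = "optophos_validation_error"
    )
  }
  m <- as.matrix(cond_means[, -1, drop = FALSE])
  ref <- m[match(reference_site, cond_means$site_id), ]
  n_used <- rowSums(!is.na(m) & !is.na(ref)[col(m)])
  r <- suppressWarnings(
    apply(m, 1, function(x) cor(x, ref, use = "pairwise.complete.obs"))
  )
  scored <- n_used >= min_n & !is.na(r)
  tibble(
    site_id = cond_means$site_id,
    r = ifelse(scored, r, NA_real_),
    n_used = n_used,
    scored = scored,
    covaries = scored & !is.na(r) & r > threshold
  )
}

#' Benchmark covariation against candidate substrate lists
#'
#' For each benchmark list (a logical flag column of the annotation table),
#' compares the correlation values of in-list versus out-of-list sites with
#' a two-sided Wilcoxon rank-sum test (exact for small samples without ties,
#' normal approximation with continuity correction otherwise). Unscored
#' sites are excluded; empty lists are skipped with a warning.
#'
#' @param covar Output of [correlate_to_reference()].
#' @param annotations Site-annotation tibble with logical list-flag columns.
#' @param lists Names of flag columns to benchmark.
#' @return Tibble `list`, `n_in`, `n_out`, `statistic` (rank-sum W), `p`,
#'   `median_in`, `median_out`.
#' @export
benchmark_lists <- function(covar, annotations,
                            lists = c("in_pspdb", "in_motif", "in_inhibitors", "in_kinome")) {
  x <- covar %>%
    filter(.data$scored) %>%
    left_join(annotations, by = "site_id")
  out <- list()
  for (l in lists) {
    if (!l %in% names(x)) {
      abort(paste0("annotation flag not found: ", l),
        class = "optophos_validation_error"
      )
    }
    flag <- x[[l]]
    r_in <- x$r[flag %in% TRUE]
    r_out <- x$r[flag %in% FALSE]
    if (length(r_in) == 0 || length(r_out) == 0) {
      warn(paste0("benchmark list ", l, " is empty; skipped"))
      next
    }
    wt <- wilcox.test(r_in, r_out, alternative = "two.sided", correct = TRUE)
    out[[l]] <- tibble(
      list = l, n_in = length(r_in), n_out = length(r_out),
      statistic = unname(wt$statistic), p = wt$p.value,
      median_in = stats::median(r_in), median_out = stats::median(r_out)
    )
  }
  bind_rows(out)
}

#' Waterfall table of correlation values with list flags
#'
#' @param covar Output of [correlate_to_reference()].
#' @param annotations Site-annotation tibble.
#' @param lists Flag columns to carry along.
#' @return Scored sites sorted by decreasing `r` with `rank` and flags.
#' @export
waterfall_table <- function(covar, annotations,
                            lists = c("in_pspdb", "in_motif", "in_inhibitors", "in_kinome")) {
  covar %>%
    filter(.data$scored) %>%
    left_join(annotations[, c("site_id", intersect(lists, names(annotations)))],
      by = "site_id"
    ) %>%
    arrange(dplyr::desc(.data$r)) %>%
    mutate(rank = row_number())
}

#' Mutual support between candidate substrate lists
#'
#' For every list, the percentage of its members found in at least one and
#' at least two of the other lists, plus the full pairwise overlap counts.
#'
#' @param lists Named list (>= 2 entries) of character vectors of site ids.
#' @return List with `support` (tibble `list`, `n`, `pct_ge1`, `pct_ge2`)
#'   and `pairwise` (tibble `list1`, `list2`, `overlap`).
#' @export
mutual_support <- function(lists) {
  if (length(lists) < 2) {
    abort("need at least two lists", class = "optophos_validation_error")
  }
  nms <- names(lists)
  support <- purrr::map(nms, function(nm) {
    members <- unique(lists[[nm]])
    others <- lists[nms != nm]
    hits <- vapply(
      members,
      function(s) sum(vapply(others, function(o) s %in% o, logical(1))),
      integer(1)
    )
    tibble(
      list = nm, n = length(members),
      pct_ge1 = 100 * mean(hits >= 1),
      pct_ge2 = 100 * mean(hits >= 2)
    )
  }) %>% bind_rows()
  prs <- utils::combn(nms, 2)
  pairwise <- purrr::map(seq_len(ncol(prs)), function(k) {
    tibble(
      list1 = prs[1, k], list2 = prs[2, k],
      overlap = length(intersect(lists[[prs[1, k]]], lists[[prs[2, k]]]))
    )
  }) %>% bind_rows()
  list(support = support, pairwise = pairwise)
}
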