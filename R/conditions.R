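# Condition naming shared by the generator, the IO layer and all stages.
# A condition is one biological treatment cell (all replicates pooled):
#   dark control         -> "dark"
#   light regime         -> "<pattern><intensity>_<time>", e.g. "Pe025_10"
#   growth-factor series -> "GF_<time>"
# The group of a condition drops the time suffix ("Pe025", "GF", "dark").

#' Condition identifiers for a study design
#'
#' @param design A study-design tibble with columns `sample_id`, `intensity`,
#'   `pattern`, `time_min`, `replicate`, `stimulus`.
#' @return Character vector of condition ids, one per row of `design`.
#' @export
condition_id <- function(design) {
  dplyr::case_when(
    design$stimulus == "dark" ~ "dark",
    design$stimulus == "growth_factor" ~ paste0("GF_", design$time_min),
    TRUE ~ paste0(design$pattern, design$intensity, "_", design$time_min)
  )
}

#' @rdname condition_id
#' @export
condition_group <- function(design) {
  dplyr::case_when(
    design$stimulus == "dark" ~ "dark",
    design$stimulus == "growth_factor" ~ "GF",
    TRUE ~ paste0(design$pattern, design$intensity)
  )
}

#' Canonical condition order
#'
#' Dark control first, then light conditions ordered by intensity, pattern and
#' time (lexicographic), then the growth-factor series by time.
#'
#' @inheritParams condition_id
#' @return Character vector of unique condition ids in canonical order.
#' @export
canonical_conditions <- function(design) {
  d <- design %>%
    mutate(condition = condition_id(design)) %>%
    distinct(.data$condition, .data$stimulus, .data$intensity,
      .data$pattern, .data$time_min
    ) %>%
    mutate(block = dplyr::case_when(
      .data$stimulus == "dark" ~ 0L,
      .data$stimulus == "light" ~ 1L,
      TRUE ~ 2L
    )) %>%
    arrange(.data$block, .data$intensity, .data$pattern, .data$time_min)
  d$condition
}

# resolve a group name like "Pe025", "Su010", "GF"/"growth_factor", "dark"
normalize_group <- function(group) {
  if (identical(group, "growth_factor")) "GF" else group
}
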