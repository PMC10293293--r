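# Covariate-adjusted trait attribution. For every site, an ordinary
# least-squares model with main effects of the three categorical stimulation
# traits (intensity, pattern, duration) is fitted on replicate-level light
# samples; the F statistic for one "major" trait is the nested comparison of
# the full model against the model without that trait, the other two traits
# staying in as covariates.

#' Per-site trait attribution by covariate-adjusted F-tests
#'
#' Fits, per site, `log2 intensity ~ intensity + pattern + duration`
#' (main effects only) on replicate-level observations of the light samples
#' (the dark control is excluded; its traits are undefined). For each
#' requested major trait the F-test compares the full model with the model
#' dropping the major trait. P-values are two-sided and unadjusted.
#'
#' Sites with missing observations in more than `max_missing_conditions` of
#' the light conditions are skipped (reported with `skipped = TRUE`); other
#' sites with missing values are fitted on their available observations.
#'
#' @param quant Wide quantification tibble.
#' @param design Study-design tibble.
#' @param majors Traits to test; subset of
#'   `c("intensity", "pattern", "duration")`.
#' @param alpha Significance level for the `significant` flag (unadjusted).
#' @param max_missing_conditions Fraction of conditions that may be affected
#'   by missingness before a site is skipped.
#' @return Tibble with `site_id`, `trait`, `F`, `df1`, `df2`, `p`,
#'   `ss_major` (the extra sum of squares explained by the major trait),
#'   `rss` (full-model residual sum of squares), `significant`, `skipped`.
#' @export
anova_traits <- function(quant, design,
                         majors = c("intensity", "pattern", "duration"),
                         alpha = 0.01,
                         max_missing_conditions = 0.2) {
  majors <- match.arg(majors, several.ok = TRUE)
  keep <- design$stimulus == "light"
  design <- design[keep, ]
  samples <- design$sample_id
  missing_samples <- setdiff(samples, names(quant))
  if (length(missing_samples)) {
    abort(paste0("quant lacks samples: ", paste(missing_samples, collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  fac <- tibble(
    intensity = factor(design$intensity),
    pattern = factor(design$pattern),
    duration = factor(design$time_min)
  )
  # single-level traits carry no information and are dropped from the model;
  # this makes the no-covariate limit coincide with classical one-way ANOVA
  modelled <- names(fac)[vapply(fac, nlevels, integer(1)) >= 2]
  bad_major <- setdiff(majors, modelled)
  if (length(bad_major)) {
    abort(
      paste0(
        "design is rank-deficient: major trait(s) with a single level: ",
        paste(bad_major, collapse = ", ")
      ),
      class = "optophos_validation_error"
    )
  }
  x_full <- stats::model.matrix(
    stats::reformulate(modelled), fac[modelled]
  )
  term_cols <- attr(x_full, "assign")
  term_names <- c("(intercept)", modelled)

  y <- as.matrix(quant[, samples, drop = FALSE])
  n_obs <- ncol(y)
  complete <- !apply(y, 1, anyNA)

  conds <- condition_id(design[, , drop = FALSE])
  n_cond <- length(unique(conds))

  res <- list()
  for (major in majors) {
    drop_idx <- which(term_names[term_cols + 1L] == major)
    x_red <- x_full[, -drop_idx, drop = FALSE]
    df1 <- length(drop_idx)

    f <- rep(NA_real_, nrow(y))
    p <- rep(NA_real_, nrow(y))
    df2 <- rep(NA_real_, nrow(y))
    rss <- rep(NA_real_, nrow(y))
    ss_major <- rep(NA_real_, nrow(y))
    skipped <- rep(FALSE, nrow(y))

    if (any(complete)) {
      rss_f <- proj_rss(y[complete, , drop = FALSE], x_full)
      rss_r <- proj_rss(y[complete, , drop = FALSE], x_red)
      d2 <- n_obs - ncol(x_full)
      fs <- ((rss_r - rss_f) / df1) / (rss_f / d2)
      ps <- pf(fs, df1, d2, lower.tail = FALSE)
      # numerically constant sites (no residual AND no attributable signal)
      degen <- rss_f < 1e-12 * n_obs & (rss_r - rss_f) < 1e-12 * n_obs
      fs[degen] <- 0
      ps[degen] <- 1
      f[complete] <- fs
      p[complete] <- ps
      df2[complete] <- d2
      rss[complete] <- rss_f
      ss_major[complete] <- rss_r - rss_f
    }

    for (i in which(!complete)) {
      ok <- !is.na(y[i, ])
      affected <- length(unique(conds[!ok]))
      if (affected > max_missing_conditions * n_cond) {
        skipped[i] <- TRUE
        next
      }
      xf <- x_full[ok, , drop = FALSE]
      xr <- x_red[ok, , drop = FALSE]
      if (qr(xf)$rank < ncol(xf)) {
        skipped[i] <- TRUE
        next
      }
      yy <- y[i, ok]
      rf <- sum(stats::lm.fit(xf, yy)$residuals^2)
      rr <- sum(stats::lm.fit(xr, yy)$residuals^2)
      d2 <- sum(ok) - ncol(xf)
      if (rf < 1e-12 * sum(ok) && (rr - rf) < 1e-12 * sum(ok)) {
        f[i] <- 0
        p[i] <- 1
      } else {
        f[i] <- ((rr - rf) / df1) / (rf / d2)
        p[i] <- pf(f[i], df1, d2, lower.tail = FALSE)
      }
      df2[i] <- d2
      rss[i] <- rf
      ss_major[i] <- rr - rf
    }

    res[[major]] <- tibble(
      site_id = quant$site_id, trait = major,
      F = f, df1 = df1, df2 = df2, p = p,
      ss_major = ss_major, rss = rss,
      significant = !is.na(p) & p < alpha,
      skipped = skipped
    )
  }
  bind_rows(res)
}

# residual sums of squares of Y rows against a fixed design matrix,
# via the annihilator M = I - X (X'X)^-1 X'
proj_rss <- function(y_rows, x) {
  qx <- qr.Q(qr(x))
  fitted_part <- (y_rows %*% qx) %*% t(qx)
  resid <- y_rows - fitted_part
  rowSums(resid^2)
}

#' Trait-significant site counts
#'
#' @param trait_result Output of [anova_traits()].
#' @return Tibble `trait`, `n_significant`, `n_tested`, `n_skipped`.
#' @export
trait_counts <- function(trait_result) {
  trait_result %>%
    group_by(.data$trait) %>%
    summarise(
      n_significant = sum(.data$significant),
      n_tested = sum(!.data$skipped),
      n_skipped = sum(.data$skipped),
      .groups = "drop"
    )
}
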