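# Two-series time-course differential analysis: per site, a polynomial
# time-course model with a series indicator and interactions is fitted on
# replicate-level observations; an F-test of all series-difference terms
# (nested model comparison) is BH-adjusted across sites, gated by model R^2,
# and the significant fitted difference curves are partitioned by k-means.

#' Differential testing between two stimulation time series
#'
#' Fits, per site, `y = b0 + b1 t + ... + z (g0 + g1 t + ...)` with `z` the
#' series indicator and polynomial degree `degree`, on replicate-level
#' observations of the two series. The dark control supplies the 0-min
#' observations and is carried by the reference series (`z = 0`); the second
#' series' 0-min level is identified through its polynomial, so no
#' observation enters the fit twice and the null F statistic keeps its
#' nominal distribution. The F statistic tests all `g` terms
#' jointly (full vs reduced OLS fit); p-values are Benjamini-Hochberg
#' adjusted across all tested sites, and sites are flagged significant when
#' `q < alpha` and the full-model `R^2` reaches `rsq`.
#'
#' Series names are condition groups: a light group such as `"Su010"` or the
#' growth-factor series (`"GF"` / `"growth_factor"`). Sites with missing
#' observations are fitted on their available observations; sites whose
#' remaining observations no longer cover every (series, time) cell are
#' reported unscored.
#'
#' @param quant Wide quantification tibble.
#' @param design Study-design tibble.
#' @param series_a,series_b Condition group names.
#' @param degree Polynomial degree in time (default 2, quadratic).
#' @param alpha FDR level for the significance flag.
#' @param rsq Minimum full-model R-squared.
#' @return Object of class `optophos_two_series`: tibble with `site_id`,
#'   `F`, `df1`, `df2`, `p`, `q`, `r_squared`, `significant`, `scored` and
#'   the series-difference coefficients `gamma0..gamma<degree>`; attributes
#'   `times`, `degree`, `series`.
#' @export
fit_two_series <- function(quant, design, series_a = "Su010",
                           series_b = "growth_factor", degree = 2,
                           alpha = 0.05, rsq = 0.8) {
  series_a <- normalize_group(series_a)
  series_b <- normalize_group(series_b)
  groups <- condition_group(design)
  obs <- list()
  for (s in c(series_a, series_b)) {
    z <- as.integer(s == series_b)
    rows <- design[groups == s, ]
    if (nrow(rows) == 0) {
      abort(paste0("no samples for series ", s), class = "optophos_validation_error")
    }
    obs[[s]] <- tibble(sample_id = rows$sample_id, time = rows$time_min, z = z)
  }
  # the dark control is the 0-min observation, carried by the reference
  # series (z = 0); series B's 0-min level is identified through its
  # polynomial, so no observation is used twice
  if (!0 %in% obs[[series_a]]$time) {
    dark <- design[design$stimulus == "dark", ]
    if (nrow(dark) == 0) {
      abort("no dark control available as the 0-min timepoint",
        class = "optophos_validation_error"
      )
    }
    obs[["t0"]] <- tibble(sample_id = dark$sample_id, time = 0, z = 0L)
  }
  obs <- bind_rows(obs)
  times <- sort(unique(obs$time))
  t_a <- sort(unique(obs$time[obs$z == 0]))
  t_b <- sort(unique(obs$time[obs$z == 1]))
  if (!identical(setdiff(t_a, 0), setdiff(t_b, 0)) ||
      length(setdiff(t_b, 0)) <= degree) {
    abort("series do not share a common set of stimulation timepoints",
      class = "optophos_validation_error"
    )
  }

  tp <- outer(obs$time, seq_len(max(degree, 0)), `^`)
  x_red <- cbind(1, tp)
  x_full <- cbind(x_red, obs$z, obs$z * tp)
  gamma_cols <- seq(ncol(x_red) + 1L, ncol(x_full))
  df1 <- length(gamma_cols)

  y <- as.matrix(quant[, obs$sample_id, drop = FALSE])
  n <- ncol(y)
  complete <- !apply(y, 1, anyNA)

  f <- p <- r2 <- rep(NA_real_, nrow(y))
  df2 <- rep(NA_real_, nrow(y))
  gamma <- matrix(NA_real_, nrow(y), df1)
  scored <- rep(FALSE, nrow(y))

  fit_block <- function(idx, xf, xr, yy) {
    qf <- qr(xf)
    cf <- t(qr.coef(qf, t(yy)))
    rf <- rowSums((yy - cf %*% t(xf))^2)
    rr_coef <- qr.coef(qr(xr), t(yy))
    rr <- rowSums((yy - t(rr_coef) %*% t(xr))^2)
    tss <- rowSums((yy - rowMeans(yy))^2)
    d2 <- ncol(yy) - ncol(xf)
    fs <- ((rr - rf) / df1) / (rf / d2)
    degen <- rf < 1e-12 * ncol(yy)
    ps <- pf(fs, df1, d2, lower.tail = FALSE)
    fs[degen & (rr - rf) < 1e-12] <- 0
    ps[degen & (rr - rf) < 1e-12] <- 1
    r2v <- ifelse(tss > 0, 1 - rf / tss, 0)
    f[idx] <<- fs
    p[idx] <<- ps
    r2[idx] <<- r2v
    df2[idx] <<- d2
    gamma[idx, ] <<- cf[, gamma_cols, drop = FALSE]
    scored[idx] <<- TRUE
  }

  if (any(complete)) {
    fit_block(which(complete), x_full, x_red, y[complete, , drop = FALSE])
  }
  n_cells <- length(unique(paste(obs$z, obs$time)))
  for (i in which(!complete)) {
    ok <- !is.na(y[i, ])
    cells <- unique(paste(obs$z[ok], obs$time[ok]))
    if (length(cells) < n_cells || qr(x_full[ok, ])$rank < ncol(x_full)) {
      next
    }
    fit_block(i, x_full[ok, , drop = FALSE], x_red[ok, , drop = FALSE],
      y[i, ok, drop = FALSE]
    )
  }

  q <- rep(NA_real_, nrow(y))
  q[scored] <- p.adjust(p[scored], method = "BH")
  res <- tibble(
    site_id = quant$site_id,
    F = f, df1 = df1, df2 = df2, p = p, q = q, r_squared = r2,
    significant = scored & !is.na(q) & q < alpha & r2 >= rsq,
    scored = scored
  )
  colnames(gamma) <- paste0("gamma", seq_len(df1) - 1L)
  res <- bind_cols(res, as_tibble(gamma))
  structure(res,
    class = c("optophos_two_series", class(res)),
    times = times, degree = degree, series = c(series_a, series_b)
  )
}

#' Partition significant series-difference profiles
#'
#' Evaluates each significant site's fitted difference curve (series B minus
#' series A polynomial) at the shared timepoints and partitions the curves
#' with seeded k-means (10 restarts).
#'
#' @param fits An `optophos_two_series` result.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return Tibble `site_id`, `cluster`; attribute `centers` holds the
#'   cluster-mean difference curves.
#' @export
partition_profiles <- function(fits, k = 4, seed = 1) {
  sig <- fits[fits$significant, , drop = FALSE]
  if (nrow(sig) < k) {
    abort(sprintf("only %d significant sites for k = %d clusters", nrow(sig), k),
      class = "optophos_validation_error"
    )
  }
  times <- attr(fits, "times")
  degree <- attr(fits, "degree")
  gm <- as.matrix(sig[, paste0("gamma", 0:degree), drop = FALSE])
  basis <- outer(times, 0:degree, `^`)
  curves <- gm %*% t(basis)
  colnames(curves) <- paste0("t", times)
  n_distinct <- nrow(unique(curves))
  if (n_distinct < k) {
    abort(sprintf(
      "only %d distinct difference curves for k = %d clusters", n_distinct, k
    ), class = "optophos_validation_error")
  }
  if (nrow(curves) == k) {
    # one site per cluster: the partition is forced
    out <- tibble(site_id = sig$site_id, cluster = seq_len(k))
    attr(out, "centers") <- curves
    return(out)
  }
  set.seed(as.integer(seed))
  km <- kmeans(curves, centers = k, nstart = 10)
  out <- tibble(site_id = sig$site_id, cluster = km$cluster)
  attr(out, "centers") <- km$centers
  out
}

#' Benjamini-Hochberg adjustment (step-up)
#'
#' Thin wrapper over [stats::p.adjust()] exposed for auditability of the
#' multiple-testing step.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
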