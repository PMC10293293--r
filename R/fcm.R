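# Fuzzy c-means temporal clustering (Bezdek alternating optimisation) with
# the first-timepoint normalisation used for temporal phosphosite profiles.

#' Select activation-responsive sites by repeated fold gating
#'
#' Returns the sites whose linear fold change versus the dark control exceeds
#' `fold` at every timepoint of the named condition group (all-of semantics:
#' a site must clear the gate at 10, 20 and 30 min of, e.g., the periodic
#' high-intensity group). Sites missing at any gated timepoint are excluded.
#'
#' @param cond_means Condition-level matrix from [condition_means()].
#' @param group Condition group carrying the gate (default `"Pe025"`).
#' @param fold Linear fold threshold.
#' @param times Gated timepoints.
#' @param reference Reference condition column (default `"dark"`).
#' @return Character vector of site ids.
#' @export
akt_activated_sites <- function(cond_means, group = "Pe025", fold = 1.5,
                                times = c(10, 20, 30), reference = "dark") {
  group <- normalize_group(group)
  cols <- paste0(group, "_", times)
  missing_cols <- setdiff(c(cols, reference), names(cond_means))
  if (length(missing_cols)) {
    abort(paste0("unknown condition group/columns: ", paste(missing_cols, collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  lfc <- as.matrix(cond_means[, cols, drop = FALSE]) - cond_means[[reference]]
  pass <- rowSums(lfc > log2(fold)) == length(cols) & !apply(lfc, 1, anyNA)
  pass[is.na(pass)] <- FALSE
  cond_means$site_id[pass]
}

#' Normalise temporal profiles for clustering
#'
#' Mode `"t1"` subtracts the first column (the first timepoint) from each row
#' and then standardises each row to zero mean and unit standard deviation
#' (population convention with denominator `n`), so clustering compares
#' profile shapes, not amplitudes. Rows with missing entries and rows with
#' zero variance after the shift are dropped and reported via the `dropped`
#' attribute. Mode `"none"` only drops incomplete rows.
#'
#' @param profiles Tibble: `site_id` plus ordered numeric profile columns.
#' @param mode `"t1"` or `"none"`.
#' @return Tibble of normalised profiles; attribute `dropped` holds the ids
#'   of removed rows.
#' @export
normalize_profiles <- function(profiles, mode = c("t1", "none")) {
  mode <- match.arg(mode)
  m <- as.matrix(profiles[, -1, drop = FALSE])
  rownames(m) <- profiles$site_id
  ok <- !apply(m, 1, anyNA)
  dropped_na <- profiles$site_id[!ok]
  m <- m[ok, , drop = FALSE]
  dropped_const <- character(0)
  if (mode == "t1") {
    m <- m - m[, 1]
    mu <- rowMeans(m)
    sdev <- sqrt(rowMeans((m - mu)^2))
    const <- sdev < 1e-12
    dropped_const <- rownames(m)[const]
    m <- (m - mu)[!const, , drop = FALSE] / sdev[!const]
  }
  if (nrow(m) == 0) {
    abort("no usable profiles after normalisation (all constant or incomplete)",
      class = "optophos_validation_error"
    )
  }
  out <- bind_cols(tibble(site_id = rownames(m)), as_tibble(m))
  attr(out, "dropped") <- c(dropped_na, dropped_const)
  out
}

#' Fuzzy c-means clustering
#'
#' Bezdek alternating optimisation with Euclidean distances: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centres
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`. A point at exactly zero distance
#' from a centre takes membership 1 there. Iteration stops when
#' `max |U - U_prev| < tol` or after `max_iter` sweeps. Because the problem
#' is initialisation-sensitive, `n_init` seeded random restarts are run and
#' the fit with the lowest objective is returned.
#'
#' @param x Tibble with `site_id` plus numeric feature columns (e.g. from
#'   [normalize_profiles()]), or a numeric matrix with rownames.
#' @param centers Number of clusters `c >= 1`.
#' @param m Fuzzifier (> 1); the conventional soft-clustering default for
#'   standardised temporal profiles is 1.25.
#' @param max_iter,tol Convergence controls.
#' @param n_init Number of random restarts.
#' @param seed Integer seed for the restarts.
#' @return Object of class `optophos_fcm`: list with `centers` (c x T),
#'   `membership` (n x c, rows summing to 1), `objective` (per-iteration
#'   values of the best restart), `m`, `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(x, centers, m = 1.25, max_iter = 200, tol = 1e-6,
                         n_init = 10, seed = 1) {
  if (is.data.frame(x)) {
    mat <- as.matrix(x[, -1, drop = FALSE])
    rownames(mat) <- x[[1]]
  } else {
    mat <- as.matrix(x)
  }
  if (!all(is.finite(mat))) {
    abort("features must be finite", class = "optophos_validation_error")
  }
  n <- nrow(mat)
  if (centers < 1 || centers > n) {
    abort(sprintf("need 1 <= centers <= %d sites", n),
      class = "optophos_validation_error"
    )
  }
  if (m <= 1) abort("fuzzifier m must exceed 1", class = "optophos_validation_error")

  if (centers == 1) {
    v <- matrix(colMeans(mat), 1, ncol(mat), dimnames = list(NULL, colnames(mat)))
    u <- matrix(1, n, 1, dimnames = list(rownames(mat), NULL))
    obj <- sum(sweep(mat, 2, v[1, ])^2)
    return(structure(
      list(
        centers = v, membership = u, objective = obj, m = m,
        iterations = 0L, converged = TRUE
      ),
      class = "optophos_fcm"
    ))
  }

  best <- NULL
  set.seed(as.integer(seed))
  init_seeds <- sample.int(.Machine$integer.max, n_init)
  for (r in seq_len(n_init)) {
    set.seed(init_seeds[r])
    fit <- fcm_single(mat, centers, m, max_iter, tol)
    if (is.null(best) || utils::tail(fit$objective, 1) < utils::tail(best$objective, 1)) {
      best <- fit
    }
  }
  best$m <- m
  dimnames(best$centers) <- list(NULL, colnames(mat))
  rownames(best$membership) <- rownames(mat)
  structure(best, class = "optophos_fcm")
}

fcm_single <- function(mat, c, m, max_iter, tol) {
  n <- nrow(mat)
  u <- matrix(runif(n * c), n, c)
  u <- u / rowSums(u)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  exp_u <- 2 / (m - 1)
  for (iter in seq_len(max_iter)) {
    um <- u^m
    v <- (t(um) %*% mat) / colSums(um)
    d2 <- outer(rowSums(mat^2), rep(1, c)) -
      2 * mat %*% t(v) + outer(rep(1, n), rowSums(v^2))
    d2[d2 < 0] <- 0
    obj <- c(obj, sum(um * d2))
    zero <- d2 < 1e-300
    inv <- d2^(-exp_u / 2)
    u_new <- inv / rowSums(inv)
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      u_new[has_zero, ] <- 0
      first_zero <- max.col(zero[has_zero, , drop = FALSE], ties.method = "first")
      u_new[cbind(which(has_zero), first_zero)] <- 1
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  um <- u^m
  v <- (t(um) %*% mat) / colSums(um)
  d2 <- outer(rowSums(mat^2), rep(1, c)) -
    2 * mat %*% t(v) + outer(rep(1, n), rowSums(v^2))
  d2[d2 < 0] <- 0
  obj <- c(obj, sum(um * d2))
  list(
    centers = v, membership = u, objective = obj,
    iterations = iter, converged = converged
  )
}

#' Hard labels from a fuzzy clustering
#'
#' Argmax membership per site; exact ties resolve to the lowest cluster
#' index. Sites whose maximum membership falls below `threshold` are flagged
#' unassigned (`cluster = NA`).
#'
#' @param model An `optophos_fcm` fit.
#' @param threshold Minimum membership for assignment (0 assigns everything).
#' @return Tibble `site_id`, `cluster`, `membership`, `unassigned`.
#' @export
assign_clusters <- function(model, threshold = 0) {
  u <- model$membership
  idx <- max.col(u, ties.method = "first")
  mx <- u[cbind(seq_len(nrow(u)), idx)]
  unassigned <- mx < threshold
  tibble(
    site_id = rownames(u) %||% as.character(seq_len(nrow(u))),
    cluster = ifelse(unassigned, NA_integer_, idx),
    membership = mx,
    unassigned = unassigned
  )
}

#' @export
print.optophos_fcm <- function(x, ...) {
  cat(sprintf(
    "<optophos_fcm> %d sites, %d clusters, m = %g, objective = %.4g (%s in %d iterations)\n",
    nrow(x$membership), nrow(x$centers), x$m, utils::tail(x$objective, 1),
    if (x$converged) "converged" else "not converged", x$iterations
  ))
  invisible(x)
}

#' @rdname fuzzy_cmeans
#' @param x An `optophos_fcm` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.optophos_fcm <- function(x, ...) {
  u <- x$membership
  tibble(
    site_id = rep(rownames(u) %||% as.character(seq_len(nrow(u))), ncol(u)),
    cluster = rep(seq_len(ncol(u)), each = nrow(u)),
    membership = as.vector(u)
  )
}

#' @rdname fuzzy_cmeans
#' @export
glance.optophos_fcm <- function(x, ...) {
  tibble(
    n_sites = nrow(x$membership), n_clusters = nrow(x$centers),
    m = x$m, objective = utils::tail(x$objective, 1),
    iterations = x$iterations, converged = x$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
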