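# Downstream substrate occupancy model. Each phosphosite class couples to the
# upstream activation trajectory A(t) through a first-order phosphorylation /
# dephosphorylation balance:
#   standard classes:  dS/dt = k_s * A(t) * (1 - S) - k_d * S
#   integrator:        dP/dt = kp * A(t) * (1 - P) - kd_p * P   (intermediate)
#                      dS/dt = k_s * P(t)                       (capped at 1)
#   null:              S == 0
# The integrator accumulates through a persistently phosphorylated
# intermediate (a two-step cascade), so it keeps rising long after a short
# activation pulse. The "suppressed" class uses the standard dynamics but a
# negative abundance amplitude, so its measured signal falls as activation
# accumulates.

#' Default substrate class table
#'
#' Parameter table for the planted downstream substrate classes. `k_s` and
#' `k_d` are coupling/decay rates (1/min), `beta` the fold-scale amplitude on
#' the linear intensity scale (negative for the suppressed class),
#' `strict_motif_prob` the probability that a site of the class carries the
#' strict basophilic kinase recognition motif R-x-R-x-x-S/T, `kinase` the
#' planted upstream kinase label and `n_sites` the default number of sites
#' drawn per class.
#'
#' Class phenomenology: `direct_fast` tracks the activation signal closely and
#' decays quickly once it is removed; `direct_slow` responds and decays with
#' delayed kinetics; `persistent` stays phosphorylated long after a pulse;
#' `integrator` accumulates gradually over the whole time course;
#' `suppressed` loses signal upon activation; `null` is unresponsive.
#'
#' @return Tibble with one row per class.
#' @export
substrate_classes <- function() {
  tibble(
    class = c(
      "direct_fast", "direct_slow", "persistent",
      "integrator", "suppressed", "null"
    ),
    k_s = c(0.9, 0.4, 0.8, 0.03, 0.5, 0),
    k_d = c(0.6, 0.12, 0.02, 0, 0.05, 0),
    beta = c(20, 16, 8, 8, -0.85, 0),
    strict_motif_prob = c(0.16, 0.03, 0.03, 0.03, 0.03, 0.03),
    kinase = c("AKT1", "RPS6KA1", "MAPK1", "CSNK2A1", "CDK1", NA_character_),
    n_sites = c(100L, 70L, 70L, 10L, 30L, 220L)
  )
}

check_substrate_classes <- function(classes, d) {
  req <- c("class", "k_s", "k_d", "beta", "strict_motif_prob", "n_sites")
  if (!all(req %in% names(classes))) {
    abort("substrate class table is missing required columns",
      class = "optophos_validation_error"
    )
  }
  nul <- classes[classes$class == "null", ]
  if (nrow(nul) && any(nul$beta != 0)) {
    abort("null class must have beta = 0", class = "optophos_validation_error")
  }
  df <- classes[classes$class == "direct_fast", ]
  if (nrow(df) && any(df$k_d < d)) {
    abort("direct_fast must decay at least as fast as the upstream signal",
      class = "optophos_validation_error"
    )
  }
  invisible(classes)
}

#' Simulate noiseless substrate occupancy under a light schedule
#'
#' Integrates the substrate occupancy equation for one class against the
#' piecewise-analytic activation trajectory of a schedule, using fixed-step
#' fourth-order Runge-Kutta on a fine grid (the forcing A(t) is time-varying,
#' so no closed form exists in general). Occupancy is clamped to `[0, 1]`.
#'
#' @param class Class name from [substrate_classes()], or a one-row tibble of
#'   class parameters.
#' @param schedule A [light_schedule()].
#' @param kinetics A [kinetic_params()] list.
#' @param times Sampling times (minutes), a subset of the integration window.
#' @param step RK4 step in minutes (default 0.01).
#' @param classes Class parameter table used to look up `class` by name.
#' @return Tibble with `time` and `occupancy`.
#' @export
simulate_site_occupancy <- function(class, schedule, kinetics,
                                    times = c(0, 10, 20, 30),
                                    step = 0.01,
                                    classes = substrate_classes()) {
  if (is.character(class)) {
    row <- classes[classes$class == class, ]
    if (nrow(row) != 1) {
      abort(paste0("unknown substrate class: ", class),
        class = "optophos_validation_error"
      )
    }
  } else {
    row <- class
  }
  t_end <- max(times, schedule$duration)
  occ <- occupancy_on_grid(row, schedule, kinetics, t_end = t_end, step = step)
  idx <- round(times / step) + 1L
  tibble(time = times, occupancy = occ[pmin(idx, length(occ))])
}

# S on the grid seq(0, t_end, step); activation evaluated analytically at the
# half-step resolution needed by RK4.
occupancy_on_grid <- function(row, schedule, kinetics, t_end, step = 0.01) {
  n <- ceiling(t_end / step)
  if (row$class == "null" || row$k_s == 0) {
    return(rep(0, n + 1L))
  }
  grid2 <- seq(0, by = step / 2, length.out = 2L * n + 1L)
  a_half <- pakt_activity(schedule, kinetics, grid2)$activity
  k_s <- row$k_s
  k_d <- row$k_d
  integrator <- identical(row$class, "integrator")
  # cascade intermediate feeding the integrator class (persistent kinetics)
  kp <- 0.8
  kd_p <- 0.02
  s <- numeric(n + 1L)
  cur <- 0
  p_cur <- 0
  h <- step
  for (i in seq_len(n)) {
    a1 <- a_half[2L * i - 1L]
    a2 <- a_half[2L * i]
    a3 <- a_half[2L * i + 1L]
    if (integrator) {
      # coupled RK4 on (P, S): dP = kp A (1-P) - kd_p P, dS = k_s P
      fp <- function(pv, av) kp * av * (1 - pv) - kd_p * pv
      p1 <- fp(p_cur, a1)
      s1 <- k_s * p_cur
      p2 <- fp(p_cur + h / 2 * p1, a2)
      s2 <- k_s * (p_cur + h / 2 * p1)
      p3 <- fp(p_cur + h / 2 * p2, a2)
      s3 <- k_s * (p_cur + h / 2 * p2)
      p4 <- fp(p_cur + h * p3, a3)
      s4 <- k_s * (p_cur + h * p3)
      p_cur <- min(max(p_cur + h / 6 * (p1 + 2 * p2 + 2 * p3 + p4), 0), 1)
      cur <- cur + h / 6 * (s1 + 2 * s2 + 2 * s3 + s4)
    } else {
      f <- function(sv, av) k_s * av * (1 - sv) - k_d * sv
      k1 <- f(cur, a1)
      k2 <- f(cur + h / 2 * k1, a2)
      k3 <- f(cur + h / 2 * k2, a2)
      k4 <- f(cur + h * k3, a3)
      cur <- cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    cur <- min(max(cur, 0), 1)
    s[i + 1L] <- cur
  }
  s
}
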