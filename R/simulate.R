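#' Configuration for the synthetic phosphoproteome generator
#'
#' Assembles and validates all generator settings. Defaults emulate the study
#' conditions of the optogenetic stimulation experiment: 27 light conditions
#' (3 intensities x {sustained, periodic, pulsed} x {10, 20, 30} min sampled
#' from a single 30-min trajectory per regime), a dark control, an optional
#' growth-factor-like series at 10/20/30 min, biological duplicates,
#' additive Gaussian noise on the log2 scale, and missing values inserted
#' completely at random.
#'
#' @param classes Substrate class table, see [substrate_classes()].
#' @param kinetics Activation kinetics, see [kinetic_params()].
#' @param noise List with `sigma_log2` (SD of additive log2 noise) and
#'   `missing_rate` in `[0, 1)`. The default `sigma_log2` is calibrated by
#'   simulation so that cross-replicate Pearson correlations bracket 0.94.
#' @param baseline List with `mean_log2` and `sd_log2` of per-site baseline
#'   log2 abundances.
#' @param design List with `times`, `replicates` and logical `growth_factor`.
#' @param growth_factor List controlling the growth-factor-like series:
#'   `steady_state` of the kinase drive (intermediate between the Su010 and
#'   Su025 steady states), `second_a`/`second_d` rates of the independent
#'   second-pathway activity, `responder_prob` and log2 `beta_range` of
#'   second-pathway responsiveness.
#' @param annotation List with `kinase_prob` (probability a site is annotated
#'   with its planted kinase), `background_kinase_prob` (probability of a
#'   spurious annotation from the kinase pool) and per-class benchmark list
#'   probabilities `pspdb`, `inhibitors`, `kinome` (named by class, with a
#'   `.default`).
#' @param reference List describing the simulated reference activation site
#'   (the pT308 analogue): `site_id`, `protein`, `position`, `flank`, `beta`.
#' @param step RK4 integration step (minutes) for substrate occupancies.
#' @return A validated list of class `optophos_sim_config`.
#' @export
sim_config <- function(classes = substrate_classes(),
                       kinetics = kinetic_params(),
                       noise = list(sigma_log2 = 0.44, missing_rate = 0.03),
                       baseline = list(mean_log2 = 20, sd_log2 = 1.3),
                       design = list(
                         times = c(10, 20, 30), replicates = 2,
                         growth_factor = TRUE
                       ),
                       growth_factor = list(
                         steady_state = 0.63, second_a = 0.3, second_d = 0.1,
                         responder_prob = 0.25, beta_range = c(0.5, 2)
                       ),
                       annotation = list(
                         kinase_prob = 0.6, background_kinase_prob = 0.02,
                         pspdb = c(direct_fast = 0.5, direct_slow = 0.25, .default = 0.05),
                         inhibitors = c(direct_fast = 0.4, direct_slow = 0.2, .default = 0.02),
                         kinome = c(direct_fast = 0.5, direct_slow = 0.1, .default = 0.03)
                       ),
                       reference = list(
                         site_id = "AKT1_T308", protein = "AKT1", position = 308,
                         flank = "KDGATMKTFCGTPEY", beta = 12
                       ),
                       step = 0.01) {
  cfg <- list(
    classes = classes, kinetics = kinetics, noise = noise,
    baseline = baseline, design = design, growth_factor = growth_factor,
    annotation = annotation, reference = reference, step = step
  )
  check_substrate_classes(classes, kinetics$d)
  if (sum(classes$n_sites) <= 0) {
    abort("config defines zero sites", class = "optophos_validation_error")
  }
  if (is.null(reference$site_id) || is.null(reference$flank) ||
      nchar(reference$flank) != 15) {
    abort("config must define a reference site with a 15-residue flank",
      class = "optophos_validation_error"
    )
  }
  if (noise$sigma_log2 < 0 || noise$missing_rate < 0 || noise$missing_rate >= 1) {
    abort("noise settings out of range", class = "optophos_validation_error")
  }
  structure(cfg, class = "optophos_sim_config")
}

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random +/-7 flanks centred on S/T; with probability `strict_prob` the strict
# basophilic motif (R at -5 and -3) is planted on top of the random background
random_flanks <- function(n, strict_prob) {
  if (n == 0) return(character(0))
  m <- matrix(sample(AMINO_ACIDS, 15L * n, replace = TRUE), nrow = n)
  m[, 8] <- sample(c("S", "T"), n, replace = TRUE)
  plant <- runif(n) < strict_prob
  m[plant, 3] <- "R"
  m[plant, 5] <- "R"
  apply(m, 1, paste0, collapse = "")
}

#' Generate a synthetic optogenetic phosphoproteome with known ground truth
#'
#' Draws a full study: per-class noiseless substrate occupancies under every
#' stimulation regime (via the piecewise-analytic activation solution and RK4
#' substrate integration), per-site baselines, flanking sequences with planted
#' motifs, planted kinase annotations and benchmark-list memberships, then
#' emits replicate log2 measurements
#' `log2(baseline * (1 + beta * S)) + noise` with missing values inserted
#' completely at random. All stochastic draws flow from a single seeded
#' generator in a fixed order (classes, baselines, flanks, annotations,
#' growth-factor responsiveness, noise, missingness), so output is
#' deterministic for a given `config` and `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `optophos_sim` with tibbles `quant` (wide, site_id
#'   plus one column per sample), `design`, `annotations` and `truth`.
#' @examples
#' sim <- simulate_phospho_experiment(seed = 1)
#' dim(sim$quant)
#' @export
simulate_phospho_experiment <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "optophos_sim_config"))
  set.seed(as.integer(seed))

  classes <- config$classes
  kin <- config$kinetics
  times <- config$design$times
  reps <- config$design$replicates

  ## ---- study design -------------------------------------------------------
  schedules <- all_light_schedules(duration_min = max(times))
  light <- tidyr::expand_grid(
    intensity = light_intensities(), pattern = light_patterns(),
    time_min = times, replicate = seq_len(reps)
  ) %>% mutate(stimulus = "light")
  dark <- tidyr::expand_grid(replicate = seq_len(reps)) %>%
    mutate(intensity = "none", pattern = "none", time_min = 0, stimulus = "dark")
  design <- bind_rows(dark, light)
  if (isTRUE(config$design$growth_factor)) {
    gf <- tidyr::expand_grid(time_min = times, replicate = seq_len(reps)) %>%
      mutate(intensity = "none", pattern = "none", stimulus = "growth_factor")
    design <- bind_rows(design, gf)
  }
  design <- design %>%
    mutate(
      sample_id = paste0(condition_id(.), "_r", .data$replicate)
    ) %>%
    select("sample_id", "intensity", "pattern", "time_min", "replicate", "stimulus")

  ## ---- per-class noiseless occupancies ------------------------------------
  # one trajectory per class x regime, sampled at the within-regime timepoints
  occ <- list() # occ[[class]][[condition]] -> occupancy
  for (ci in seq_len(nrow(classes))) {
    row <- classes[ci, ]
    by_cond <- list()
    for (nm in names(schedules)) {
      s <- simulate_site_occupancy(row, schedules[[nm]], kin,
        times = times, step = config$step
      )
      for (k in seq_along(times)) {
        by_cond[[paste0(nm, "_", times[k])]] <- s$occupancy[k]
      }
    }
    by_cond[["dark"]] <- 0
    occ[[row$class]] <- by_cond
  }
  # reference site occupancy is the activation trajectory itself
  ref_occ <- list(dark = 0)
  for (nm in names(schedules)) {
    a <- pakt_activity(schedules[[nm]], kin, times)$activity
    for (k in seq_along(times)) ref_occ[[paste0(nm, "_", times[k])]] <- a[k]
  }

  # growth-factor series: kinase driven at an intermediate sustained level,
  # plus an independent second-pathway activity
  if (isTRUE(config$design$growth_factor)) {
    gfp <- config$growth_factor
    a_gf <- kin$d * gfp$steady_state / (1 - gfp$steady_state)
    gf_kin <- list(a_by_intensity = c("005" = a_gf, "010" = a_gf, "025" = a_gf), d = kin$d)
    gf_sched <- light_schedule("Su", "005", max(times))
    for (ci in seq_len(nrow(classes))) {
      row <- classes[ci, ]
      s <- simulate_site_occupancy(row, gf_sched, gf_kin,
        times = times, step = config$step
      )
      for (k in seq_along(times)) {
        occ[[row$class]][[paste0("GF_", times[k])]] <- s$occupancy[k]
      }
    }
    a <- pakt_activity(gf_sched, gf_kin, times)$activity
    for (k in seq_along(times)) ref_occ[[paste0("GF_", times[k])]] <- a[k]
    # second-pathway activity at the sampling times
    e_kin <- list(
      a_by_intensity = c(
        "005" = gfp$second_a, "010" = gfp$second_a, "025" = gfp$second_a
      ),
      d = gfp$second_d
    )
    second <- pakt_activity(gf_sched, e_kin, times)$activity
    names(second) <- paste0("GF_", times)
  } else {
    second <- numeric(0)
  }

  ## ---- site table (stochastic draws in documented order) ------------------
  site_classes <- rep(classes$class, classes$n_sites)
  n_sites <- length(site_classes) + 1L # + reference
  site_id <- c(
    config$reference$site_id,
    sprintf("PROT%04d_%s", seq_along(site_classes), site_classes_short(site_classes))
  )
  class_vec <- c("reference", site_classes)

  baseline <- rnorm(n_sites, config$baseline$mean_log2, config$baseline$sd_log2)

  flanks <- character(n_sites)
  flanks[1] <- config$reference$flank
  motif_prob <- classes$strict_motif_prob[match(site_classes, classes$class)]
  flanks[-1] <- random_flanks(n_sites - 1L, motif_prob)

  kin_pool <- unique(stats::na.omit(classes$kinase))
  planted_kinase <- c(NA_character_, classes$kinase[match(site_classes, classes$class)])
  ann_cfg <- config$annotation
  has_planted <- !is.na(planted_kinase) & runif(n_sites) < ann_cfg$kinase_prob
  bg_kinase <- ifelse(
    runif(n_sites) < ann_cfg$background_kinase_prob,
    sample(kin_pool, n_sites, replace = TRUE), NA_character_
  )
  kinases <- purrr::map2_chr(
    ifelse(has_planted, planted_kinase, NA_character_), bg_kinase,
    ~ paste(stats::na.omit(c(.x, .y)), collapse = ";")
  )
  kinases[kinases == ""] <- NA_character_
  kinases[1] <- "PDK1"

  list_flag <- function(probs) {
    p <- probs[class_vec]
    p[is.na(p)] <- probs[[".default"]]
    out <- runif(n_sites) < p
    out[1] <- TRUE # the reference site is a canonical list member
    out
  }
  in_pspdb <- list_flag(ann_cfg$pspdb)
  in_inhibitors <- list_flag(ann_cfg$inhibitors)
  in_kinome <- list_flag(ann_cfg$kinome)
  in_motif <- match_motif(flanks, builtin_motifs()$akt_strict)

  gfp <- config$growth_factor
  gf_responder <- isTRUE(config$design$growth_factor) &
    runif(n_sites) < gfp$responder_prob
  gf_responder[1] <- FALSE # the reference reads out the kinase drive only
  gf_beta <- ifelse(
    gf_responder,
    sample(c(-1, 1), n_sites, replace = TRUE) *
      runif(n_sites, gfp$beta_range[1], gfp$beta_range[2]),
    0
  )

  beta <- c(config$reference$beta, classes$beta[match(site_classes, classes$class)])

  ## ---- measurement matrix -------------------------------------------------
  conds <- condition_id(design)
  n_samp <- nrow(design)
  signal <- matrix(0, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    cn <- conds[j]
    s_site <- vapply(
      class_vec,
      function(cl) if (cl == "reference") ref_occ[[cn]] else occ[[cl]][[cn]],
      numeric(1)
    )
    y <- baseline + log2(1 + beta * s_site)
    if (design$stimulus[j] == "growth_factor") {
      y <- y + gf_beta * second[[cn]]
    }
    signal[, j] <- y
  }
  noise <- matrix(
    rnorm(n_sites * n_samp, 0, config$noise$sigma_log2), n_sites, n_samp
  )
  values <- signal + noise
  if (config$noise$missing_rate > 0) {
    miss <- matrix(
      runif(n_sites * n_samp) < config$noise$missing_rate, n_sites, n_samp
    )
    miss[1, ] <- FALSE # reference quantified in every sample
    values[miss] <- NA_real_
  }
  colnames(values) <- design$sample_id

  quant <- bind_cols(tibble(site_id = site_id), as_tibble(values))

  annotations <- tibble(
    site_id = site_id,
    protein = c(config$reference$protein, sub("_.*$", "", site_id[-1])),
    position = c(config$reference$position, seq_len(n_sites - 1L) %% 900L + 10L),
    residue = substr(flanks, 8, 8),
    flank15 = flanks,
    kinases = kinases,
    in_pspdb = in_pspdb,
    in_motif = in_motif,
    in_inhibitors = in_inhibitors,
    in_kinome = in_kinome
  )

  truth <- tibble(
    site_id = site_id,
    class = class_vec,
    planted_kinase = planted_kinase,
    flank15 = flanks,
    strict_motif = in_motif,
    is_reference = site_id == config$reference$site_id,
    gf_responder = gf_responder,
    gf_beta = gf_beta,
    baseline_log2 = baseline,
    beta = beta
  )

  structure(
    list(quant = quant, design = design, annotations = annotations, truth = truth),
    class = "optophos_sim"
  )
}

site_classes_short <- function(cl) {
  abbr <- c(
    direct_fast = "DF", direct_slow = "DS", persistent = "PS",
    integrator = "IN", suppressed = "SP", null = "NL"
  )
  abbr[cl]
}

#' @export
print.optophos_sim <- function(x, ...) {
  cat(sprintf(
    "<optophos_sim> %d sites x %d samples (%d conditions)\n",
    nrow(x$quant), nrow(x$design), length(unique(condition_id(x$design)))
  ))
  invisible(x)
}

#' Average cross-replicate Pearson correlation
#'
#' For every condition with two or more replicates, computes the Pearson
#' correlation between replicate sample columns across sites (pairwise for
#' replicate pairs) and returns the mean. Used to calibrate the noise model
#' against the reproducibility observed in real replicate runs.
#'
#' @param quant Wide quantification tibble (`site_id` + sample columns).
#' @param design Study-design tibble.
#' @return Mean Pearson correlation over replicate pairs.
#' @export
replicate_correlation <- function(quant, design) {
  conds <- condition_id(design)
  vals <- as.matrix(quant[, design$sample_id, drop = FALSE])
  cors <- c()
  for (cn in unique(conds)) {
    cols <- which(conds == cn)
    if (length(cols) < 2) next
    prs <- utils::combn(cols, 2)
    for (k in seq_len(ncol(prs))) {
      cors <- c(cors, cor(
        vals[, prs[1, k]], vals[, prs[2, k]],
        use = "pairwise.complete.obs"
      ))
    }
  }
  mean(cors)
}
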