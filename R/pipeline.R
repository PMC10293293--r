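#' Pipeline configuration
#'
#' Collects every stage threshold with its standard default: trait-test
#' alpha 0.01, paired-test alpha 0.01 with linear fold gate 1.5 and 5
#' hierarchical clusters, activation fold gate 1.5 on the periodic
#' high-intensity group, fuzzy c-means with 4 clusters and fuzzifier 1.25
#' (12 clusters for the cross-regime analysis), enrichment gates EF > 1 /
#' >= 4 sites / p < 0.05, covariation threshold R > 0.85, two-series gate
#' q < 0.05 with R-squared >= 0.8 and 4 profile clusters.
#'
#' @param simulate A [sim_config()] used to generate inputs, or `NULL` when
#'   `quant`/`design`/`annotations` are supplied to [run_pipeline()].
#' @param anova_alpha,paired_alpha,paired_fold,paired_gate,hcluster_k
#'   Trait-test and intensity-contrast settings.
#' @param activation_group,activation_fold Activation filter settings.
#' @param fcm_clusters,fcm_m,fcm_threshold Fuzzy clustering settings.
#' @param enrich_min_sites,enrich_alpha Enrichment gates.
#' @param covariation_threshold,covariation_min_n Covariation settings.
#' @param timecourse_series_a,timecourse_series_b,timecourse_degree,
#'   timecourse_alpha,timecourse_rsq,timecourse_k Two-series settings.
#' @param stages Character vector of stages to run (any of `"anova"`,
#'   `"intensity"`, `"fcm"`, `"enrich"`, `"covariation"`, `"timecourse"`).
#' @return List of class `optophos_pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            anova_alpha = 0.01,
                            paired_alpha = 0.01,
                            paired_fold = 1.5,
                            paired_gate = "both",
                            hcluster_k = 5,
                            activation_group = "Pe025",
                            activation_fold = 1.5,
                            fcm_clusters = 4,
                            fcm_m = 1.25,
                            fcm_threshold = 0,
                            enrich_min_sites = 4,
                            enrich_alpha = 0.05,
                            covariation_threshold = 0.85,
                            covariation_min_n = 10,
                            timecourse_series_a = "Su010",
                            timecourse_series_b = "growth_factor",
                            timecourse_degree = 2,
                            timecourse_alpha = 0.05,
                            timecourse_rsq = 0.8,
                            timecourse_k = 4,
                            stages = c(
                              "anova", "intensity", "fcm", "enrich",
                              "covariation", "timecourse"
                            )) {
  cfg <- as.list(environment())
  structure(cfg, class = "optophos_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping of [pipeline_config()] arguments (unknown keys are
#' rejected). The configuration round-trips losslessly through
#' [write_pipeline_config()].
#'
#' @param path YAML file path.
#' @return An `optophos_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  if (!is.null(vals$stages)) vals$stages <- unlist(vals$stages)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config An `optophos_pipeline_config` (the `simulate` block is not
#'   serialised; defaults are restored on read).
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals$simulate <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or ingestion), trait attribution,
#' intensity contrasts with hierarchical clustering, activation filtering
#' with fuzzy c-means temporal clustering on the pulsed regime, motif and
#' kinase enrichment of the temporal clusters, covariation discovery against
#' the reference site, and two-series time-course differential analysis.
#' Every stage is a pure function of its declared inputs and all randomness
#' derives from `seed`, so two runs with the same configuration and seed
#' produce identical results.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed (drives simulation and the seeded clusterings).
#' @param quant,design,annotations Optional pre-existing input tables; when
#'   omitted, data are simulated from `config$simulate`.
#' @param reference_site Reference site id; defaults to the simulated
#'   reference.
#' @param outdir Optional directory; when given, per-stage TSVs and a
#'   summary are written there.
#' @return List of class `optophos_pipeline` with per-stage results and a
#'   `summary` tibble of funnel counts.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         quant = NULL, design = NULL, annotations = NULL,
                         reference_site = NULL, outdir = NULL) {
  stopifnot(inherits(config, "optophos_pipeline_config"))
  truth <- NULL
  if (is.null(quant)) {
    sim <- simulate_phospho_experiment(config$simulate, seed = seed)
    quant <- sim$quant
    design <- sim$design
    annotations <- sim$annotations
    truth <- sim$truth
    if (is.null(reference_site)) {
      reference_site <- config$simulate$reference$site_id
    }
  }
  res <- list(
    quant = quant, design = design, annotations = annotations, truth = truth
  )
  summary <- list(tibble(
    stage = "input", metric = "n_sites", value = nrow(quant)
  ), tibble(
    stage = "input", metric = "n_samples", value = nrow(design)
  ))
  cmeans_all <- condition_means(quant, design)
  res$condition_means <- cmeans_all

  if ("anova" %in% config$stages) {
    res$anova <- anova_traits(quant, design, alpha = config$anova_alpha)
    cnt <- trait_counts(res$anova)
    summary <- c(summary, list(tibble(
      stage = "anova", metric = paste0(cnt$trait, "_significant"),
      value = cnt$n_significant
    )))
  }

  if ("intensity" %in% config$stages) {
    res$paired_tests <- paired_intensity_tests(cmeans_all)
    passing <- intensity_regulated_sites(
      res$paired_tests,
      alpha = config$paired_alpha, fold = config$paired_fold,
      gate = config$paired_gate
    )
    res$intensity_regulated <- passing
    summary <- c(summary, list(tibble(
      stage = "intensity", metric = "n_regulated", value = length(passing)
    )))
    if (length(passing) >= config$hcluster_k) {
      res$hclusters <- cluster_intensity_profiles(
        cmeans_all, passing,
        k = config$hcluster_k
      )
      sizes <- table(res$hclusters$cluster)
      summary <- c(summary, list(tibble(
        stage = "intensity",
        metric = paste0("hC", names(sizes), "_size"),
        value = as.numeric(sizes)
      )))
    }
  }

  activated <- NULL
  if ("fcm" %in% config$stages) {
    activated <- akt_activated_sites(
      cmeans_all,
      group = config$activation_group, fold = config$activation_fold
    )
    res$activated_sites <- activated
    summary <- c(summary, list(tibble(
      stage = "fcm", metric = "n_activated", value = length(activated)
    )))
    pulse_group <- sub("^Pe", "Pu", normalize_group(config$activation_group))
    prof_cols <- c("dark", grep(
      paste0("^", pulse_group, "_"), names(cmeans_all),
      value = TRUE
    ))
    profiles <- cmeans_all[match(activated, cmeans_all$site_id), c("site_id", prof_cols)]
    feats <- normalize_profiles(profiles, mode = "t1")
    if (nrow(feats) >= config$fcm_clusters) {
      res$fcm <- fuzzy_cmeans(
        feats,
        centers = config$fcm_clusters, m = config$fcm_m,
        seed = seed + 101L
      )
      res$fcm_labels <- assign_clusters(res$fcm, threshold = config$fcm_threshold)
      sizes <- table(res$fcm_labels$cluster)
      summary <- c(summary, list(tibble(
        stage = "fcm", metric = paste0("fC", names(sizes), "_size"),
        value = as.numeric(sizes)
      )))
    }
  }

  if ("enrich" %in% config$stages && !is.null(res$fcm_labels)) {
    strict <- builtin_motifs()$akt_strict
    bg <- annotations$flank15
    per_cluster <- res$fcm_labels %>%
      left_join(annotations[, c("site_id", "flank15")], by = "site_id") %>%
      group_by(.data$cluster) %>%
      summarise(
        motif_pct = motif_fraction(.data$flank15, strict), .groups = "drop"
      )
    res$motif_fractions <- per_cluster
    res$motif_enrichment <- res$fcm_labels %>%
      left_join(annotations[, c("site_id", "flank15")], by = "site_id") %>%
      group_by(.data$cluster) %>%
      dplyr::group_modify(~ motif_enrichment(.x$flank15, bg, strict)) %>%
      ungroup()
    labelled <- res$fcm_labels[!is.na(res$fcm_labels$cluster), ]
    res$kinase_enrichment <- kinase_site_enrichment(
      labelled, annotations[annotations$site_id %in% labelled$site_id, ],
      min_sites = config$enrich_min_sites, alpha = config$enrich_alpha
    )
    summary <- c(summary, list(
      tibble(
        stage = "enrich",
        metric = paste0("fC", per_cluster$cluster, "_strict_motif_pct"),
        value = per_cluster$motif_pct
      ),
      tibble(
        stage = "enrich", metric = "n_kinase_enrichments_passing",
        value = sum(res$kinase_enrichment$pass)
      )
    ))
  }

  if ("covariation" %in% config$stages && !is.null(reference_site)) {
    res$covariation <- correlate_to_reference(
      cmeans_all, reference_site,
      threshold = config$covariation_threshold,
      min_n = config$covariation_min_n
    )
    res$benchmarks <- benchmark_lists(res$covariation, annotations)
    core <- res$covariation$site_id[res$covariation$covaries]
    res$core_set <- core
    lists <- list(
      core = core,
      pspdb = annotations$site_id[annotations$in_pspdb],
      motif = annotations$site_id[annotations$in_motif],
      inhibitors = annotations$site_id[annotations$in_inhibitors],
      kinome = annotations$site_id[annotations$in_kinome]
    )
    res$mutual_support <- mutual_support(lists)
    summary <- c(summary, list(tibble(
      stage = "covariation", metric = "core_set_size", value = length(core)
    )))
  }

  if ("timecourse" %in% config$stages &&
      any(condition_group(design) == normalize_group(config$timecourse_series_b))) {
    res$two_series <- fit_two_series(
      quant, design,
      series_a = config$timecourse_series_a,
      series_b = config$timecourse_series_b,
      degree = config$timecourse_degree,
      alpha = config$timecourse_alpha, rsq = config$timecourse_rsq
    )
    n_sig <- sum(res$two_series$significant)
    summary <- c(summary, list(tibble(
      stage = "timecourse", metric = "n_significant", value = n_sig
    )))
    if (n_sig >= config$timecourse_k) {
      res$timecourse_clusters <- partition_profiles(
        res$two_series,
        k = config$timecourse_k, seed = seed + 202L
      )
      sizes <- table(res$timecourse_clusters$cluster)
      summary <- c(summary, list(tibble(
        stage = "timecourse", metric = paste0("mC", names(sizes), "_size"),
        value = as.numeric(sizes)
      )))
    }
  }

  res$summary <- bind_rows(summary)
  res$seed <- seed
  res$config <- config
  out <- structure(res, class = "optophos_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' @export
print.optophos_pipeline <- function(x, ...) {
  cat("<optophos_pipeline>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_quant_matrix(res$quant, file.path(outdir, "quant_matrix.tsv"))
  write_study_design(res$design, file.path(outdir, "design.tsv"))
  write_site_annotations(res$annotations, file.path(outdir, "annotations.tsv"))
  if (!is.null(res$truth)) {
    readr::write_tsv(res$truth, file.path(outdir, "truth.tsv"), na = "NA")
  }
  tsv <- function(obj, name) {
    if (!is.null(obj) && is.data.frame(obj)) {
      readr::write_tsv(as_tibble(obj), file.path(outdir, name), na = "NA")
    }
  }
  tsv(res$anova, "anova.tsv")
  tsv(res$paired_tests, "paired_tests.tsv")
  tsv(res$hclusters, "hclusters.tsv")
  tsv(res$fcm_labels, "fcm_labels.tsv")
  if (!is.null(res$fcm)) {
    tsv(as_tibble(res$fcm$centers), "fcm_centers.tsv")
    tsv(tidy(res$fcm), "fcm_memberships.tsv")
  }
  tsv(res$motif_fractions, "motif_fractions.tsv")
  tsv(res$kinase_enrichment, "kinase_enrichment.tsv")
  tsv(res$covariation, "covariation.tsv")
  tsv(res$benchmarks, "benchmarks.tsv")
  if (!is.null(res$mutual_support)) {
    tsv(res$mutual_support$support, "mutual_support.tsv")
  }
  tsv(res$two_series, "two_series.tsv")
  tsv(res$timecourse_clusters, "timecourse_clusters.tsv")
  tsv(res$summary, "summary.tsv")
  invisible(outdir)
}
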