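strict <- builtin_motifs()$akt_strict
generic <- builtin_motifs()$akt_generic

test_that("constructed flanks match the expected motifs", {
  # R at -5 and -3, S at the centre
  strict_flank <- "AARARAASAAAAAAA"
  expect_true(match_motif(strict_flank, strict))
  expect_true(match_motif(strict_flank, generic))
  # R at -3 only
  generic_flank <- "AAAARAASAAAAAAA"
  expect_false(match_motif(generic_flank, strict))
  expect_true(match_motif(generic_flank, generic))
  # padding never satisfies a constraint
  padded <- "__R_RAASAAAAAAA"
  expect_true(match_motif(padded, strict))
  expect_false(match_motif("_____AASAAAAAAA", generic))
  expect_error(match_motif("SHORT", strict), class = "optophos_validation_error")
})

test_that("matching agrees exactly with a regular-expression oracle", {
  set.seed(10)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- 10000
  m <- matrix(sample(aa, 15 * n, replace = TRUE), n, 15)
  m[, 8] <- sample(c("S", "T", "Y", "A"), n, replace = TRUE)
  flanks <- apply(m, 1, paste0, collapse = "")
  oracles <- list(
    akt_strict = "^..R.R..[ST]",
    akt_generic = "^....R..[ST]",
    mapk_pxstp = "^.....P.[ST]P",
    mapk_pxstpxp = "^.....P.[ST]P.P",
    ck2_stdxe = "^.......[ST]D.E"
  )
  for (nm in names(oracles)) {
    expect_identical(
      match_motif(flanks, builtin_motifs()[[nm]]),
      grepl(oracles[[nm]], flanks),
      label = nm
    )
  }
})

test_that("motif fractions are percentages with an empty-set guard", {
  expect_equal(motif_fraction(rep("AARARAASAAAAAAA", 5), strict), 100)
  expect_equal(
    motif_fraction(c("AARARAASAAAAAAA", rep("AAAAAAASAAAAAAA", 3)), strict), 25
  )
  expect_error(motif_fraction(character(0), strict), class = "optophos_validation_error")
})

test_that("planted motif probabilities are recovered by the generator", {
  cls <- substrate_classes()
  cls$n_sites <- c(5000L, 0L, 0L, 0L, 0L, 5000L)
  cfg <- sim_config(classes = cls)
  sim <- simulate_phospho_experiment(cfg, seed = 12)
  tr <- sim$truth[!sim$truth$is_reference, ]
  for (cl in c("direct_fast", "null")) {
    p_cfg <- cls$strict_motif_prob[cls$class == cl]
    frac <- motif_fraction(tr$flank15[tr$class == cl], strict) / 100
    se <- sqrt(p_cfg * (1 - p_cfg) / sum(tr$class == cl))
    # random background can also match by chance, inflating slightly
    expect_lt(abs(frac - p_cfg), 3 * se + 1 / 20^2)
  }
})

test_that("enrichment factor and Fisher p behave on canonical tables", {
  # foreground rate equals background rate -> EF = 1
  fg <- c(rep("AARARAASAAAAAAA", 2), rep("AAAAAAASAAAAAAA", 8))
  bg <- c(fg, rep("AARARAASAAAAAAA", 4), rep("AAAAAAASAAAAAAA", 16))
  rec <- motif_enrichment(fg, bg, strict)
  expect_equal(rec$enrichment_factor, 1)
  # no foreground matches -> one-sided p = 1
  fg0 <- rep("AAAAAAASAAAAAAA", 5)
  rec0 <- motif_enrichment(fg0, c(fg0, fg), strict)
  expect_equal(rec0$a, 0)
  expect_equal(rec0$p, 1)
  expect_error(
    motif_enrichment(character(0), bg, strict),
    class = "optophos_validation_error"
  )
})

test_that("the published-style table reproduces the hypergeometric tail", {
  p <- optophos:::fisher_enrichment_p(8, 42, 30, 920)
  expect_equal(p, hyper_tail_oracle(8, 42, 30, 920), tolerance = 1e-12)
  expect_equal(
    p,
    stats::fisher.test(matrix(c(8, 42, 30, 920), 2, byrow = TRUE),
      alternative = "greater"
    )$p.value,
    tolerance = 1e-9
  )
})

test_that("kinase enrichment applies the minimum-count and EF gates", {
  labels <- tibble::tibble(
    site_id = paste0("s", 1:40),
    cluster = rep(1:2, each = 20)
  )
  # 3 annotated sites concentrated in cluster 1: gated out regardless of p
  ann3 <- tibble::tibble(site_id = paste0("s", 1:3), kinase = "K3")
  res3 <- kinase_site_enrichment(labels, ann3)
  expect_false(any(res3$pass[res3$kinase == "K3"]))
  # 8 annotated sites in cluster 1: passes there and nowhere else
  ann8 <- tibble::tibble(site_id = paste0("s", 1:8), kinase = "K8")
  res8 <- kinase_site_enrichment(labels, ann8)
  expect_true(res8$pass[res8$kinase == "K8" & res8$cluster == 1])
  expect_false(res8$pass[res8$kinase == "K8" & res8$cluster == 2])
  expect_true(res8$predominant[res8$kinase == "K8" & res8$cluster == 1])
})

test_that("annotations outside the universe are dropped with a warning", {
  labels <- tibble::tibble(site_id = paste0("s", 1:10), cluster = rep(1:2, 5))
  ann <- tibble::tibble(site_id = c("s1", "s2", "ghost"), kinase = "K")
  expect_warning(res <- kinase_site_enrichment(labels, ann), "outside")
  expect_equal(max(res$a + res$c), 2)
})

test_that("planted kinases are recovered in their own class", {
  sim <- simulate_phospho_experiment(seed = 13)
  truth <- sim$truth[!sim$truth$is_reference & sim$truth$class != "null", ]
  class_levels <- sort(unique(truth$class))
  labels <- tibble::tibble(
    site_id = truth$site_id,
    cluster = match(truth$class, class_levels)
  )
  ann_in <- sim$annotations[sim$annotations$site_id %in% labels$site_id, ]
  res <- kinase_site_enrichment(labels, ann_in)
  res <- res[res$kinase %in% stats::na.omit(substrate_classes()$kinase), ]
  cls <- substrate_classes()
  for (kin in unique(res$kinase)) {
    own_class <- cls$class[match(kin, cls$kinase)]
    pred <- res[res$kinase == kin & res$predominant, ]
    expect_equal(nrow(pred), 1)
    expect_equal(class_levels[pred$cluster], own_class)
  }
})
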