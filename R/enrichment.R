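# Positional phospho-motif matching on +/-7 flanking windows, motif fold
# enrichment, and site-level kinase-substrate enrichment with one-sided
# Fisher tests and the enrichment gates (EF > 1, >= 4 annotated sites for
# kinase categories, p < 0.05).

#' Built-in phosphorylation sequence motifs
#'
#' Positional constraint sets on the +/-7 window (position 0 is the
#' phosphoacceptor): the strict basophilic AKT motif `R-x-R-x-x-S/T`, the
#' generic `R-x-x-S/T`, the proline-directed MAPK motifs `P-x-S/T-P` and
#' `P-x-S/T-P-x-P`, and the acidophilic CK2 motif `S/T-D-x-E`.
#'
#' @return Named list of motif objects (class `optophos_motif`).
#' @export
builtin_motifs <- function() {
  list(
    akt_strict = motif_pattern("akt_strict", "-5:R,-3:R,0:ST"),
    akt_generic = motif_pattern("akt_generic", "-3:R,0:ST"),
    mapk_pxstp = motif_pattern("mapk_pxstp", "-2:P,0:ST,1:P"),
    mapk_pxstpxp = motif_pattern("mapk_pxstpxp", "-2:P,0:ST,1:P,3:P"),
    ck2_stdxe = motif_pattern("ck2_stdxe", "0:ST,1:D,3:E")
  )
}

#' Define a positional motif
#'
#' @param name Motif name.
#' @param definition Comma-separated `position:residues` constraints with
#'   positions relative to the phosphoacceptor (e.g. `"-5:R,-3:R,0:ST"`).
#'   A constraint at position 0 (the acceptor) is required.
#' @return An `optophos_motif` object.
#' @export
motif_pattern <- function(name, definition) {
  parts <- strsplit(strsplit(definition, ",")[[1]], ":")
  pos <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  res <- vapply(parts, function(p) p[2], character(1))
  if (any(abs(pos) > 7)) {
    abort("motif positions must lie within +/-7", class = "optophos_validation_error")
  }
  if (!0 %in% pos) {
    abort("motif must constrain the central phosphoacceptor (position 0)",
      class = "optophos_validation_error"
    )
  }
  structure(
    list(name = name, positions = pos, residues = strsplit(res, "")),
    class = "optophos_motif"
  )
}

#' Match flanking sequences against a motif
#'
#' Vectorised positional matching of 15-residue flanks (phosphoacceptor at
#' the centre). The padding character `_` never satisfies a residue
#' constraint, so truncated windows near protein termini can only fail.
#'
#' @param flank15 Character vector of 15-residue flanks.
#' @param pattern An `optophos_motif` (see [builtin_motifs()]).
#' @return Logical vector.
#' @examples
#' match_motif("AARTRAASAAAAAAA", builtin_motifs()$akt_strict)
#' @export
match_motif <- function(flank15, pattern) {
  stopifnot(inherits(pattern, "optophos_motif"))
  if (any(nchar(flank15) != 15)) {
    abort("flanks must be exactly 15 residues", class = "optophos_validation_error")
  }
  out <- rep(TRUE, length(flank15))
  for (k in seq_along(pattern$positions)) {
    at <- pattern$positions[k] + 8L
    ch <- substr(flank15, at, at)
    out <- out & ch %in% pattern$residues[[k]]
  }
  out
}

#' Percentage of sites matching a motif
#'
#' @param flank15 Character vector of flanks (non-empty).
#' @inheritParams match_motif
#' @return Percentage in `[0, 100]`.
#' @export
motif_fraction <- function(flank15, pattern) {
  if (length(flank15) == 0) {
    abort("empty site set", class = "optophos_validation_error")
  }
  100 * mean(match_motif(flank15, pattern))
}

# one-sided (enrichment) Fisher p from the hypergeometric upper tail of the
# 2x2 table [[a, b], [c, d]]: a successes among a+b draws from a+c successes
# in N = a+b+c+d
fisher_enrichment_p <- function(a, b, c, d) {
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

enrichment_record <- function(a, b, c, d) {
  n <- a + b + c + d
  ef <- (a / (a + b)) / ((a + c) / n)
  tibble(
    a = a, b = b, c = c, d = d,
    enrichment_factor = ef,
    p = fisher_enrichment_p(a, b, c, d)
  )
}

#' Motif enrichment of a foreground set against the measured background
#'
#' Builds the 2x2 table (foreground matches / foreground non-matches /
#' background-only matches / background-only non-matches) and reports the
#' enrichment factor `EF = (a/(a+b)) / ((a+c)/N)` with a one-sided Fisher
#' exact p-value from the hypergeometric upper tail. The background universe
#' is the full set of quantified sites (including the foreground).
#'
#' @param foreground Flanks of the foreground site set (non-empty).
#' @param background Flanks of the universe; must contain the foreground.
#' @inheritParams match_motif
#' @return One-row tibble with `motif`, counts `a`-`d`, `enrichment_factor`,
#'   `p`, `pass` (EF > 1 and p < 0.05).
#' @export
motif_enrichment <- function(foreground, background, pattern) {
  if (length(foreground) == 0) {
    abort("empty foreground set", class = "optophos_validation_error")
  }
  if (length(background) < length(foreground)) {
    abort("background universe smaller than foreground",
      class = "optophos_validation_error"
    )
  }
  fg <- match_motif(foreground, pattern)
  bg <- match_motif(background, pattern)
  a <- sum(fg)
  b <- sum(!fg)
  cc <- sum(bg) - a
  dd <- sum(!bg) - b
  rec <- enrichment_record(a, b, cc, dd)
  bind_cols(tibble(motif = pattern$name), rec) %>%
    mutate(pass = .data$enrichment_factor > 1 & .data$p < 0.05)
}

#' Site-level kinase-substrate enrichment per cluster
#'
#' For every (cluster, kinase) pair, tests over-representation of the
#' kinase's annotated sites in the cluster against the clustered universe
#' with a one-sided Fisher exact test. The pass gate requires an enrichment
#' factor above 1, at least `min_sites` annotated sites inside the cluster
#' and p below `alpha`. When a kinase passes in several clusters, its
#' `predominant` cluster is the one with the lowest p-value.
#'
#' @param labels Tibble with `site_id` and `cluster` (the clustered
#'   universe).
#' @param kinase_annotations Either a long tibble (`site_id`, `kinase`) or a
#'   site-annotation table with a `;`-separated `kinases` column. Annotated
#'   sites absent from the universe are dropped with a warning.
#' @param min_sites Minimum annotated sites in the cluster for the gate.
#' @param alpha P-value gate.
#' @return Tibble with `cluster`, `kinase`, counts `a`-`d`,
#'   `enrichment_factor`, `p`, `pass`, `predominant`.
#' @export
kinase_site_enrichment <- function(labels, kinase_annotations,
                                   min_sites = 4, alpha = 0.05) {
  ann <- kinase_annotation_long(kinase_annotations)
  universe <- labels$site_id
  outside <- setdiff(unique(ann$site_id), universe)
  if (length(outside)) {
    warn(sprintf(
      "%d annotated sites are outside the clustered universe and were dropped",
      length(outside)
    ))
    ann <- ann[ann$site_id %in% universe, ]
  }
  n_univ <- length(universe)
  out <- list()
  for (kin in sort(unique(ann$kinase))) {
    kin_sites <- unique(ann$site_id[ann$kinase == kin])
    n_kin <- length(kin_sites)
    for (cl in sort(unique(labels$cluster))) {
      cl_sites <- labels$site_id[labels$cluster == cl]
      a <- length(intersect(cl_sites, kin_sites))
      b <- length(cl_sites) - a
      cc <- n_kin - a
      dd <- n_univ - length(cl_sites) - cc
      rec <- enrichment_record(a, b, cc, dd)
      out[[paste(kin, cl)]] <- bind_cols(tibble(cluster = cl, kinase = kin), rec)
    }
  }
  res <- bind_rows(out) %>%
    mutate(pass = .data$enrichment_factor > 1 &
      .data$a >= min_sites & .data$p < alpha) %>%
    group_by(.data$kinase) %>%
    mutate(predominant = .data$pass & .data$p == min(.data$p[.data$pass], Inf)) %>%
    ungroup()
  res
}

kinase_annotation_long <- function(x) {
  if ("kinase" %in% names(x)) {
    return(x[!is.na(x$kinase) & x$kinase != "", c("site_id", "kinase")])
  }
  if (!"kinases" %in% names(x)) {
    abort("kinase annotations need a `kinase` or `kinases` column",
      class = "optophos_validation_error"
    )
  }
  x %>%
    select("site_id", "kinases") %>%
    filter(!is.na(.data$kinases), .data$kinases != "") %>%
    mutate(kinase = strsplit(.data$kinases, ";", fixed = TRUE)) %>%
    tidyr::unnest("kinase") %>%
    select("site_id", "kinase")
}
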