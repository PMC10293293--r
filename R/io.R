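# Tab-separated readers/writers for the three study tables. Missing values
# are written as "NA"; empty cells and "NA" are both read back as missing.

#' Read and write the wide quantification matrix
#'
#' The quantification matrix is a wide TSV: first column `site_id`, one column
#' per sample, cells are log2 intensities with `NA` (or empty) marking missing
#' values. `write_quant_matrix()` followed by `read_quant_matrix()`
#' round-trips values bit-exactly (missing preserved).
#'
#' @param path File path.
#' @return `read_quant_matrix()`: a tibble with `site_id` and numeric sample
#'   columns.
#' @export
read_quant_matrix <- function(path) {
  qm <- readr::read_tsv(path,
    na = c("", "NA"), show_col_types = FALSE, progress = FALSE
  )
  if (names(qm)[1] != "site_id") names(qm)[1] <- "site_id"
  check_quant_matrix(qm, where = path)
  qm
}

#' @rdname read_quant_matrix
#' @param quant Wide quantification tibble.
#' @export
write_quant_matrix <- function(quant, path) {
  check_quant_matrix(quant)
  readr::write_tsv(quant, path, na = "NA", progress = FALSE)
  invisible(path)
}

check_quant_matrix <- function(quant, where = "quant matrix") {
  dup <- quant$site_id[duplicated(quant$site_id)]
  if (length(dup)) {
    abort(
      sprintf("%s: duplicated site_id: %s", where, paste(unique(dup), collapse = ", ")),
      class = "optophos_parse_error"
    )
  }
  dupc <- names(quant)[duplicated(names(quant))]
  if (length(dupc)) {
    abort(
      sprintf("%s: duplicated sample column: %s", where, paste(unique(dupc), collapse = ", ")),
      class = "optophos_parse_error"
    )
  }
  bad <- names(quant)[-1][!vapply(quant[-1], is.numeric, logical(1))]
  if (length(bad)) {
    abort(
      sprintf("%s: non-numeric sample column: %s", where, paste(bad, collapse = ", ")),
      class = "optophos_parse_error"
    )
  }
  inf <- vapply(quant[-1], function(x) any(is.infinite(x)), logical(1))
  if (any(inf)) {
    abort(
      sprintf("%s: non-finite values in column %s", where, paste(names(which(inf)), collapse = ", ")),
      class = "optophos_parse_error"
    )
  }
  invisible(quant)
}

#' Read and write the study-design table
#'
#' Columns: `sample_id`, `intensity` (`005`/`010`/`025`/`none`), `pattern`
#' (`Su`/`Pe`/`Pu`/`none`), `time_min`, `replicate`, `stimulus`
#' (`light`/`dark`/`growth_factor`).
#'
#' @param path File path.
#' @export
read_study_design <- function(path) {
  d <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = "c", intensity = "c", pattern = "c",
      time_min = "d", replicate = "i", stimulus = "c"
    ),
    na = "", progress = FALSE
  )
  check_study_design(d)
  d
}

#' @rdname read_study_design
#' @param design Study-design tibble.
#' @export
write_study_design <- function(design, path) {
  readr::write_tsv(design, path, na = "NA", progress = FALSE)
  invisible(path)
}

check_study_design <- function(design) {
  req <- c("sample_id", "intensity", "pattern", "time_min", "replicate", "stimulus")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(paste0("design is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "optophos_parse_error"
    )
  }
  key <- paste(condition_id(design), design$replicate)
  if (anyDuplicated(key)) {
    abort("design has duplicated (condition, replicate) pairs",
      class = "optophos_parse_error"
    )
  }
  invisible(design)
}

#' Read and write the site-annotation table
#'
#' Columns: `site_id`, `protein`, `position`, `residue`, `flank15` (+/-7
#' residue window, `_`-padded, phosphoacceptor at the centre), `kinases`
#' (`;`-separated annotations) and logical benchmark-list flags.
#'
#' @param path File path.
#' @export
read_site_annotations <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_site_annotations
#' @param annotations Site-annotation tibble.
#' @export
write_site_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Long-format view of a wide quantification matrix
#'
#' @param quant Wide quantification tibble.
#' @return Tibble with `site_id`, `sample_id`, `log2_intensity`.
#' @export
quant_long <- function(quant) {
  tidyr::pivot_longer(quant, -"site_id",
    names_to = "sample_id", values_to = "log2_intensity"
  )
}

#' Replicate-averaged condition-level matrix
#'
#' Averages replicate samples per condition, ignoring missing values
#' (a condition mean over only-missing replicates stays missing). Output
#' columns follow the canonical condition order (dark first, then light
#' conditions by intensity, pattern and time, then the growth-factor series).
#'
#' @param quant Wide quantification tibble.
#' @param design Study-design tibble covering every sample column of `quant`.
#' @return Tibble `site_id` + one numeric column per condition.
#' @export
condition_means <- function(quant, design) {
  samples <- setdiff(names(quant), "site_id")
  unknown <- setdiff(samples, design$sample_id)
  if (length(unknown)) {
    abort(
      paste0("samples absent from design: ", paste(unknown, collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  design <- design[match(samples, design$sample_id), ]
  conds <- condition_id(design)
  order <- canonical_conditions(design)
  vals <- as.matrix(quant[, samples, drop = FALSE])
  out <- vapply(order, function(cn) {
    m <- rowMeans(vals[, conds == cn, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(vals)))
  if (nrow(quant) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, order))
  bind_cols(tibble(site_id = quant$site_id), as_tibble(out))
}

#' Per-site linear fold change between two conditions
#'
#' @param cond_means Condition-level matrix from [condition_means()].
#' @param condition,reference Condition column names.
#' @return Tibble `site_id`, `fold_change` (`2^(log2 cond - log2 ref)`);
#'   missing values propagate.
#' @export
fold_change <- function(cond_means, condition, reference = "dark") {
  for (cn in c(condition, reference)) {
    if (!cn %in% names(cond_means)) {
      abort(paste0("unknown condition: ", cn), class = "optophos_validation_error")
    }
  }
  tibble(
    site_id = cond_means$site_id,
    fold_change = 2^(cond_means[[condition]] - cond_means[[reference]])
  )
}
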