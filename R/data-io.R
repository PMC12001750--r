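# Data model and I/O: amplicon panels, count matrices, cohort metadata,
# protein panels and well-level mutation read tables. Counts travel as TSV
# (samples as rows), metadata as CSV; "." or the empty string mean missing.

ACROCENTRIC_SHORT_ARMS <- c("13p", "14p", "15p", "21p", "22p")

#' Construct and validate an amplicon panel
#'
#' An amplicon panel describes the loci of a repeated-element amplicon assay:
#' one row per amplicon with its chromosome, chromosome arm (e.g. `"1p"`,
#' `"8q"`), a 1-based start coordinate and the expected insert length in bp.
#' The insert length is what links an amplicon to cfDNA fragment length:
#' short-insert amplicons are preferentially amplifiable from highly
#' fragmented DNA.
#'
#' @param x Data frame with columns `amplicon_id`, `chrom`, `arm`, `start`,
#'   `insert_length`.
#' @param drop_acrocentric_p Drop the acrocentric short arms (13p, 14p, 15p,
#'   21p, 22p), which carry no usable loci. Default `TRUE`.
#' @return A tibble of class `amplicon_panel`.
#' @export
amplicon_panel <- function(x, drop_acrocentric_p = TRUE) {
  required <- c("amplicon_id", "chrom", "arm", "start", "insert_length")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[required]
  x$amplicon_id <- as.character(x$amplicon_id)
  x$arm <- as.character(x$arm)
  if (anyDuplicated(x$amplicon_id)) abort("duplicate amplicon_id in panel")
  if (any(!is.finite(x$insert_length)) || any(x$insert_length <= 0)) {
    abort("insert_length must be a positive number for every amplicon")
  }
  if (!all(grepl("^(chr)?[0-9XY]+[pq]$", x$arm))) {
    abort("arm labels must look like '<chrom><p|q>', e.g. '1p', '8q'")
  }
  if (drop_acrocentric_p) {
    x <- x[!(x$arm %in% ACROCENTRIC_SHORT_ARMS), ]
  }
  class(x) <- c("amplicon_panel", class(tibble::tibble()))
  x
}

#' Construct and validate a count matrix
#'
#' Bundles an integer samples-by-amplicons read-count matrix with per-sample
#' batch labels. Every amplicon must be described by the companion
#' [amplicon_panel()].
#'
#' @param counts Non-negative integer matrix, samples in rows, amplicons in
#'   columns; dimnames required.
#' @param batch Character vector of per-sample batch labels, recycled if
#'   length 1.
#' @param panel An `amplicon_panel` covering every column.
#' @return A `count_matrix` object (list with elements `counts` and `batch`).
#' @export
count_matrix <- function(counts, batch = "batch1", panel = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry sample_ids (rownames) and amplicon_ids (colnames)")
  }
  if (any(counts < 0)) abort("negative read counts are not allowed")
  if (any(counts != round(counts))) abort("read counts must be integers")
  storage.mode(counts) <- "double"  # keeps >2^31 totals safe; values stay integral
  batch <- rep_len(as.character(batch), nrow(counts))
  names(batch) <- rownames(counts)
  if (!is.null(panel)) {
    extra <- setdiff(colnames(counts), panel$amplicon_id)
    if (length(extra) > 0) {
      abort(paste0("amplicons absent from panel: ", paste(head(extra, 5), collapse = ", ")))
    }
  }
  structure(list(counts = counts, batch = batch), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d samples x %d amplicons, %d batch(es)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$batch))
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.count_matrix <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "sample_id") |>
    tibble::add_column(batch = unname(x$batch), .after = "sample_id")
}

na_like <- function(x) x %in% c("", ".", "na", "n/a", "not available", "missing")

normalize_enum <- function(x, levels, field) {
  raw <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(raw))
  miss <- is.na(raw) | na_like(raw)
  key <- names(levels) %||% levels
  idx <- match(raw[!miss], key)
  if (anyNA(idx)) {
    bad <- unique(raw[!miss][is.na(idx)])
    abort(paste0("unknown ", field, " value(s): ", paste(bad, collapse = ", ")))
  }
  out[!miss] <- unname(levels)[idx]
  out
}

#' Read a count matrix and its amplicon panel
#'
#' The counts file is a TSV with one row per sample: columns `sample_id`,
#' `batch`, then one integer column per amplicon. The panel file is a TSV
#' with columns `amplicon_id`, `chrom`, `arm`, `start`, `insert_length`.
#' Amplicons present in the matrix but absent from the panel are an error.
#'
#' @param path Path to the counts TSV.
#' @param panel_path Path to the panel TSV.
#' @return A list with elements `counts` (a [count_matrix()]) and `panel`
#'   (an [amplicon_panel()]).
#' @export
read_counts <- function(path, panel_path) {
  if (!file.exists(path)) abort(paste0("counts file not found: ", path))
  if (!file.exists(panel_path)) abort(paste0("panel file not found: ", panel_path))
  panel <- amplicon_panel(
    readr::read_tsv(panel_path, show_col_types = FALSE, progress = FALSE),
    drop_acrocentric_p = FALSE
  )
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "batch") %in% names(tab))) {
    abort("counts TSV must start with sample_id and batch columns")
  }
  amp_cols <- setdiff(names(tab), c("sample_id", "batch"))
  m <- as.matrix(tab[amp_cols])
  if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0)) {
    abort("counts must be non-negative integers")
  }
  rownames(m) <- tab$sample_id
  cm <- count_matrix(m, batch = tab$batch, panel = panel)
  list(counts = cm, panel = panel)
}

#' Write a count matrix and panel to TSV
#'
#' @param x A `count_matrix`.
#' @param panel The companion `amplicon_panel`.
#' @param path,panel_path Output TSV paths.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(x, panel, path, panel_path = NULL) {
  readr::write_tsv(as_tibble.count_matrix(x), path, progress = FALSE)
  if (!is.null(panel_path)) {
    readr::write_tsv(tibble::as_tibble(unclass(panel)), panel_path, progress = FALSE)
  }
  invisible(path)
}

#' Read per-sample cohort metadata
#'
#' Expects a CSV with columns `sample_id`, `group` and, for adenoma cases,
#' `size_cm` (maximum dimension, cm), `histology`, `dysplasia` and
#' `location`. Enumerated fields are normalized case-insensitively
#' ("Villous adenoma" becomes `villous`, "High grade/severe" becomes
#' `high`); "Not available", "." or an empty string become `NA`.
#'
#' @param path Path to the cohort CSV.
#' @return A validated tibble of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort_table(tab)
}

#' @rdname read_cohort
#' @param x A data frame laid out like the cohort CSV.
#' @export
as_cohort_table <- function(x) {
  if (!all(c("sample_id", "group") %in% names(x))) {
    abort("cohort table needs sample_id and group columns")
  }
  x <- tibble::as_tibble(x)
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in cohort table")
  x$group <- normalize_enum(x$group, c(
    case = "case", control = "control", cancer = "cancer",
    non_cancer = "non_cancer", "non-cancer" = "non_cancer"
  ), "group")
  if (anyNA(x$group)) abort("group must be present for every sample")
  if (!"size_cm" %in% names(x)) x$size_cm <- NA_real_
  x$size_cm <- suppressWarnings(as.numeric(ifelse(na_like(tolower(as.character(x$size_cm))),
                                                  NA, x$size_cm)))
  if (!"histology" %in% names(x)) x$histology <- NA_character_
  x$histology <- normalize_enum(
    sub("\\s+adenoma$", "", trimws(tolower(as.character(x$histology)))),
    c(tubular = "tubular", tubulovillous = "tubulovillous",
      villous = "villous", serrated = "serrated"),
    "histology"
  )
  if (!"dysplasia" %in% names(x)) x$dysplasia <- NA_character_
  x$dysplasia <- normalize_enum(x$dysplasia, c(
    low = "low", high = "high", "high grade/severe" = "high",
    "high grade" = "high", severe = "high", "low grade" = "low"
  ), "dysplasia")
  if (!"location" %in% names(x)) x$location <- NA_character_
  x$location <- normalize_enum(x$location, c(
    cecum = "cecum", "ascending colon" = "ascending colon",
    "hepatic flexure" = "hepatic flexure", "transverse colon" = "transverse colon",
    "descending colon" = "descending colon", "sigmoid colon" = "sigmoid colon",
    rectum = "rectum"
  ), "location")
  is_case <- x$group == "case"
  if (any(is_case & (is.na(x$size_cm) | is.na(x$histology)))) {
    abort("size_cm and histology must be present for every case")
  }
  if (any(!is.na(x$size_cm) & x$size_cm <= 0)) abort("size_cm must be positive")
  class(x) <- c("cohort_table", class(tibble::tibble()))
  x
}

#' Read a 17-analyte plasma protein table
#'
#' Expects a CSV with `sample_id` plus the 17 analyte columns named as in
#' [protein17_analytes()] (any column order; matching is case-insensitive).
#' Concentrations must be non-negative; `.` or empty means missing.
#'
#' @param path Path to the proteins CSV.
#' @return A validated tibble of class `protein_table` with analytes in
#'   canonical order.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) abort(paste0("protein file not found: ", path))
  as_protein_table(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_proteins
#' @param x A data frame with `sample_id` and the 17 analyte columns.
#' @export
as_protein_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) abort("protein table needs a sample_id column")
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in protein table")
  idx <- match(toupper(PROTEIN17_ANALYTES), toupper(names(x)))
  if (anyNA(idx)) {
    abort(paste0("missing analyte column(s): ",
                 paste(PROTEIN17_ANALYTES[is.na(idx)], collapse = ", ")))
  }
  out <- x[c(match("sample_id", names(x)), idx)]
  names(out) <- c("sample_id", PROTEIN17_ANALYTES)
  for (a in PROTEIN17_ANALYTES) {
    v <- out[[a]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(na_like(tolower(v)), NA, v)))
    if (any(v < 0, na.rm = TRUE)) abort(paste0("negative concentration in ", a))
    out[[a]] <- as.numeric(v)
  }
  class(out) <- c("protein_table", class(tibble::tibble()))
  out
}

#' Read a multi-well mutation read table
#'
#' One row per (sample, mutation, well): the mutant and total template reads
#' observed in that well of the partitioned assay, and whether the variant
#' is a target mutation (identified in the patient's adenoma tissue) or a
#' non-target variant used for background-noise modelling.
#'
#' @param path Path to the wells TSV with columns `sample_id`,
#'   `mutation_id`, `well_index`, `mutant_reads`, `total_reads`,
#'   `is_target`.
#' @return A validated tibble of class `well_table`.
#' @export
read_wells <- function(path) {
  if (!file.exists(path)) abort(paste0("wells file not found: ", path))
  as_well_table(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_wells
#' @param x A data frame laid out like the wells TSV.
#' @export
as_well_table <- function(x) {
  required <- c("sample_id", "mutation_id", "well_index", "mutant_reads",
                "total_reads", "is_target")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("well table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[required]
  x$is_target <- as.logical(x$is_target)
  for (col in c("well_index", "mutant_reads", "total_reads")) {
    if (any(x[[col]] != round(x[[col]]) | x[[col]] < 0)) {
      abort(paste0(col, " must be a non-negative integer"))
    }
  }
  if (any(x$mutant_reads > x$total_reads)) {
    abort("mutant_reads exceeds total_reads")
  }
  dup <- duplicated(x[c("sample_id", "mutation_id", "well_index")])
  if (any(dup)) abort("well_index must be unique within (sample_id, mutation_id)")
  class(x) <- c("well_table", class(tibble::tibble()))
  x
}

#' Packaged study fixtures
#'
#' `study_cases()` returns the published per-case table of the advanced
#' adenoma study: 40 cases with adenoma location, dysplasia grade, maximum
#' size, histologic type and the three assay scores (fragmentation, global
#' aneuploidy, protein-17).
#'
#' `study_controls()` returns a *synthetic* 32-row control score table. The
#' per-control scores were never published; this stand-in reproduces the
#' published control positivity counts at the study thresholds (0 of 32
#' fragmentation-positive, 0 of 32 protein-positive, 2 of 32
#' aneuploidy-positive) so specificity columns can be recomputed.
#'
#' @return A tibble; `study_cases()` also carries the `cohort_table` class.
#' @export
study_cases <- function() {
  path <- system.file("extdata", "table2_cases.csv", package = "adenoscreen")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  scores <- tab[c("sample_id", "signal_score", "gas_score", "protein17_score")]
  out <- as_cohort_table(tab[setdiff(names(tab), names(scores)[-1])])
  dplyr::left_join(out, scores, by = "sample_id")
}

#' @rdname study_cases
#' @export
study_controls <- function() {
  path <- system.file("extdata", "synthetic_controls_scores.csv", package = "adenoscreen")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
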