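#' @importFrom rlang .data abort warn
#' @importFrom stats cor cor.test lm median pnorm predict qnorm quantile
#'   resid rnorm runif sd setNames rbinom p.adjust plogis chisq.test
#'   kruskal.test wilcox.test t.test coef complete.cases
#' @importFrom utils head
NULL

METRICS <- c("volume", "area", "thickness", "fa", "adc")
ANAT_METRICS <- c("volume", "area", "thickness")
DIFF_METRICS <- c("fa", "adc")
TISSUES <- c("cortical_gm", "subcortical_gm", "wm", "other")
HEMISPHERES <- c("left", "right", "midline")

#' Region metadata table
#'
#' Builds the per-region metadata used to tag metric-table columns with a
#' hemisphere and a tissue class. Tissue drives the expected direction of
#' maturation effects (e.g. FA rises with age in white matter and
#' subcortical grey matter).
#'
#' @param name Character vector of unique region labels.
#' @param hemisphere One of `"left"`, `"right"`, `"midline"` per region
#'   (recycled if length 1).
#' @param tissue One of `"cortical_gm"`, `"subcortical_gm"`, `"wm"`,
#'   `"other"` per region (recycled if length 1).
#' @return A tibble with columns `name`, `hemisphere`, `tissue`.
#' @export
region_info <- function(name, hemisphere = "left", tissue = "cortical_gm") {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    abort("region names must be unique within a table")
  }
  hemisphere <- vctrs_recycle(as.character(hemisphere), length(name), "hemisphere")
  tissue <- vctrs_recycle(as.character(tissue), length(name), "tissue")
  if (!all(hemisphere %in% HEMISPHERES)) {
    abort(paste0("hemisphere must be one of: ", paste(HEMISPHERES, collapse = ", ")))
  }
  if (!all(tissue %in% TISSUES)) {
    abort(paste0("tissue must be one of: ", paste(TISSUES, collapse = ", ")))
  }
  tibble::tibble(name = name, hemisphere = hemisphere, tissue = tissue)
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) abort(sprintf("`%s` must have length 1 or %d", what, n))
  x
}

#' Construct a regional metric table
#'
#' A metric table is a tibble of one brain metric (participants in rows,
#' named regions in columns) carrying the metric name and per-region
#' metadata as attributes. The first column, `id`, holds participant ids.
#'
#' @param values A data frame / tibble whose first column is the participant
#'   id and whose remaining columns are numeric regional values.
#' @param metric One of `"volume"`, `"area"`, `"thickness"` (cortical
#'   anatomy, 68 regions in the default atlas), `"fa"`, `"adc"` (diffusion,
#'   176 regions).
#' @param regions Optional region metadata as produced by [region_info()];
#'   defaults to cortical grey matter for anatomical metrics and unlabelled
#'   (`"other"`) tissue for diffusion metrics.
#' @return A `metric_table` tibble.
#' @export
metric_table <- function(values, metric, regions = NULL) {
  metric <- match.arg(metric, METRICS)
  values <- tibble::as_tibble(values)
  if (ncol(values) < 2L) abort("a metric table needs an id column and at least one region")
  names(values)[1] <- "id"
  values$id <- as.character(values$id)
  if (anyDuplicated(values$id)) {
    abort(paste0("duplicated participant id(s): ",
                 paste(unique(values$id[duplicated(values$id)]), collapse = ", ")))
  }
  region_names <- names(values)[-1]
  for (j in seq_along(region_names)) {
    col <- values[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      abort(sprintf("non-numeric value in column '%s'%s", region_names[j],
                    if (length(bad)) sprintf(" (row %d)", bad[1]) else ""))
    }
  }
  if (is.null(regions)) {
    default_tissue <- if (metric %in% ANAT_METRICS) "cortical_gm" else "other"
    regions <- region_info(region_names, hemisphere = "midline", tissue = default_tissue)
  } else {
    regions <- tibble::as_tibble(regions)
    if (!all(c("name", "hemisphere", "tissue") %in% names(regions))) {
      abort("`regions` needs columns name, hemisphere, tissue")
    }
    missing_meta <- setdiff(region_names, regions$name)
    if (length(missing_meta)) {
      abort(paste0("regions missing from metadata: ",
                   paste(head(missing_meta, 5), collapse = ", ")))
    }
    regions <- regions[match(region_names, regions$name), c("name", "hemisphere", "tissue")]
  }
  if (metric == "fa") {
    vals <- as.matrix(values[-1])
    if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
      warn("FA values outside [0, 1] found; values kept as-is")
    }
  }
  structure(values,
            metric = metric,
            regions = regions,
            class = c("metric_table", class(values)))
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> metric = %s, %d participants x %d regions\n",
              attr(x, "metric"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

table_metric <- function(x) attr(x, "metric", exact = TRUE)
table_regions <- function(x) attr(x, "regions", exact = TRUE)
table_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$id
  m
}

#' Read a regional metric table from CSV
#'
#' Expects a header of region names with the participant id in the first
#' column; empty cells become missing values. FA values outside `[0, 1]`
#' raise a warning but are kept.
#'
#' @param path Path to the CSV file.
#' @param metric Metric name (see [metric_table()]).
#' @param region_metadata Optional path to a region metadata CSV with
#'   columns `name,hemisphere,tissue`.
#' @return A `metric_table`.
#' @export
read_metric_table <- function(path, metric, region_metadata = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2L) abort("metric CSV needs an id column plus region columns")
  out <- raw
  for (j in 2:ncol(raw)) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "")
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    col[bad[1]], bad[1], names(raw)[j], path))
    }
    out[[j]] <- num
  }
  regions <- if (!is.null(region_metadata)) read_region_metadata(region_metadata) else NULL
  metric_table(out, metric = metric, regions = regions)
}

#' Write a regional metric table to CSV
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces the table bit-identically.
#'
#' @param x A `metric_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass_table(x)), path, na = "")
  invisible(path)
}

unclass_table <- function(x) {
  class(x) <- setdiff(class(x), "metric_table")
  x
}

#' Read region metadata (`name,hemisphere,tissue`) from CSV
#' @param path CSV path.
#' @return A region metadata tibble.
#' @export
read_region_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("name", "hemisphere", "tissue") %in% names(meta))) {
    abort("region metadata CSV needs columns name, hemisphere, tissue")
  }
  region_info(meta$name, meta$hemisphere, meta$tissue)
}

#' Read a phenotype table
#'
#' Required columns: `id`, `group` (TDC/ASD), `age` (years), `sex` (M/F).
#' Optional: `iq_verbal`, `iq_nonverbal`, `iq_total`, `ados_css` (ordinal
#' 1-10), `motion` (RMS displacement, mm). Empty cells are read as missing
#' values, never as zero.
#'
#' @param path CSV path.
#' @param age_range Permitted chronological age range in years.
#' @return A tibble of participant records.
#' @export
read_phenotypes <- function(path, age_range = c(1, 120)) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("id", "group", "age", "sex")
  miss <- setdiff(required, names(raw))
  if (length(miss)) abort(paste0("phenotype CSV missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  n <- nrow(raw)
  num_col <- function(name) {
    if (!name %in% names(raw)) return(rep(NA_real_, n))
    col <- raw[[name]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "")
    if (length(bad)) abort(sprintf("unparsable value '%s' in column '%s' row %d",
                                   col[bad[1]], name, bad[1]))
    num
  }
  age <- num_col("age")
  if (anyNA(age)) abort("age is required for every participant")
  phenotypes <- tibble::tibble(
    id = as.character(raw$id),
    group = raw$group,
    age = age,
    sex = raw$sex,
    iq_verbal = num_col("iq_verbal"),
    iq_nonverbal = num_col("iq_nonverbal"),
    iq_total = num_col("iq_total"),
    ados_css = num_col("ados_css"),
    motion = num_col("motion")
  )
  validate_phenotypes(phenotypes, age_range = age_range)
}

validate_phenotypes <- function(phenotypes, age_range = c(1, 120)) {
  if (anyDuplicated(phenotypes$id)) abort("duplicated participant id in phenotypes")
  if (!all(phenotypes$group %in% c("TDC", "ASD"))) {
    abort("group must be 'TDC' or 'ASD'")
  }
  if (!all(phenotypes$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'")
  if (any(phenotypes$age <= 0) ||
      any(phenotypes$age < age_range[1] | phenotypes$age > age_range[2])) {
    abort(sprintf("age outside the study range [%g, %g]", age_range[1], age_range[2]))
  }
  css <- phenotypes$ados_css
  ok <- is.na(css) | (css == round(css) & css >= 1 & css <= 10)
  if (!all(ok)) abort("ados_css must be an integer in 1..10 when present")
  phenotypes
}

#' Write a phenotype table to CSV
#' @param phenotypes A phenotype tibble (see [read_phenotypes()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path, na = "")
  invisible(path)
}

#' Align phenotype records and metric tables into a cohort
#'
#' Restricts the cohort to the participants present in the phenotype table
#' and in every *required* metric table, mirroring the usual
#' complete-modality analysis set (e.g. a combined anatomical+diffusion
#' model can only use participants with both modalities). Availability
#' counts per modality and for the intersection are stored on the result.
#'
#' @param phenotypes Participant records (tibble from [read_phenotypes()]).
#' @param tables Named list of `metric_table`s; names are metric names.
#' @param required_metrics Metrics the cohort must jointly cover; defaults
#'   to all supplied tables.
#' @return A `ddi_cohort`: list with elements `phenotypes` (tibble) and
#'   `tables` (the required metric tables, row-restricted), with an
#'   `availability` attribute.
#' @export
align_cohort <- function(phenotypes, tables, required_metrics = names(tables)) {
  if (length(tables) == 0L) abort("at least one metric table is required")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- vapply(tables, table_metric, character(1))
  }
  bad <- setdiff(required_metrics, names(tables))
  if (length(bad)) abort(paste0("required metric(s) not supplied: ", paste(bad, collapse = ", ")))
  phenotypes <- validate_phenotypes(tibble::as_tibble(phenotypes))

  availability <- purrr::imap(tables, function(tab, metric) {
    tibble::tibble(metric = metric, n_available = length(intersect(phenotypes$id, tab$id)))
  }) |> purrr::list_rbind()

  keep <- phenotypes$id
  for (m in required_metrics) keep <- intersect(keep, tables[[m]]$id)
  if (length(keep) == 0L) abort("no participant has all required metrics")

  tables_out <- purrr::map(tables[required_metrics], function(tab) {
    sub <- tab[match(keep, tab$id), , drop = FALSE]
    metric_table(tibble::as_tibble(unclass_table(sub)),
                 metric = table_metric(tab), regions = table_regions(tab))
  })
  structure(
    list(phenotypes = phenotypes[match(keep, phenotypes$id), , drop = FALSE],
         tables = tables_out),
    availability = availability,
    n_intersection = length(keep),
    class = "ddi_cohort"
  )
}

#' @export
print.ddi_cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf("<ddi_cohort> %d participants (%d TDC, %d ASD), metrics: %s\n",
              nrow(ph), sum(ph$group == "TDC"), sum(ph$group == "ASD"),
              paste(names(x$tables), collapse = ", ")))
  av <- attr(x, "availability")
  if (!is.null(av)) {
    cat("availability before alignment:\n")
    for (i in seq_len(nrow(av))) cat(sprintf("  %s: %d\n", av$metric[i], av$n_available[i]))
  }
  invisible(x)
}

#' Modality availability counts recorded during alignment
#' @param cohort A `ddi_cohort`.
#' @return Tibble of per-metric available counts plus the intersection size.
#' @export
cohort_availability <- function(cohort) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  av <- attr(cohort, "availability")
  dplyr::bind_rows(av, tibble::tibble(metric = "(intersection)",
                                      n_available = attr(cohort, "n_intersection")))
}

#' Restrict a cohort to one diagnostic group
#' @param cohort A `ddi_cohort`.
#' @param group `"TDC"` or `"ASD"`.
#' @return A `ddi_cohort` with only that group's participants.
#' @export
cohort_subset <- function(cohort, group) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  group <- match.arg(group, c("TDC", "ASD"))
  keep <- cohort$phenotypes$id[cohort$phenotypes$group == group]
  if (!length(keep)) abort(sprintf("no %s participants in cohort", group))
  tables <- purrr::map(cohort$tables, function(tab) {
    sub <- tab[tab$id %in% keep, , drop = FALSE]
    metric_table(tibble::as_tibble(unclass_table(sub)),
                 metric = table_metric(tab), regions = table_regions(tab))
  })
  structure(list(phenotypes = cohort$phenotypes[cohort$phenotypes$id %in% keep, , drop = FALSE],
                 tables = tables),
            class = "ddi_cohort")
}
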