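#' Construct a TMB cohort
#'
#' A cohort is a tibble of per-sample tumor mutational burden (TMB)
#' measurements with one row per sample. Mandatory columns are `sample_id`,
#' `histology` and `tmb_wes` (whole-exome TMB in mutations/Mb); optional
#' columns are `tmb_panel` (panel TMB in mutations/Mb) and `response`
#' (binary treatment response, 0/1).
#'
#' @param df data frame with at least `sample_id`, `histology`, `tmb_wes`.
#' @param provenance free-text source tag (e.g. a file path or `"synthetic"`).
#' @return A tibble of class `tmb_cohort` with a `provenance` attribute.
#' @export
tmb_cohort <- function(df, provenance = "unspecified") {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "histology", "tmb_wes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"tmb_panel" %in% names(df)) df$tmb_panel <- NA_real_
  if (!"response" %in% names(df)) df$response <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df$histology <- as.character(df$histology)
  df$tmb_wes <- as.numeric(df$tmb_wes)
  df$tmb_panel <- as.numeric(df$tmb_panel)
  df$response <- as.integer(df$response)
  df <- df[, c("sample_id", "histology", "tmb_wes", "tmb_panel", "response")]
  validate_tmb_cohort(df)
  structure(df, class = c("tmb_cohort", class(tibble::tibble())),
            provenance = provenance)
}

#' Validate a cohort table
#'
#' Checks the cohort invariants: unique sample ids, non-empty histology
#' labels, nonnegative TMB values, and `response` in \{0, 1, NA\}. Offending
#' rows are named in the error message.
#'
#' @param df data frame with cohort columns.
#' @return Invisibly `TRUE` if all checks pass; otherwise an error.
#' @export
validate_tmb_cohort <- function(df) {
  fail <- function(rows, what) {
    stop("cohort validation error: ", what, " (row ",
         paste(utils::head(rows, 10), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(TRUE))
  dup <- which(duplicated(df$sample_id))
  if (length(dup) > 0) fail(dup, "duplicate sample_id")
  bad_hist <- which(is.na(df$histology) | !nzchar(df$histology))
  if (length(bad_hist) > 0) fail(bad_hist, "empty histology")
  bad_wes <- which(!is.finite(df$tmb_wes) | df$tmb_wes < 0)
  if (length(bad_wes) > 0) fail(bad_wes, "tmb_wes missing or negative")
  bad_panel <- which(!is.na(df$tmb_panel) & df$tmb_panel < 0)
  if (length(bad_panel) > 0) fail(bad_panel, "negative tmb_panel")
  bad_resp <- which(!is.na(df$response) & !df$response %in% c(0L, 1L))
  if (length(bad_resp) > 0) fail(bad_resp, "response not in {0, 1}")
  invisible(TRUE)
}

#' Read a cohort TMB table from CSV or TSV
#'
#' The file must have a header with at least the columns `sample_id`,
#' `histology` and `tmb_wes`; `tmb_panel` and `response` are recognised when
#' present. A `col_map` renames non-standard headers to the canonical schema
#' before validation, so supplementary tables with their own column names can
#' be ingested without rewriting the file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(tmb_wes = "WES_TMB")`.
#' @return A [tmb_cohort] with `provenance` set to `path`.
#' @export
read_tmb_table <- function(path, format = c("auto", "csv", "tsv"),
                           col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  tmb_cohort(df, provenance = path)
}

#' Write a cohort TMB table to CSV or TSV
#'
#' @param cohort a [tmb_cohort] or compatible data frame.
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_tmb_table <- function(cohort, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Preset parameters for synthetic histology-specific TMB distributions, in
# mutations/Mb. Lognormal (mixture) components were chosen once to emulate
# the shapes of TCGA cohorts: LUAD-like is a bimodal mixture with a heavy
# tail (never-smoker low mode, smoker high mode plus hypermutators),
# LUSC-like is unimodal with a high median, low-TMB-like matches
# BRCA/PRAD-scale burdens, and NSCLC-like is an even LUAD/LUSC blend.
.tmb_presets <- list(
  luad_like = list(kind = "lnorm_mix",
                   weight = c(0.35, 0.65),
                   meanlog = log(c(2.5, 9.0)),
                   sdlog = c(0.65, 0.75),
                   histology = "LUAD", median_band = c(5.0, 8.0)),
  lusc_like = list(kind = "lnorm_mix",
                   weight = 1, meanlog = log(9.5), sdlog = 0.55,
                   histology = "LUSC", median_band = c(8.8, 10.2)),
  low_tmb_like = list(kind = "lnorm_mix",
                      weight = 1, meanlog = log(1.3), sdlog = 0.8,
                      histology = "BRCA", median_band = c(1.2, 1.4)),
  nsclc_like = list(kind = "lnorm_mix",
                    weight = c(0.175, 0.325, 0.5),
                    meanlog = log(c(2.5, 9.0, 9.5)),
                    sdlog = c(0.65, 0.75, 0.55),
                    histology = "NSCLC", median_band = c(7.5, 10.0)),
  uniform = list(kind = "uniform", min = 0, max = 20,
                 histology = "UNIF", median_band = c(9.5, 10.5))
)

#' Parameters of a synthetic cohort preset
#'
#' @param preset one of `"luad_like"`, `"lusc_like"`, `"low_tmb_like"`,
#'   `"nsclc_like"`, `"uniform"`.
#' @return Named list of distribution parameters (lognormal-mixture weights,
#'   `meanlog`, `sdlog`, or uniform bounds), the default histology label, and
#'   the documented median band used by reproducibility checks.
#' @export
tmb_preset_params <- function(preset) {
  if (!preset %in% names(.tmb_presets)) {
    stop("unknown preset: ", preset, "; available: ",
         paste(names(.tmb_presets), collapse = ", "), call. = FALSE)
  }
  .tmb_presets[[preset]]
}

#' Generate a synthetic TMB cohort
#'
#' Draws `n` whole-exome TMB values from a documented nonnegative preset
#' distribution (see [tmb_preset_params]). Draws are fully reproducible from
#' `seed`.
#'
#' @param preset preset name; see [tmb_preset_params].
#' @param n number of samples (>= 0).
#' @param seed integer seed.
#' @param histology optional histology label overriding the preset default.
#' @return A [tmb_cohort] with `tmb_wes` filled in.
#' @export
generate_synthetic_cohort <- function(preset, n, seed, histology = NULL) {
  p <- tmb_preset_params(preset)
  stopifnot(n >= 0)
  if (is.null(histology)) histology <- p$histology
  tmb <- withr::with_seed(seed, draw_preset(p, n))
  tmb_cohort(
    tibble::tibble(
      sample_id = if (n > 0) sprintf("%s-%05d", histology, seq_len(n)) else character(0),
      histology = rep(histology, n),
      tmb_wes = tmb
    ),
    provenance = paste0("synthetic:", preset, ":seed=", seed)
  )
}

draw_preset <- function(p, n) {
  if (n == 0) return(numeric(0))
  if (p$kind == "uniform") return(stats::runif(n, p$min, p$max))
  comp <- sample.int(length(p$weight), n, replace = TRUE, prob = p$weight)
  stats::rlnorm(n, meanlog = p$meanlog[comp], sdlog = p$sdlog[comp])
}

#' In-silico panel counts by binomial thinning
#'
#' Emulates intersecting whole-exome mutation calls with a panel's target
#' territory: each of the `exome_count` exome mutations lands on the panel
#' independently with probability `size_ratio` (panel size / exome size), so
#' each replicate is a draw from Binomial(exome_count, size_ratio). This is
#' the brute-force sampling process the Gaussian noise approximation is
#' checked against.
#'
#' @param exome_count nonnegative integer count of exome mutations.
#' @param size_ratio panel-to-exome size ratio in (0, 1].
#' @param seed integer seed.
#' @param replicates number of replicate draws.
#' @return Integer vector of panel mutation counts, length `replicates`.
#' @export
thin_to_panel <- function(exome_count, size_ratio, seed, replicates = 1) {
  if (length(size_ratio) != 1 || size_ratio <= 0 || size_ratio > 1) {
    stop("size_ratio must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(exome_count >= 0, replicates >= 0)
  withr::with_seed(seed,
    stats::rbinom(replicates, size = round(exome_count), prob = size_ratio))
}

#' Add simulated panel measurements to a cohort
#'
#' Fills the `tmb_panel` column with one simulated panel readout per sample,
#' conditional on each sample's `tmb_wes`. `method = "model"` uses the
#' Gaussian + Poisson measurement model ([simulate_panel_tmb]);
#' `method = "thinning"` uses binomial thinning of the exome mutation count
#' ([thin_to_panel]), i.e. the in-silico resampling construction.
#'
#' @param cohort a [tmb_cohort].
#' @param panel a [panel_model].
#' @param seed integer seed.
#' @param method `"model"` or `"thinning"`.
#' @return The cohort with `tmb_panel` replaced by simulated readouts.
#' @export
add_panel_measurements <- function(cohort, panel, seed,
                                   method = c("model", "thinning")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "panel_model"))
  n <- nrow(cohort)
  if (n == 0) return(cohort)
  if (method == "model") {
    readout <- simulate_panel_tmb(panel, cohort$tmb_wes, n_reps = 1, seed = seed)
  } else {
    K <- panel$panel_size_L / panel$exome_size_L0
    counts <- withr::with_seed(seed, stats::rbinom(
      n, size = round(cohort$tmb_wes * panel$exome_size_L0), prob = K))
    readout <- counts / panel$panel_size_L
  }
  cohort$tmb_panel <- as.numeric(readout)
  cohort
}
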