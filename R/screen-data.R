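#' Read an arrayed-screen phenotype table
#'
#' Loads a delimited table with one row per CAR construct: the
#' costimulatory-domain label plus the measured phenotypes. Required columns
#' are `domain_label`, `stemness` (percent IL7Ra+/KLRG1- cells, 0-100), and
#' either `nalm6_survival` (fraction of Nalm 6 target cells surviving the
#' killing assay, 0-1) or a precomputed `cytotoxicity` score. Optional
#' columns `memory_naive_pct` and `replicate_id` are carried through.
#'
#' Rows that fail parsing or range checks are reported with their row
#' numbers.
#'
#' @param path Path to a TSV (default) or CSV file; the delimiter is chosen
#'   from the file extension.
#' @param library A [motif_library()] used to validate domain labels.
#' @return A tibble of screen records.
#' @export
read_screen_table <- function(path, library = motif_library()) {
  if (!file.exists(path)) abort(paste0("screen table not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv
            else readr::read_tsv
  df <- reader(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(df) == 0) abort(paste0("screen table is empty: ", path))
  required <- "domain_label"
  if (!"stemness" %in% names(df)) {
    abort("screen table is missing required column: stemness")
  }
  if (!any(c("nalm6_survival", "cytotoxicity") %in% names(df))) {
    abort("screen table needs a nalm6_survival or cytotoxicity column")
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("screen table is missing required column: ",
                 paste(missing, collapse = ", ")))
  }
  # label validation doubles as a parse check against the library
  parse_domain_label(df$domain_label, library)
  bad <- integer(0)
  if ("nalm6_survival" %in% names(df)) {
    bad <- c(bad, which(!is.finite(df$nalm6_survival)))
  }
  bad <- c(bad, which(!is.finite(df$stemness)))
  if (length(bad) > 0) {
    abort(paste0("non-numeric or missing phenotype values in row(s): ",
                 paste(sort(unique(bad)), collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Write a screen table
#'
#' Writes records as UTF-8 TSV; [read_screen_table()] round-trips the result
#' losslessly.
#'
#' @param records A screen-records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Normalize phenotypes onto their modeling scales
#'
#' Cytotoxicity is defined as `1 - nalm6_survival` (survival first clipped to
#' \[0,1\]): a CAR whose targets all die scores 1, one that spares them all
#' scores 0. Stemness is clipped to \[0,100\] percent. Negative raw inputs
#' are rejected as measurement errors rather than clipped.
#'
#' @param records A screen-records tibble with `nalm6_survival` and/or
#'   `cytotoxicity`, plus `stemness`.
#' @return The tibble with `cytotoxicity` and `stemness` on their modeling
#'   scales.
#' @export
#' @examples
#' normalize_phenotypes(tibble::tibble(
#'   domain_label = "M1", nalm6_survival = 0.25, stemness = 40))
normalize_phenotypes <- function(records) {
  stopifnot(is.data.frame(records))
  if ("nalm6_survival" %in% names(records)) {
    if (any(records$nalm6_survival < 0)) {
      abort(paste0("negative nalm6_survival in row(s): ",
                   paste(which(records$nalm6_survival < 0), collapse = ", ")))
    }
    records$cytotoxicity <- 1 - pmin(records$nalm6_survival, 1)
  }
  if (!"cytotoxicity" %in% names(records)) {
    abort("records need nalm6_survival or cytotoxicity")
  }
  if (any(records$stemness < 0)) {
    abort(paste0("negative stemness in row(s): ",
                 paste(which(records$stemness < 0), collapse = ", ")))
  }
  records$cytotoxicity <- pmin(pmax(records$cytotoxicity, 0), 1)
  records$stemness <- pmin(records$stemness, 100)
  tibble::as_tibble(records)
}

#' Average replicate measurements per construct
#'
#' Constructs measured in replicate are collapsed to one record (mean of each
#' phenotype) before modeling.
#'
#' @param records A normalized screen-records tibble.
#' @return One row per distinct `domain_label`.
#' @export
average_replicates <- function(records) {
  num <- intersect(c("nalm6_survival", "cytotoxicity", "stemness",
                     "memory_naive_pct"), names(records))
  records |>
    dplyr::group_by(.data$domain_label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num), mean), .groups = "drop")
}

#' Split screen records into training and test sets
#'
#' A uniform random split without stratification, deterministic under `seed`.
#' The default sizes mirror an arrayed screen of 246 constructs split into
#' 221 training and 25 withheld test examples.
#'
#' @param records A screen-records tibble.
#' @param n_test Number of test records, `0 <= n_test < nrow(records)`.
#' @param seed Integer seed controlling the draw.
#' @return An object of class `screen_split`: a list with `train`, `test`
#'   (tibbles) and `seed`.
#' @export
split_screen <- function(records, n_test = 25, seed = 1) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n_test < 0 || n_test >= n) {
    abort(paste0("n_test must be in [0, ", n - 1, "], got ", n_test))
  }
  test_idx <- withr::with_seed(seed, sample.int(n, n_test))
  structure(
    list(
      train = records[setdiff(seq_len(n), test_idx), , drop = FALSE],
      test = records[sort(test_idx), , drop = FALSE],
      seed = as.integer(seed)
    ),
    class = "screen_split"
  )
}

#' @export
print.screen_split <- function(x, ...) {
  cat("<screen_split> ", nrow(x$train), " train / ", nrow(x$test),
      " test (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
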