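#' Read an OTU count table
#'
#' Two dialects are supported. `"tsv-wide"`: first column `sample`, one
#' column per OTU, integer counts. `"mothur-shared"`: the classic
#' `.shared` layout with columns `label` (clustering cutoff, e.g. `0.10`
#' for SST 90%), `Group` (sample id), `numOtus`, then the OTU columns;
#' `numOtus` is validated against the actual column count and `label` is
#' converted to the SST percent stored in the `sst` attribute.
#'
#' @param path Path to the table.
#' @param dialect `"tsv-wide"` or `"mothur-shared"`.
#' @return Wide count tibble (`sample` + OTU columns) with attributes
#'   `sst` (may be `NA`) and `dialect`.
#' @export
read_otu_table <- function(path, dialect = c("tsv-wide", "mothur-shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (dialect == "mothur-shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(raw))) {
      abort("mothur-shared table must have columns label, Group, numOtus")
    }
    otu_cols <- setdiff(names(raw), need)
    if (any(raw$numOtus != length(otu_cols))) {
      abort(paste0("numOtus (", raw$numOtus[1], ") does not match the ",
                   length(otu_cols), " OTU column(s) present"))
    }
    sst <- unique(round((1 - as.numeric(raw$label)) * 100))
    if (length(sst) != 1) abort("mixed label values in .shared file")
    out <- dplyr::bind_cols(tibble::tibble(sample = raw$Group),
                            raw[otu_cols])
  } else {
    if (names(raw)[1] != "sample") {
      names(raw)[1] <- "sample"
    }
    out <- raw
    sst <- NA_real_
  }
  check_integer_counts(out)
  if (anyDuplicated(out$sample)) abort("duplicate sample ids")
  if (anyDuplicated(names(out))) abort("duplicate OTU ids")
  attr(out, "sst") <- sst
  attr(out, "dialect") <- dialect
  out
}

check_integer_counts <- function(table) {
  for (col in setdiff(names(table), "sample")) {
    x <- table[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      abort(paste0("non-numeric or missing count in column ", col))
    }
    bad <- which(x < 0 | abs(x - round(x)) > 1e-9)
    if (length(bad) > 0) {
      abort(paste0("non-integer or negative count in column ", col,
                   ", row ", bad[1]))
    }
  }
  invisible(table)
}

#' Write an OTU count table
#'
#' @param table Wide count tibble (`sample` + OTU columns).
#' @param path Output path.
#' @param dialect `"tsv-wide"` or `"mothur-shared"`.
#' @param sst SST percent recorded in the mothur `label` column (defaults
#'   to the table's `sst` attribute).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path,
                            dialect = c("tsv-wide", "mothur-shared"),
                            sst = attr(table, "sst")) {
  dialect <- match.arg(dialect)
  if (dialect == "mothur-shared") {
    if (is.null(sst) || is.na(sst)) {
      abort("mothur-shared output needs an SST for the label column")
    }
    otu_cols <- setdiff(names(table), "sample")
    out <- dplyr::bind_cols(
      tibble::tibble(label = sprintf("%.2f", 1 - sst / 100),
                     Group = table$sample,
                     numOtus = length(otu_cols)),
      table[otu_cols])
    readr::write_tsv(out, path)
  } else {
    readr::write_tsv(table, path)
  }
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total so every row sums to 1.
#'
#' @param table Wide count tibble.
#' @return Wide tibble of proportions, attribute `relative = TRUE`.
#' @export
to_relative <- function(table) {
  m <- otu_matrix(table)
  totals <- rowSums(m)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    abort(paste0("zero total count for sample(s): ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  out <- matrix_to_table(m / totals, template = table)
  attr(out, "relative") <- TRUE
  out
}

#' Remove rare OTUs by sample occupancy
#'
#' Keeps an OTU only if it occurs (abundance > 0) in strictly more than
#' `fraction` of the samples, i.e. in at least the smallest integer
#' strictly greater than `fraction * N` samples (for 90 samples at the
#' default 5% rule that minimum is 5). Rows are **not** renormalized after
#' removal — the index is invariant to per-sample rescaling, so
#' renormalizing would change nothing downstream.
#'
#' The filter is idempotent and the kept set shrinks (weakly) as `fraction`
#' grows.
#'
#' @param table Wide relative-abundance (or count) tibble.
#' @param fraction Occupancy fraction threshold in (0, 1); default 0.05.
#' @return List with `table` (filtered tibble, attribute
#'   `rare_filtered = TRUE`) and `report` (list: `n_samples`, `fraction`,
#'   `min_occupancy`, `n_before`, `n_after`, `removed`).
#' @export
filter_rare <- function(table, fraction = 0.05) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  m <- otu_matrix(table)
  n <- nrow(m)
  min_occ <- rare_filter_threshold(n, fraction)
  occupancy <- colSums(m > 0)
  keep <- occupancy >= min_occ
  if (!any(keep)) abort("rare-OTU filter removed every OTU")
  out <- matrix_to_table(m[, keep, drop = FALSE], template = table)
  attr(out, "rare_filtered") <- TRUE
  report <- list(n_samples = n,
                 fraction = fraction,
                 min_occupancy = min_occ,
                 n_before = ncol(m),
                 n_after = sum(keep),
                 removed = colnames(m)[!keep])
  list(table = out, report = report)
}
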