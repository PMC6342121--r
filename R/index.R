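#' Compute the OTU quality index for one sample
#'
#' The index is an adapted Zelinka–Marvan weighted average over the OTUs
#' present in both the sample (`a_j > 0`) and the profile database:
#' \deqn{Idx = \frac{\sum_j a_j s_j w_j}{\sum_j a_j w_j}}
#' with `a_j` the OTU's relative abundance, `s_j` its ecological optimum,
#' and weight `w_j = 1 / v_j` (dialect `"inverse_tolerance"`, the default:
#' narrow-niche OTUs are the strong indicators) or `w_j = v_j` (dialect
#' `"raw_tolerance"`, the tolerance used directly as the weight). OTUs in
#' the sample but absent from the database are ignored. The result is a
#' convex combination of the `s_j` of contributing OTUs, hence bounded by
#' their range, and invariant to rescaling the abundance vector.
#'
#' @param abundances Named numeric vector of (relative) abundances for one
#'   sample.
#' @param db A `profile_db` from [estimate_profiles()].
#' @param dialect `"inverse_tolerance"` or `"raw_tolerance"`.
#' @return One-row tibble `idx`, `n_otus`, `missing`; `idx` is `NA` and
#'   `missing` `TRUE` when no profiled OTU is present.
#' @export
compute_index <- function(abundances, db,
                          dialect = c("inverse_tolerance", "raw_tolerance")) {
  dialect <- match.arg(dialect)
  if (nrow(db) == 0) abort("empty profile database")
  pos <- abundances[abundances > 0]
  hit <- match(names(pos), db$otu)
  keep <- !is.na(hit)
  if (!any(keep)) {
    return(tibble::tibble(idx = NA_real_, n_otus = 0L, missing = TRUE))
  }
  a <- pos[keep]
  s <- db$s[hit[keep]]
  v <- db$v[hit[keep]]
  w <- if (dialect == "inverse_tolerance") 1 / v else v
  tibble::tibble(idx = sum(a * s * w) / sum(a * w),
                 n_otus = sum(keep),
                 missing = FALSE)
}

#' Compute the OTU quality index for every sample of a table
#'
#' Vectorized application of [compute_index()] over the rows of a wide
#' relative-abundance table. Samples with no profiled OTU present get a
#' missing index (flagged, counted in a message).
#'
#' @param table Wide relative-abundance tibble.
#' @param db A `profile_db`.
#' @param dialect `"inverse_tolerance"` or `"raw_tolerance"`.
#' @return Tibble `sample`, `idx`, `n_otus`, `missing`.
#' @export
compute_index_table <- function(table, db,
                                dialect = c("inverse_tolerance",
                                            "raw_tolerance")) {
  dialect <- match.arg(dialect)
  if (nrow(db) == 0) abort("empty profile database")
  m <- otu_matrix(table)
  shared <- intersect(colnames(m), db$otu)
  if (length(shared) == 0) {
    warn("no table OTU appears in the profile database; all indices missing")
    return(tibble::tibble(sample = table$sample, idx = NA_real_,
                          n_otus = 0L, missing = TRUE))
  }
  a <- m[, shared, drop = FALSE]
  prof <- db[match(shared, db$otu), ]
  w <- if (dialect == "inverse_tolerance") 1 / prof$v else prof$v
  num <- as.vector(a %*% (prof$s * w))
  den <- as.vector(a %*% w)
  out <- tibble::tibble(sample = table$sample,
                        idx = ifelse(den > 0, num / den, NA_real_),
                        n_otus = as.integer(rowSums(a > 0)),
                        missing = den <= 0)
  n_miss <- sum(out$missing)
  if (n_miss > 0) {
    inform(paste0(n_miss, " sample(s) have no profiled OTU; index missing"))
  }
  out
}

#' Write per-sample index values as TSV
#'
#' @param index_table Tibble from [compute_index_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index_table, path) {
  readr::write_tsv(index_table, path)
  invisible(path)
}
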