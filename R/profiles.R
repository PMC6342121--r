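#' Estimate OTU ecological profiles by weighted averaging
#'
#' For each OTU `j` with positive total abundance over the training samples,
#' the ecological optimum is the abundance-weighted mean position along the
#' pressure gradient and the tolerance is the abundance-weighted
#' (population-form) standard deviation:
#' \deqn{s_j = \frac{\sum_i a_{ij} x_i}{\sum_i a_{ij}}, \qquad
#'       v_j = \max\!\left(v_{floor},
#'       \sqrt{\tfrac{\sum_i a_{ij} (x_i - s_j)^2}{\sum_i a_{ij}}}\right)}
#' where `a_ij` is the relative abundance of OTU `j` in training sample `i`
#' and `x_i` that sample's PC1 score. The population form is the standard
#' weighted-averaging calibration choice and stays defined for an OTU seen
#' in a single sample (raw tolerance 0, floored to `v_floor`).
#'
#' OTUs with zero total training abundance are excluded from the database
#' (a message reports how many).
#'
#' @param train_table Wide relative-abundance tibble restricted to (or
#'   containing) the training samples; only rows with a gradient score are
#'   used if `gradient` covers a subset.
#' @param gradient A `pressure_gradient`, or a tibble with columns `sample`
#'   and `pc1`.
#' @param v_floor Minimum tolerance (gradient units); default 1% of the
#'   training score range. Prevents division blow-ups for narrow-niche OTUs
#'   in the inverse-tolerance index dialect.
#' @return Tibble of class `profile_db` with columns `otu`, `s`, `v`,
#'   `occupancy`, `weight`; attributes `v_floor`, `fingerprint` (md5 of the
#'   gradient scores used) and `x_range`.
#' @export
#' @examples
#' train <- tibble::tibble(sample = c("a", "b"),
#'                         OTU1 = c(0.5, 0.5), OTU2 = c(0.5, 0.5))
#' grad <- tibble::tibble(sample = c("a", "b"), pc1 = c(-1, 1))
#' estimate_profiles(train, grad, v_floor = 0.01)
estimate_profiles <- function(train_table, gradient, v_floor = NULL) {
  scores <- gradient_scores(gradient)
  if (nrow(train_table) == 0) abort("empty training set")
  idx <- match(train_table$sample, scores$sample)
  if (anyNA(idx)) {
    abort(paste0("no gradient score for sample(s): ",
                 paste(train_table$sample[is.na(idx)], collapse = ", ")))
  }
  x <- scores$pc1[idx]
  if (is.null(v_floor)) v_floor <- 0.01 * diff(range(x))
  if (!(v_floor > 0)) abort("v_floor must be > 0")
  a <- otu_matrix(train_table)
  w <- colSums(a)
  dropped <- sum(w == 0)
  if (dropped > 0) {
    inform(paste0(dropped, " OTU(s) absent from the training set dropped ",
                  "from the profile database"))
  }
  keep <- w > 0
  a <- a[, keep, drop = FALSE]
  w <- w[keep]
  s <- colSums(a * x) / w
  v_raw <- sqrt(colSums(a * outer(x, s, "-")^2) / w)
  db <- tibble::tibble(otu = colnames(a),
                       s = unname(s),
                       v = pmax(v_floor, unname(v_raw)),
                       occupancy = unname(colSums(a > 0)),
                       weight = unname(w))
  structure(db, class = c("profile_db", class(db)),
            v_floor = v_floor,
            fingerprint = object_md5(list(scores$sample[idx], x)),
            x_range = range(x))
}

gradient_scores <- function(gradient) {
  if (inherits(gradient, "pressure_gradient")) return(gradient$scores)
  if (is.data.frame(gradient) && all(c("sample", "pc1") %in% names(gradient))) {
    return(gradient)
  }
  abort("gradient must be a pressure_gradient or a tibble with sample, pc1")
}

#' Write a profile database as TSV with a JSON header sidecar
#'
#' @param db A `profile_db`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(db, path) {
  readr::write_tsv(tibble::as_tibble(db), path)
  jsonlite::write_json(list(v_floor = attr(db, "v_floor"),
                            fingerprint = attr(db, "fingerprint"),
                            x_range = attr(db, "x_range")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
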