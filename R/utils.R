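#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest
#' @importFrom purrr map map_dbl map2 imap list_rbind
NULL

# Canonical water-chemistry variables (units: turbidity NFU, all others mg/L).
ENV_VARIABLES <- c("turbidity", "TSS", "DOC", "TOC", "TN",
                   "TP", "NO2", "NO3", "PO4", "NH4")

#' Names of the water-chemistry variables used for the pressure gradient
#'
#' Turbidity is measured in NFU; total suspended solids (TSS), dissolved and
#' total organic carbon (DOC, TOC), total nitrogen and phosphorus (TN, TP),
#' nitrite, nitrate, phosphate and ammonium are in mg/L.
#'
#' @return Character vector of the ten variable names.
#' @export
env_variables <- function() ENV_VARIABLES

# Extract the count/abundance matrix from a wide table (sample + OTU columns).
otu_matrix <- function(table) {
  stopifnot(is.data.frame(table), "sample" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "sample")])
  rownames(m) <- table$sample
  storage.mode(m) <- "double"
  m
}

# Rebuild a wide tibble from a matrix, preserving metadata attributes.
matrix_to_table <- function(m, template = NULL) {
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(m)),
                          tibble::as_tibble(m))
  if (!is.null(template)) {
    for (a in c("sst", "dialect", "relative", "rare_filtered")) {
      attr(out, a) <- attr(template, a)
    }
  }
  out
}

# md5 of an arbitrary R object via a canonical serialized temp file
# (no in-memory hashing in base R).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Smallest integer strictly greater than `fraction * n` — the minimum number
# of occupied samples an OTU needs to survive the rare-OTU filter.
rare_filter_threshold <- function(n, fraction) {
  stopifnot(fraction > 0, fraction < 1, n >= 1)
  as.integer(floor(fraction * n + 1e-9)) + 1L
}

# Largest-remainder apportionment of `total` items over groups with target
# shares `quota` (need not be integers). Ties broken by larger quota, then by
# position — deterministic.
largest_remainder <- function(quota, total) {
  base <- floor(quota)
  left <- total - sum(base)
  if (left < 0) {
    abort("internal: largest-remainder target below floor allocation")
  }
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, -quota, seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

min_max <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || diff(r) == 0) {
    abort("min-max normalization undefined: values are constant")
  }
  (x - r[1]) / diff(r)
}
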