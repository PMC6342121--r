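#' Read a water-chemistry table
#'
#' Expects a TSV with a `sample` column, a `network` column (REF, RCS or
#' POLL) and the ten chemistry variables listed by [env_variables()].
#' Unknown columns are dropped with a warning; a missing required variable
#' or a negative value is an error.
#'
#' @param path Path to a TSV file.
#' @param impute If `TRUE`, missing values are replaced by the per-variable
#'   median; if `FALSE` (default) missing values are an error.
#' @return Tibble `sample`, `network`, then the ten variables.
#' @export
read_env_table <- function(path, impute = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  required <- c("sample", "network", ENV_VARIABLES)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
  }
  env <- raw[required]
  for (v in ENV_VARIABLES) {
    x <- env[[v]]
    if (anyNA(x)) {
      if (!impute) {
        abort(paste0("missing values in variable ", v,
                     " (rows ", paste(which(is.na(x)), collapse = ", "),
                     "); re-run with impute = TRUE for median imputation"))
      }
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      env[[v]] <- x
    }
    neg <- which(x < 0)
    if (length(neg) > 0) {
      abort(paste0("negative value in variable ", v, ", row ", neg[1]))
    }
  }
  env
}

#' Write a water-chemistry table as TSV
#'
#' @param env Chemistry tibble (`sample`, `network`, variables).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  readr::write_tsv(env, path)
  invisible(path)
}

#' Log10-transform chemistry variables
#'
#' Replaces each value `x` of variable `k` by `log10(x + d_k)`. Under the
#' default `"half-min-positive"` policy the offset `d_k` is half the
#' variable's smallest positive value when the variable contains zeros, and
#' 0 otherwise; a policy `"fixed:<d>"` applies the same offset `d`
#' everywhere. Within each variable the transform is strictly monotone, so
#' sample ordering is preserved.
#'
#' @param env Chemistry tibble (values >= 0).
#' @param offset_policy `"half-min-positive"` (default) or `"fixed:<d>"`.
#' @return Tibble of the same shape; the offsets used are attached as
#'   attribute `offsets`.
#' @export
log_transform <- function(env, offset_policy = "half-min-positive") {
  vars <- intersect(ENV_VARIABLES, names(env))
  if (length(vars) == 0) abort("no chemistry variables found")
  fixed <- NULL
  if (grepl("^fixed:", offset_policy)) {
    fixed <- as.numeric(sub("^fixed:", "", offset_policy))
    if (is.na(fixed) || fixed < 0) abort("invalid fixed offset policy")
  } else if (!identical(offset_policy, "half-min-positive")) {
    abort(paste0("unknown offset policy: ", offset_policy))
  }
  offsets <- stats::setNames(numeric(length(vars)), vars)
  out <- env
  for (v in vars) {
    x <- env[[v]]
    if (any(x < 0, na.rm = TRUE)) abort(paste0("negative values in ", v))
    if (is.null(fixed)) {
      d <- 0
      if (any(x == 0, na.rm = TRUE)) {
        pos <- x[x > 0]
        if (length(pos) == 0) {
          abort(paste0("variable ", v, " is identically zero: no positive ",
                       "minimum exists for the half-min-positive offset"))
        }
        d <- min(pos) / 2
      }
    } else {
      d <- fixed
      if (d == 0 && any(x == 0, na.rm = TRUE)) {
        abort(paste0("variable ", v, " contains zeros; fixed:0 offset ",
                     "would produce -Inf"))
      }
    }
    offsets[[v]] <- d
    out[[v]] <- log10(x + d)
  }
  attr(out, "offsets") <- offsets
  out
}

#' Build the reference pressure gradient (PC1 of chemistry)
#'
#' Standardizes every variable to zero mean and unit variance and runs a
#' principal component analysis (correlation-matrix PCA via
#' [stats::prcomp()]). The per-sample scores on the first axis define the
#' reference pressure gradient against which the OTU index is validated.
#' The axis is oriented so that the sum of the ten variable loadings is
#' positive: since all variables are pollution indicators, a higher score
#' means poorer quality. The orientation is idempotent — re-orienting an
#' already oriented gradient changes nothing.
#'
#' The PCA is computed once on the full sample set; downstream train/test
#' splitting reuses these scores and never recomputes the gradient.
#'
#' @param env Chemistry tibble, typically already passed through
#'   [log_transform()].
#' @return Object of class `pressure_gradient`: list with `scores` (tibble
#'   `sample`, `network`, `pc1`), `loadings` (tibble `variable`, `pc1`),
#'   `var_explained` (fraction for axis 1), `flipped` (logical), `sdev`
#'   (all axes).
#' @export
#' @examples
#' sc <- otu_scenario(n_samples = 30, n_species = 50, depth = 500, seed = 3)
#' g <- simulate_gradient(sc)
#' chem <- simulate_chemistry(g, sc)
#' pg <- compute_gradient(log_transform(chem))
#' glance(pg)
compute_gradient <- function(env) {
  vars <- intersect(ENV_VARIABLES, names(env))
  if (nrow(env) < 3) abort("need at least 3 samples for PCA")
  if (length(vars) < 2) abort("need at least 2 chemistry variables")
  x <- as.matrix(env[vars])
  if (anyNA(x)) abort("missing values in chemistry; impute or drop first")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance variable(s): ",
                 paste(vars[sds == 0], collapse = ", ")))
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1]
  loadings <- pca$rotation[, 1]
  flipped <- sum(loadings) < 0
  if (flipped) {
    scores <- -scores
    loadings <- -loadings
  }
  var_explained <- pca$sdev[1]^2 / sum(pca$sdev^2)
  structure(
    list(scores = tibble::tibble(
           sample = env$sample,
           network = if ("network" %in% names(env)) env$network else NA,
           pc1 = unname(scores)),
         loadings = tibble::tibble(variable = vars, pc1 = unname(loadings)),
         var_explained = var_explained,
         flipped = flipped,
         sdev = pca$sdev),
    class = "pressure_gradient")
}

#' @export
print.pressure_gradient <- function(x, ...) {
  cat("<pressure_gradient>  ", nrow(x$scores), " samples, axis 1 explains ",
      sprintf("%.1f%%", 100 * x$var_explained), " of variance\n", sep = "")
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' @rdname compute_gradient
#' @param x,object A `pressure_gradient`.
#' @param ... Unused.
#' @export
tidy.pressure_gradient <- function(x, ...) x$scores

#' @rdname compute_gradient
#' @export
glance.pressure_gradient <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_variables = nrow(x$loadings),
                 var_explained = x$var_explained,
                 flipped = x$flipped)
}

#' Write / read pressure-gradient scores
#'
#' The TSV holds the per-sample scores; a JSON sidecar (same path with
#' `.json` appended) records loadings, explained variance and orientation.
#'
#' @param gradient A `pressure_gradient`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gradient <- function(gradient, path) {
  readr::write_tsv(gradient$scores, path)
  sidecar <- list(loadings = gradient$loadings,
                  var_explained = gradient$var_explained,
                  flipped = gradient$flipped,
                  sdev = gradient$sdev)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
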