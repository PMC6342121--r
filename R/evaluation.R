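#' Stratified train/test split plans
#'
#' Draws `reps` random 75/25 train/test partitions of the samples,
#' stratified by monitoring network so every partition preserves the
#' network proportions of the full design. The total training size is
#' `round(train_frac * N)` (round-half-to-even); per-network training
#' sizes start at `floor(train_frac * n_net)` and leftover slots go to the
#' networks with the largest fractional remainders (ties to the larger
#' network, then by name). Iteration `i` uses derived seed `seed + i`, so
#' the whole plan is reproducible from the master seed alone.
#'
#' @param samples Tibble with columns `sample` and `network` (one row per
#'   sample), or a `pressure_gradient` (its scores are used).
#' @param train_frac Training fraction; default 0.75.
#' @param reps Number of randomizations; default 100.
#' @param seed Master seed.
#' @return Tibble of class `split_plan`: columns `iteration`, `seed`,
#'   `train` and `test` (list-columns of sample ids); per-network
#'   allocation attached as attribute `allocation`.
#' @export
make_splits <- function(samples, train_frac = 0.75, reps = 100, seed = 1L) {
  if (inherits(samples, "pressure_gradient")) samples <- samples$scores
  stopifnot(all(c("sample", "network") %in% names(samples)))
  if (anyNA(samples$network)) abort("every sample must carry a network label")
  if (!(train_frac > 0 && train_frac < 1)) {
    abort("train_frac must be in (0, 1)")
  }
  n_net <- table(samples$network)
  if (any(n_net < 2)) {
    abort(paste0("network(s) with fewer than 2 samples: ",
                 paste(names(n_net)[n_net < 2], collapse = ", ")))
  }
  total_train <- round(train_frac * nrow(samples))
  nets <- names(sort(n_net, decreasing = TRUE)) # ties: larger first, by name
  quota <- train_frac * as.numeric(n_net[nets])
  base <- floor(quota)
  left <- total_train - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, -as.numeric(n_net[nets]), nets)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  train_n <- stats::setNames(as.integer(base), nets)
  test_n <- as.integer(n_net[nets]) - train_n
  if (any(test_n == 0)) {
    abort(paste0("network(s) with an empty test share: ",
                 paste(nets[test_n == 0], collapse = ", ")))
  }
  by_net <- split(samples$sample, samples$network)
  plans <- purrr::map(seq_len(reps), function(i) {
    set.seed(seed + i)
    train_ids <- sort(unlist(lapply(nets, function(nt) {
      sample(by_net[[nt]], train_n[[nt]])
    }), use.names = FALSE))
    test_ids <- sort(setdiff(samples$sample, train_ids))
    tibble::tibble(iteration = i, seed = seed + i,
                   train = list(train_ids), test = list(test_ids))
  })
  out <- purrr::list_rbind(plans)
  structure(out, class = c("split_plan", class(out)),
            allocation = tibble::tibble(network = nets,
                                        n = as.integer(n_net[nets]),
                                        train = train_n, test = test_n),
            train_frac = train_frac, master_seed = seed)
}

#' Evaluate one train/test randomization at one SST
#'
#' Estimates OTU profiles from the training rows only, computes the index
#' for the test rows, and summarizes the fit of the test index values to
#' the pressure gradient with an ordinary least-squares simple regression
#' (`R^2` = squared Pearson correlation) plus the discrimination power
#' `SD_index` = sample SD (n-1 denominator) of the non-missing test index
#' values.
#'
#' Conventions for degenerate draws: fewer than 3 non-missing test values
#' flags the iteration invalid (excluded from aggregates); zero variance in
#' the test index values gives `R^2 = 0` with the `degenerate` flag.
#'
#' @param rel_table Wide relative-abundance tibble covering all split
#'   samples (typically rare-filtered).
#' @param gradient A `pressure_gradient` (or tibble `sample`, `pc1`).
#' @param split One row of a [make_splits()] plan (or a list with `train`,
#'   `test`, `iteration`).
#' @param dialect Index dialect, see [compute_index_table()].
#' @param v_floor Tolerance floor for [estimate_profiles()]; `NULL` uses
#'   1% of the training score range.
#' @return One-row tibble: `iteration`, `n_test`, `n_valid`, `r2`, `slope`,
#'   `intercept`, `p_value`, `sd_index`, `valid`, `degenerate`, and a
#'   list-column `sample_idx` holding the per-test-sample index values.
#' @export
evaluate_iteration <- function(rel_table, gradient, split,
                               dialect = c("inverse_tolerance",
                                           "raw_tolerance"),
                               v_floor = NULL) {
  dialect <- match.arg(dialect)
  train_ids <- if (is.list(split$train)) split$train[[1]] else split$train
  test_ids <- if (is.list(split$test)) split$test[[1]] else split$test
  iteration <- split$iteration %||% NA_integer_
  missing_rows <- setdiff(c(train_ids, test_ids), rel_table$sample)
  if (length(missing_rows) > 0) {
    abort(paste0("table is missing split sample(s): ",
                 paste(missing_rows, collapse = ", ")))
  }
  scores <- gradient_scores(gradient)
  train_tbl <- rel_table[match(train_ids, rel_table$sample), ]
  test_tbl <- rel_table[match(test_ids, rel_table$sample), ]
  db <- suppressMessages(estimate_profiles(train_tbl, gradient, v_floor))
  idx <- suppressMessages(compute_index_table(test_tbl, db, dialect))
  idx$pc1 <- scores$pc1[match(idx$sample, scores$sample)]
  ok <- !idx$missing & !is.na(idx$pc1)
  n_valid <- sum(ok)
  base <- tibble::tibble(iteration = iteration,
                         n_test = nrow(idx), n_valid = n_valid,
                         r2 = NA_real_, slope = NA_real_,
                         intercept = NA_real_, p_value = NA_real_,
                         sd_index = NA_real_, valid = FALSE,
                         degenerate = FALSE,
                         sample_idx = list(idx[c("sample", "idx", "missing")]))
  if (n_valid < 3) return(base)
  y <- idx$idx[ok]
  x <- idx$pc1[ok]
  base$valid <- TRUE
  base$sd_index <- stats::sd(y)
  if (base$sd_index == 0 || stats::sd(x) == 0) {
    base$r2 <- 0
    base$degenerate <- TRUE
    return(base)
  }
  r <- stats::cor(x, y)
  base$r2 <- r^2
  base$slope <- r * stats::sd(y) / stats::sd(x)
  base$intercept <- mean(y) - base$slope * mean(x)
  base$p_value <- if (base$r2 >= 1) 0 else {
    tt <- r * sqrt((n_valid - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n_valid - 2)
  }
  base
}

#' Sweep the evaluation over SST levels
#'
#' Applies the *same* list of split plans at every SST level (a paired
#' design: level-to-level differences are never driven by split
#' randomness) and aggregates, per level, the mean `R^2`, the
#' discrimination power (mean of `SD_index` over valid iterations) and the
#' stability (SD of `SD_index` over iterations — larger means *less*
#' stable), plus per-sample mean and SD of the index across the iterations
#' in which the sample fell into the test set.
#'
#' @param tables Named list of wide relative-abundance tibbles, one per SST
#'   level; names are the SST percents.
#' @param gradient A `pressure_gradient`.
#' @param splits A [make_splits()] plan.
#' @param dialect Index dialect.
#' @param v_floor Tolerance floor (see [estimate_profiles()]).
#' @return Object of class `sst_sweep`: list with `metrics` (one row per
#'   SST x iteration), `summary` (one row per SST: `sst`, `n_valid`,
#'   `mean_r2`, `median_r2`, `discrimination`, `stability_sd`),
#'   `sample_stats` (per sample x SST: `mean_idx`, `sd_idx`, `n_obs`),
#'   `dialect`, `n_evaluations`.
#' @export
#' @examples
#' sc <- otu_scenario(n_samples = 24, n_species = 40, depth = 2000, seed = 5)
#' sim <- simulate_dataset(sc, sst_grid = c(85, 95))
#' pg <- compute_gradient(log_transform(sim$chemistry))
#' tabs <- lapply(sim$tables,
#'                function(t) filter_rare(to_relative(t))$table)
#' sw <- run_sweep(tabs, pg, make_splits(pg$scores, reps = 5, seed = 9))
#' sw$summary
run_sweep <- function(tables, gradient, splits,
                      dialect = c("inverse_tolerance", "raw_tolerance"),
                      v_floor = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("tables must be a named list keyed by SST level")
  }
  grid <- sort(as.numeric(names(tables)))
  missing_lvl <- grid[is.na(grid)]
  if (length(missing_lvl) > 0) abort("non-numeric SST level name")
  metrics <- purrr::list_rbind(purrr::map(grid, function(lvl) {
    tbl <- tables[[as.character(lvl)]]
    if (is.null(tbl)) abort(paste0("no table for SST level ", lvl))
    rows <- purrr::map(seq_len(nrow(splits)), function(i) {
      evaluate_iteration(tbl, gradient, splits[i, ], dialect, v_floor)
    })
    dplyr::mutate(purrr::list_rbind(rows), sst = lvl, .before = 1)
  }))
  n_invalid <- sum(!metrics$valid)
  if (n_invalid > 0) {
    inform(paste0(n_invalid, " iteration(s) invalid (fewer than 3 usable ",
                  "test values); excluded from aggregates"))
  }
  summary <- metrics |>
    dplyr::group_by(.data$sst) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      mean_r2 = mean(.data$r2[.data$valid]),
      median_r2 = stats::median(.data$r2[.data$valid]),
      discrimination = mean(.data$sd_index[.data$valid]),
      stability_sd = if (sum(.data$valid) >= 2) {
        stats::sd(.data$sd_index[.data$valid])
      } else NA_real_,
      .groups = "drop")
  if (any(is.na(summary$stability_sd))) {
    inform("stability undefined for level(s) with fewer than 2 valid draws")
  }
  sample_stats <- metrics |>
    dplyr::select("sst", "iteration", "sample_idx") |>
    tidyr::unnest("sample_idx") |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(.data$sst, .data$sample) |>
    dplyr::summarise(mean_idx = mean(.data$idx),
                     sd_idx = if (dplyr::n() >= 2) stats::sd(.data$idx)
                              else NA_real_,
                     n_obs = dplyr::n(), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 sample_stats = sample_stats, dialect = dialect,
                 n_evaluations = nrow(metrics),
                 paired_splits = TRUE,
                 master_seed = attr(splits, "master_seed")),
            class = "sst_sweep")
}

#' @export
print.sst_sweep <- function(x, ...) {
  cat("<sst_sweep>  ", length(unique(x$metrics$sst)), " SST level(s) x ",
      max(x$metrics$iteration), " iteration(s) = ", x$n_evaluations,
      " evaluations (dialect: ", x$dialect, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_sweep
#' @param x,object An `sst_sweep`.
#' @param ... Unused.
#' @export
tidy.sst_sweep <- function(x, ...) {
  dplyr::select(x$metrics, -"sample_idx")
}

#' @rdname run_sweep
#' @export
glance.sst_sweep <- function(x, ...) {
  tibble::tibble(n_levels = nrow(x$summary),
                 n_evaluations = x$n_evaluations,
                 dialect = x$dialect,
                 mean_r2 = mean(x$summary$mean_r2),
                 best_sst = x$summary$sst[which.max(x$summary$mean_r2)])
}

#' Normalize the discrimination/stability trade-off curves
#'
#' Min–max normalizes the per-SST discrimination power (mean `SD_index`)
#' and stability SD (SD of `SD_index`) to `[0, 1]` across the SST grid so
#' both curves can be read on one scale; each normalized curve attains 0
#' and 1.
#'
#' @param sweep An `sst_sweep`.
#' @return Tibble `sst`, `discrimination`, `stability_sd`,
#'   `discrimination_norm`, `stability_norm`.
#' @export
summarize_tradeoff <- function(sweep) {
  s <- sweep$summary[!is.na(sweep$summary$stability_sd), ]
  if (nrow(s) < 2) abort("need at least 2 SST levels with valid aggregates")
  dplyr::transmute(s, sst = .data$sst,
                   discrimination = .data$discrimination,
                   stability_sd = .data$stability_sd,
                   discrimination_norm = min_max(.data$discrimination),
                   stability_norm = min_max(.data$stability_sd))
}

#' Compare index performance between low and high SST groups
#'
#' Pools the per-iteration `R^2` values of all valid iterations whose SST
#' falls in the low range against those in the high range and applies a
#' pooled-variance two-sample Student's t test. With zero pooled variance
#' the statistic is 0 / p = 1 for identical means, and +/-Inf / p = 0
#' (flagged `zero_variance`) otherwise.
#'
#' @param sweep An `sst_sweep`.
#' @param low,high Length-2 numeric ranges of SST percents (inclusive);
#'   defaults 80–85 vs 90–99.
#' @return One-row tibble: `mean_low`, `mean_high`, `n_low`, `n_high`,
#'   `t`, `df`, `p_value`, `zero_variance`.
#' @export
compare_sst_groups <- function(sweep, low = c(80, 85), high = c(90, 99)) {
  m <- sweep$metrics[sweep$metrics$valid, ]
  r2_low <- m$r2[m$sst >= low[1] & m$sst <= low[2]]
  r2_high <- m$r2[m$sst >= high[1] & m$sst <= high[2]]
  n1 <- length(r2_low); n2 <- length(r2_high)
  if (n1 < 2 || n2 < 2) abort("each SST group needs at least 2 valid R^2")
  m1 <- mean(r2_low); m2 <- mean(r2_high)
  sp2 <- ((n1 - 1) * stats::var(r2_low) + (n2 - 1) * stats::var(r2_high)) /
    (n1 + n2 - 2)
  df <- n1 + n2 - 2
  zero_var <- sp2 == 0
  if (zero_var) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  tibble::tibble(mean_low = m1, mean_high = m2, n_low = n1, n_high = n2,
                 t = t_stat, df = df, p_value = p, zero_variance = zero_var)
}

#' Correlate per-sample index stability with OTU richness
#'
#' For every (sample, SST) pair, pairs the sample's OTU richness at that
#' SST (number of OTUs with abundance > 0, min–max normalized within the
#' SST level so levels with very different OTU totals are comparable) with
#' the SD of that sample's index values across the randomizations at that
#' level, then reports the Pearson correlation over all pairs with a
#' defined SD. Levels whose richness is constant are dropped with a
#' message; if every level is constant, or the SDs are constant, the
#' correlation is undefined and an error is raised.
#'
#' @param sweep An `sst_sweep`.
#' @param tables The same named list of tables used for the sweep.
#' @return List with `r`, `p_value`, `n_pairs` and `pairs` (tibble
#'   `sample`, `sst`, `richness`, `richness_norm`, `sd_idx`).
#' @export
sample_stability_vs_richness <- function(sweep, tables) {
  levels_used <- unique(sweep$sample_stats$sst)
  rich <- purrr::list_rbind(purrr::map(levels_used, function(lvl) {
    tbl <- tables[[as.character(lvl)]]
    if (is.null(tbl)) abort(paste0("no table for SST level ", lvl))
    m <- otu_matrix(tbl)
    tibble::tibble(sst = lvl, sample = rownames(m),
                   richness = as.integer(rowSums(m > 0)))
  }))
  const <- rich |>
    dplyr::group_by(.data$sst) |>
    dplyr::summarise(const = diff(range(.data$richness)) == 0,
                     .groups = "drop")
  if (all(const$const)) {
    abort("richness is constant within every SST level; correlation undefined")
  }
  if (any(const$const)) {
    inform(paste0("dropping SST level(s) with constant richness: ",
                  paste(const$sst[const$const], collapse = ", ")))
    rich <- rich[!rich$sst %in% const$sst[const$const], ]
  }
  rich <- rich |>
    dplyr::group_by(.data$sst) |>
    dplyr::mutate(richness_norm = min_max(.data$richness)) |>
    dplyr::ungroup()
  pairs <- dplyr::inner_join(rich, sweep$sample_stats,
                             by = c("sst", "sample")) |>
    dplyr::filter(!is.na(.data$sd_idx)) |>
    dplyr::select("sample", "sst", "richness", "richness_norm", "sd_idx")
  if (nrow(pairs) < 3) abort("fewer than 3 usable (sample, SST) pairs")
  if (stats::sd(pairs$sd_idx) == 0 || stats::sd(pairs$richness_norm) == 0) {
    abort("correlation undefined: constant values")
  }
  ct <- stats::cor.test(pairs$richness_norm, pairs$sd_idx)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = nrow(pairs), pairs = pairs)
}
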