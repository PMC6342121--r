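# Shared small evaluation fixture: one scenario, gradient, filtered tables.
eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- tiny_scenario(n_samples = 36, n_species = 80, depth = 3000,
                          seed = 19)
      sim <- simulate_dataset(sc, sst_grid = c(82, 90, 97))
      pg <- compute_gradient(log_transform(sim$chemistry))
      tabs <- lapply(sim$tables,
                     function(t) filter_rare(to_relative(t), 0.05)$table)
      cache <<- list(sc = sc, sim = sim, pg = pg, tabs = tabs)
    }
    cache
  }
})

test_that("stratified splits respect network proportions and the rounding rule", {
  labels <- tibble::tibble(
    sample = sprintf("s%02d", 1:90),
    network = rep(c("REF", "RCS", "POLL"), c(37, 30, 23)))
  splits <- make_splits(labels, train_frac = 0.75, reps = 10, seed = 5)
  alloc <- attr(splits, "allocation")

  # rule-enumeration oracle: floor quotas, then largest remainders
  quota <- 0.75 * c(REF = 37, RCS = 30, POLL = 23)
  base <- floor(quota)                      # 27, 22, 17 = 66
  total <- round(0.75 * 90)                 # 68 (round-half-to-even)
  rem <- sort(quota - base, decreasing = TRUE)
  expect_equal(total - sum(base), 2)
  oracle <- base + c(REF = 1, RCS = 1, POLL = 0) # remainders .75,.50,.25
  got <- stats::setNames(alloc$train, alloc$network)
  expect_equal(got[names(oracle)], oracle)
  expect_equal(sum(alloc$train), total)

  for (i in c(1, 10)) {
    tr <- splits$train[[i]]
    te <- splits$test[[i]]
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), labels$sample)
    per_net <- table(labels$network[labels$sample %in% tr])
    expect_equal(unname(per_net[alloc$network]), unname(as.table(oracle)),
                 ignore_attr = TRUE)
  }
})

test_that("splits divide exactly when the fraction is exact", {
  labels <- tibble::tibble(sample = sprintf("s%d", 1:8),
                           network = rep(c("REF", "POLL"), each = 4))
  splits <- make_splits(labels, train_frac = 0.5, reps = 3, seed = 1)
  alloc <- attr(splits, "allocation")
  expect_true(all(alloc$train == 2))
  expect_true(all(alloc$test == 2))
})

test_that("split edge cases error out", {
  labels <- tibble::tibble(sample = c("a", "b", "c", "d"),
                           network = c("REF", "REF", "REF", "POLL"))
  expect_error(make_splits(labels, reps = 2), "fewer than 2")
  labels2 <- tibble::tibble(sample = sprintf("s%d", 1:6),
                            network = rep(c("REF", "POLL"), c(4, 2)))
  expect_error(make_splits(labels2, train_frac = 0.95, reps = 2),
               "test share")
})

test_that("split plans are deterministic in the master seed", {
  labels <- tibble::tibble(sample = sprintf("s%02d", 1:30),
                           network = rep(c("REF", "RCS", "POLL"), 10))
  a <- make_splits(labels, reps = 5, seed = 11)
  b <- make_splits(labels, reps = 5, seed = 11)
  c <- make_splits(labels, reps = 5, seed = 12)
  expect_identical(a$train, b$train)
  expect_false(identical(a$train, c$train))
})

test_that("iteration metrics match direct-formula oracles", {
  fx <- eval_fixture()
  splits <- make_splits(fx$pg$scores, reps = 3, seed = 23)
  met <- evaluate_iteration(fx$tabs[["90"]], fx$pg, splits[1, ])
  expect_true(met$valid)

  # recompute by hand: profiles on train, index on test, squared Pearson r
  db <- suppressMessages(
    estimate_profiles(fx$tabs[["90"]][match(splits$train[[1]],
                                            fx$tabs[["90"]]$sample), ],
                      fx$pg))
  idx <- suppressMessages(
    compute_index_table(fx$tabs[["90"]][match(splits$test[[1]],
                                              fx$tabs[["90"]]$sample), ], db))
  x <- fx$pg$scores$pc1[match(idx$sample, fx$pg$scores$sample)]
  ok <- !idx$missing
  n <- sum(ok)
  sxy <- sum((x[ok] - mean(x[ok])) * (idx$idx[ok] - mean(idx$idx[ok])))
  r_oracle <- sxy / sqrt(sum((x[ok] - mean(x[ok]))^2) *
                         sum((idx$idx[ok] - mean(idx$idx[ok]))^2))
  expect_equal(met$r2, r_oracle^2, tolerance = 1e-10)
  expect_equal(met$sd_index,
               sqrt(sum((idx$idx[ok] - mean(idx$idx[ok]))^2) / (n - 1)),
               tolerance = 1e-12)
  expect_equal(met$n_test, length(splits$test[[1]]))
})

test_that("an exact affine index gives R^2 = 1 and degenerate draws flag", {
  # hand-built table where the index is exactly affine in PC1:
  # two OTUs with s = 0 and s = 1, equal v; abundance share of the second
  # rises linearly with x
  x <- seq(-1, 1, length.out = 8)
  share <- (x + 1) / 2 * 0.8 + 0.1
  tbl <- tibble::tibble(sample = sprintf("p%d", 1:8),
                        LO = 1 - share, HI = share)
  grad <- tibble::tibble(sample = tbl$sample, pc1 = x)
  split <- list(train = list(tbl$sample[1:4]), test = list(tbl$sample),
                iteration = 1L)
  # a large floor makes both tolerances equal, so the weights cancel and
  # the index is exactly affine in the abundance share, hence in PC1
  met <- evaluate_iteration(tbl, grad, split, v_floor = 10)
  expect_equal(met$r2, 1, tolerance = 1e-10)

  # all test indices equal -> SD 0 and R^2 convention 0
  tbl2 <- tibble::tibble(sample = sprintf("p%d", 1:8),
                         LO = rep(0.5, 8), HI = rep(0.5, 8))
  met2 <- evaluate_iteration(tbl2, grad, split, v_floor = 10)
  expect_equal(met2$sd_index, 0)
  expect_equal(met2$r2, 0)
  expect_true(met2$degenerate)

  # < 3 usable test values -> invalid
  split3 <- list(train = list(tbl$sample[1:4]), test = list(tbl$sample[1:2]),
                 iteration = 2L)
  met3 <- evaluate_iteration(tbl, grad, split3, v_floor = 10)
  expect_false(met3$valid)
  expect_true(is.na(met3$r2))
})

test_that("the sweep is paired, complete and deterministic", {
  fx <- eval_fixture()
  splits <- make_splits(fx$pg$scores, reps = 4, seed = 31)
  sw <- suppressMessages(run_sweep(fx$tabs, fx$pg, splits))
  expect_equal(sw$n_evaluations, 3 * 4)
  expect_setequal(unique(sw$metrics$sst), c(82, 90, 97))

  # aggregates recomputed from stored per-iteration metrics
  for (lvl in c(82, 90, 97)) {
    m <- sw$metrics[sw$metrics$sst == lvl & sw$metrics$valid, ]
    srow <- sw$summary[sw$summary$sst == lvl, ]
    expect_equal(srow$mean_r2, mean(m$r2), tolerance = 1e-12)
    expect_equal(srow$discrimination, mean(m$sd_index), tolerance = 1e-12)
    expect_equal(srow$stability_sd, stats::sd(m$sd_index), tolerance = 1e-12)
  }

  # determinism
  sw2 <- suppressMessages(run_sweep(fx$tabs, fx$pg, splits))
  expect_identical(tidy(sw), tidy(sw2))

  # per-sample stats recompute from unnested values
  unn <- tidyr::unnest(sw$metrics[c("sst", "iteration", "sample_idx")],
                       "sample_idx")
  one <- sw$sample_stats[1, ]
  vals <- unn$idx[unn$sst == one$sst & unn$sample == one$sample &
                  !unn$missing]
  expect_equal(one$mean_idx, mean(vals), tolerance = 1e-12)
  expect_equal(one$sd_idx, stats::sd(vals), tolerance = 1e-12)

  expect_error(suppressMessages(run_sweep(stats::setNames(fx$tabs[1:2],
                                                          c("82", "")),
                                          fx$pg, splits)), "named")
})

test_that("single-draw sweeps flag undefined stability", {
  fx <- eval_fixture()
  splits <- make_splits(fx$pg$scores, reps = 1, seed = 7)
  expect_message(sw <- run_sweep(fx$tabs["90"], fx$pg, splits),
                 "stability undefined")
  expect_equal(sw$n_evaluations, 1)
  expect_true(is.na(sw$summary$stability_sd))
  expect_error(summarize_tradeoff(sw), "2 SST levels")
})

test_that("trade-off normalization matches a hand min-max", {
  fx <- eval_fixture()
  splits <- make_splits(fx$pg$scores, reps = 4, seed = 31)
  sw <- suppressMessages(run_sweep(fx$tabs, fx$pg, splits))
  to <- summarize_tradeoff(sw)
  mm <- function(z) (z - min(z)) / (max(z) - min(z))
  expect_equal(to$discrimination_norm, mm(to$discrimination))
  expect_equal(to$stability_norm, mm(to$stability_sd))
  expect_equal(range(to$discrimination_norm), c(0, 1))
  expect_equal(range(to$stability_norm), c(0, 1))
  expect_equal(order(to$discrimination_norm), order(to$discrimination))

  # two-level grid: normalized values are exactly {0, 1}
  sw2 <- suppressMessages(run_sweep(fx$tabs[c("82", "97")], fx$pg, splits))
  to2 <- summarize_tradeoff(sw2)
  expect_setequal(to2$discrimination_norm, c(0, 1))
  expect_setequal(to2$stability_norm, c(0, 1))
})

test_that("group comparison matches the closed-form pooled t", {
  # synthetic sweep object with known R^2 values
  fake <- list(metrics = tibble::tibble(
    sst = rep(c(80, 95), each = 5),
    r2 = c(0.42, 0.40, 0.44, 0.38, 0.41, 0.52, 0.47, 0.55, 0.49, 0.50),
    valid = TRUE))
  class(fake) <- "sst_sweep"
  got <- compare_sst_groups(fake, low = c(80, 85), high = c(90, 99))
  g1 <- fake$metrics$r2[1:5]; g2 <- fake$metrics$r2[6:10]
  sp2 <- (4 * var(g1) + 4 * var(g2)) / 8
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (2 / 5))
  p_oracle <- 2 * pt(-abs(t_oracle), 8)
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(got$df, 8)
  # cross-check against stats::t.test
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- list(metrics = tibble::tibble(sst = rep(c(80, 95), each = 3),
                                        r2 = rep(0.5, 6), valid = TRUE))
  class(same) <- "sst_sweep"
  got0 <- compare_sst_groups(same)
  expect_equal(got0$t, 0)
  expect_equal(got0$p_value, 1)
  expect_true(got0$zero_variance)

  # zero variance, different means: guarded as maximal significance
  det <- list(metrics = tibble::tibble(sst = rep(c(80, 95), each = 3),
                                       r2 = rep(c(0, 1), each = 3),
                                       valid = TRUE))
  class(det) <- "sst_sweep"
  got1 <- compare_sst_groups(det)
  expect_true(is.infinite(got1$t))
  expect_equal(got1$p_value, 0)
  expect_true(got1$zero_variance)

  expect_error(compare_sst_groups(fake, low = c(10, 20)), "at least 2")
})

test_that("richness-stability pairs and correlation match the oracle", {
  fx <- eval_fixture()
  splits <- make_splits(fx$pg$scores, reps = 6, seed = 41)
  sw <- suppressMessages(run_sweep(fx$tabs, fx$pg, splits))
  st <- suppressMessages(sample_stability_vs_richness(sw, fx$tabs))
  expect_true(abs(st$r) <= 1)

  # direct Pearson oracle on the pair table
  x <- st$pairs$richness_norm; y <- st$pairs$sd_idx
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$r, r_oracle, tolerance = 1e-10)

  # richness is min-max normalized within each level (over all samples of
  # the level's table, before pairs without a defined SD are dropped)
  for (lvl in unique(st$pairs$sst)) {
    m <- as.matrix(fx$tabs[[as.character(lvl)]][-1])
    rich_all <- rowSums(m > 0)
    rng <- range(rich_all)
    sub <- st$pairs[st$pairs$sst == lvl, ]
    expect_equal(sub$richness_norm,
                 (sub$richness - rng[1]) / diff(rng), tolerance = 1e-12)
  }

  # perfect negative construction
  fake <- list(sample_stats = tibble::tibble(
    sst = 90, sample = sprintf("q%d", 1:5),
    mean_idx = 0, sd_idx = c(1, 0.75, 0.5, 0.25, 0), n_obs = 5))
  class(fake) <- "sst_sweep"
  tabs <- list(`90` = tibble::tibble(
    sample = sprintf("q%d", 1:5),
    A = c(1, 1, 1, 1, 1), B = c(0, 1, 1, 1, 1), C = c(0, 0, 1, 1, 1),
    D = c(0, 0, 0, 1, 1), E = c(0, 0, 0, 0, 1)))
  st2 <- sample_stability_vs_richness(fake, tabs)
  expect_equal(st2$r, -1, tolerance = 1e-12)

  # constant stability: correlation undefined
  fake$sample_stats$sd_idx <- 0.5
  expect_error(sample_stability_vs_richness(fake, tabs), "constant")
})
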