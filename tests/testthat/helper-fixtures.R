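# Small scenarios and tables used across test files.

tiny_scenario <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_samples = 24, n_species = 40, depth = 2000, seed = seed),
    list(...))
  do.call(otu_scenario, args)
}

# Deterministic wide count table with known entries.
toy_counts <- function() {
  tibble::tibble(sample = c("s1", "s2", "s3"),
                 OTU_a = c(4L, 0L, 6L),
                 OTU_b = c(6L, 5L, 0L),
                 OTU_c = c(0L, 5L, 4L))
}

# Random wide relative-abundance table (rows sum to 1).
random_rel_table <- function(n_samples, n_otus, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_samples * n_otus), n_samples, n_otus)
  m[m < stats::quantile(m, 0.3)] <- 0          # sprinkle absences
  m[rowSums(m) == 0, 1] <- 1
  m <- m / rowSums(m)
  colnames(m) <- sprintf("OTU_%02d", seq_len(n_otus))
  dplyr::bind_cols(
    tibble::tibble(sample = sprintf("r%02d", seq_len(n_samples))),
    tibble::as_tibble(m))
}

# Hand-built profile database with given optima and tolerances.
toy_db2 <- function(otu, s, v) {
  structure(tibble::tibble(otu = otu, s = s, v = v,
                           occupancy = 5L, weight = 1),
            class = c("profile_db", class(tibble::tibble())),
            v_floor = min(v))
}

# Chemistry fixture: 6 samples, all ten variables, strictly positive.
toy_env <- function(seed = 3) {
  set.seed(seed)
  vals <- matrix(stats::runif(6 * 10, 0.1, 10), 6, 10)
  colnames(vals) <- env_variables()
  dplyr::bind_cols(
    tibble::tibble(sample = sprintf("e%d", 1:6),
                   network = rep(c("REF", "RCS", "POLL"), 2)),
    tibble::as_tibble(vals))
}
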