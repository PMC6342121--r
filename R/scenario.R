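#' Define a synthetic community scenario
#'
#' A scenario bundles every parameter of the synthetic data generator: the
#' sampling design (how many samples per monitoring network and where each
#' network sits on the latent pressure gradient), the species pool (niche
#' optima, breadths, peak abundances, phylogenetic niche signal), the
#' sequencing depth, and the chemistry model coupling measured variables to
#' the latent gradient.
#'
#' The defaults mirror a tropical-stream biofilm monitoring design: 90
#' samples split over reference (REF), surveillance (RCS) and polluted (POLL)
#' networks in proportions 37/30/23, a pool of 500 diatom-like taxa with
#' unimodal (Gaussian) abundance responses along the gradient, and 10,000
#' reads per sample.
#'
#' @param n_samples Number of biofilm samples (>= 6).
#' @param network_mix Named fractions for networks `REF`, `RCS`, `POLL`;
#'   must sum to 1.
#' @param network_gradient_params Data frame with columns `network`, `mean`,
#'   `sd`: the latent pressure distribution of each network (dimensionless
#'   gradient units; REF low / POLL high).
#' @param n_species Species-pool size (>= 2).
#' @param depth Reads per sample (>= 1).
#' @param peak_abundance_params Named vector `meanlog`, `sdlog` of the
#'   lognormal distribution of species peak abundances `h_j`.
#' @param niche_breadth_params Named vector `min`, `max`: uniform range of
#'   species niche breadths `t_j` (gradient units).
#' @param optimum_params Named vector `center`, `sd`: placement of species
#'   optima `u_j` on the gradient.
#' @param phylo_signal Phylogenetic niche signal kappa in \[0, 1\]: 0 gives
#'   optima independent of the merge tree, 1 gives fully tree-correlated
#'   optima, so that merging close relatives merges similar niches.
#' @param coarse_ratio Fraction of species left as distinct OTUs when the
#'   merge tree is cut at the coarsest working height (0.20, i.e. SST 80);
#'   controls how fast OTU counts grow with SST (see
#'   [simulate_species_pool()]).
#' @param chemistry_coeffs Data frame with columns `variable`, `alpha`,
#'   `beta`, `sigma`: each chemistry variable is
#'   `10^(alpha + beta * g + Normal(0, sigma^2))` (log10 units).
#' @param seed Integer master seed for all generator stages.
#'
#' @return An object of class `otu_scenario`.
#' @seealso [simulate_dataset()] for running all generator stages at once.
#' @export
#' @examples
#' sc <- otu_scenario(n_samples = 24, n_species = 40, depth = 1000, seed = 7)
#' sim <- simulate_dataset(sc, sst_grid = c(85, 95))
#' names(sim$tables)
otu_scenario <- function(n_samples = 90,
                         network_mix = c(REF = 37 / 90, RCS = 30 / 90,
                                         POLL = 23 / 90),
                         network_gradient_params = tibble::tibble(
                           network = c("REF", "RCS", "POLL"),
                           mean = c(-1.2, 0, 1.2),
                           sd = c(0.6, 0.6, 0.6)),
                         n_species = 500,
                         depth = 10000,
                         peak_abundance_params = c(meanlog = 0, sdlog = 2),
                         niche_breadth_params = c(min = 0.3, max = 1.0),
                         optimum_params = c(center = 0, sd = 2.0),
                         phylo_signal = 0.8,
                         coarse_ratio = 0.01,
                         chemistry_coeffs = default_chemistry_coeffs(),
                         seed = 1L) {
  sc <- structure(
    list(n_samples = as.integer(n_samples),
         network_mix = network_mix,
         network_gradient_params = tibble::as_tibble(network_gradient_params),
         n_species = as.integer(n_species),
         depth = as.integer(depth),
         peak_abundance_params = peak_abundance_params,
         niche_breadth_params = niche_breadth_params,
         optimum_params = optimum_params,
         phylo_signal = phylo_signal,
         coarse_ratio = coarse_ratio,
         chemistry_coeffs = tibble::as_tibble(chemistry_coeffs),
         seed = as.integer(seed)),
    class = "otu_scenario")
  validate_scenario(sc)
  sc
}

#' Default chemistry-to-gradient coupling coefficients
#'
#' Intercepts are plausible background log10 concentrations for tropical
#' streams; slopes are positive for every variable so that all ten pollution
#' indicators rise along the latent gradient; residual log10 noise of 0.3
#' corresponds to roughly factor-two multiplicative scatter, typical of
#' repeated field nutrient measurements.
#'
#' @return Tibble with columns `variable`, `alpha`, `beta`, `sigma`.
#' @export
default_chemistry_coeffs <- function() {
  tibble::tibble(
    variable = ENV_VARIABLES,
    alpha = c(0.7, 0.9, 0.3, 0.4, -0.3, -1.3, -2.0, -0.5, -1.5, -1.7),
    beta  = c(0.5, 0.5, 0.3, 0.3, 0.4, 0.5, 0.4, 0.4, 0.5, 0.6),
    sigma = rep(0.3, 10L))
}

validate_scenario <- function(sc) {
  if (!inherits(sc, "otu_scenario")) abort("not an otu_scenario")
  mix <- sc$network_mix
  if (is.null(names(mix)) || !setequal(names(mix), c("REF", "RCS", "POLL"))) {
    abort("network_mix must be named REF, RCS, POLL")
  }
  if (abs(sum(mix) - 1) > 1e-9) abort("network_mix must sum to 1")
  if (sc$n_samples < 6) abort("n_samples must be >= 6")
  if (sc$n_species < 2) abort("n_species must be >= 2")
  if (sc$depth < 1) abort("depth must be >= 1")
  gp <- sc$network_gradient_params
  if (!all(c("network", "mean", "sd") %in% names(gp))) {
    abort("network_gradient_params needs columns network, mean, sd")
  }
  if (!setequal(gp$network, c("REF", "RCS", "POLL"))) {
    abort("network_gradient_params must cover REF, RCS, POLL")
  }
  if (any(gp$sd < 0)) abort("network gradient SDs must be >= 0")
  if (sc$phylo_signal < 0 || sc$phylo_signal > 1) {
    abort("phylo_signal must lie in [0, 1]")
  }
  if (!(sc$coarse_ratio > 0 && sc$coarse_ratio < 1)) {
    abort("coarse_ratio must lie in (0, 1)")
  }
  bp <- sc$niche_breadth_params
  if (bp[["min"]] <= 0 || bp[["max"]] < bp[["min"]]) {
    abort("niche_breadth_params must satisfy 0 < min <= max")
  }
  if (sc$optimum_params[["sd"]] < 0) abort("optimum sd must be >= 0")
  cc <- sc$chemistry_coeffs
  if (!all(c("variable", "alpha", "beta", "sigma") %in% names(cc))) {
    abort("chemistry_coeffs needs columns variable, alpha, beta, sigma")
  }
  if (any(cc$sigma < 0)) abort("chemistry sigma must be >= 0")
  invisible(sc)
}

#' @export
print.otu_scenario <- function(x, ...) {
  cat("<otu_scenario>\n")
  cat("  samples:", x$n_samples, "  species:", x$n_species,
      "  depth:", x$depth, "\n")
  cat("  network mix:",
      paste(sprintf("%s %.2f", names(x$network_mix), x$network_mix),
            collapse = ", "), "\n")
  cat("  phylo signal:", x$phylo_signal, "  seed:", x$seed, "\n")
  invisible(x)
}
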