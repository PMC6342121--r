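#' Simulate the sampling design and latent pressure gradient
#'
#' Allocates samples to the three monitoring networks by largest-remainder
#' rounding of the scenario's network mix and draws each sample's latent
#' pressure `g` from its network's Normal distribution. Higher `g` means
#' poorer quality.
#'
#' Stage seed: `scenario$seed + 1`.
#'
#' @param scenario An [otu_scenario()].
#' @return Tibble with columns `sample`, `network`, `g`.
#' @export
simulate_gradient <- function(scenario) {
  validate_scenario(scenario)
  mix <- scenario$network_mix[c("REF", "RCS", "POLL")]
  n_net <- largest_remainder(mix * scenario$n_samples, scenario$n_samples)
  names(n_net) <- names(mix)
  empty <- names(n_net)[n_net == 0]
  if (length(empty) > 0) {
    abort(paste0("network(s) with no samples: ",
                 paste(empty, collapse = ", ")))
  }
  set.seed(scenario$seed + 1L)
  gp <- scenario$network_gradient_params
  network <- rep(names(n_net), n_net)
  pars <- gp[match(network, gp$network), ]
  tibble::tibble(
    sample = sprintf("S%03d", seq_len(scenario$n_samples)),
    network = network,
    g = stats::rnorm(scenario$n_samples, pars$mean, pars$sd))
}

#' Simulate water chemistry coupled to the latent gradient
#'
#' Each variable `k` in sample `i` is `10^(alpha_k + beta_k * g_i + e_ik)`
#' with `e_ik ~ Normal(0, sigma_k^2)`, i.e. concentrations are log-linearly
#' tied to the latent pressure with lognormal scatter; all values are
#' strictly positive.
#'
#' Stage seed: `scenario$seed + 2`.
#'
#' @param gradient Tibble from [simulate_gradient()] (`sample`, `network`,
#'   `g`).
#' @param scenario The same [otu_scenario()].
#' @return Tibble with columns `sample`, `network` and one column per
#'   chemistry variable.
#' @export
simulate_chemistry <- function(gradient, scenario) {
  validate_scenario(scenario)
  stopifnot(all(c("sample", "network", "g") %in% names(gradient)))
  set.seed(scenario$seed + 2L)
  cc <- scenario$chemistry_coeffs
  n <- nrow(gradient)
  vals <- purrr::pmap(list(cc$alpha, cc$beta, cc$sigma), function(a, b, s) {
    10^(a + b * gradient$g + stats::rnorm(n, 0, s))
  })
  names(vals) <- cc$variable
  dplyr::bind_cols(gradient[c("sample", "network")], tibble::as_tibble(vals))
}

#' Simulate a species pool with an ultrametric merge tree
#'
#' Builds a random coalescent topology over `n_species` leaves and places
#' its node heights in `[0, 0.5]` so that a similarity threshold SST maps
#' onto cut height `c = 1 - SST/100`, then assigns each species a niche:
#' optimum `u_j`, breadth `t_j` and peak abundance `h_j`.
#'
#' Node heights are assigned by a rank-preserving map chosen so the number
#' of clusters left by a cut at height `c` decays geometrically,
#' `n(c) = S * coarse_ratio^(c / 0.2)`: cutting at the coarsest height of
#' the working range (0.20, i.e. SST 80) keeps about `coarse_ratio` of the
#' leaves while cutting near 0 keeps almost all of them. This emulates the
#' empirically observed exponential growth of OTU counts with SST and
#' keeps the whole 80-99% grid inside the tree's dynamic range (a raw
#' coalescent collapses almost completely within the first 2% of its
#' height). The default ratio 0.01 mirrors the roughly hundredfold OTU
#' count span seen across that SST range in diatom meta-barcoding.
#'
#' Optima mix a Brownian diffusion down the tree with independent placement:
#' with phylogenetic signal `kappa`, the (standardized) tree component gets
#' weight `sqrt(kappa)` and an iid Normal component weight `sqrt(1-kappa)`,
#' then the mixture is scaled by `optimum_params`. `kappa = 0` gives optima
#' unrelated to the tree; `kappa = 1` gives fully tree-correlated optima so
#' coarser clustering merges ecologically similar species.
#'
#' Stage seed: `scenario$seed + 3`.
#'
#' @param scenario An [otu_scenario()].
#' @return Object of class `species_pool`: list with `species` (tibble
#'   `species`, `u`, `t`, `h`) and `tree` (ultrametric `phylo`).
#' @export
simulate_species_pool <- function(scenario) {
  validate_scenario(scenario)
  s <- scenario$n_species
  if (s < 2) abort("n_species must be >= 2")
  set.seed(scenario$seed + 3L)
  tree <- ape::rcoal(s, tip.label = sprintf("sp%04d", seq_len(s)))
  tree <- reshape_merge_heights(tree, coarse_ratio = scenario$coarse_ratio)

  b <- brownian_leaf_values(tree)
  b <- (b - mean(b)) / stats::sd(b)
  z <- stats::rnorm(s)
  kappa <- scenario$phylo_signal
  raw <- sqrt(kappa) * b + sqrt(1 - kappa) * z
  op <- scenario$optimum_params
  u <- op[["center"]] + op[["sd"]] * raw

  bp <- scenario$niche_breadth_params
  pp <- scenario$peak_abundance_params
  species <- tibble::tibble(
    species = tree$tip.label,
    u = u[tree$tip.label],
    t = stats::runif(s, bp[["min"]], bp[["max"]]),
    h = stats::rlnorm(s, pp[["meanlog"]], pp[["sdlog"]]))
  structure(list(species = species, tree = tree), class = "species_pool")
}

# Reassign ultrametric node heights by a rank-preserving map so a cut at
# height c leaves ~ S * ratio^(c/0.2) clusters; heights stay in [0, 0.5]
# for any S below ~10^8 at the default ratio. Edge lengths are rebuilt from
# the new heights, so the topology and merge order are untouched.
reshape_merge_heights <- function(tree, coarse_ratio = 0.01) {
  stopifnot(coarse_ratio > 0, coarse_ratio < 1)
  s <- length(tree$tip.label)
  rate <- -log(coarse_ratio) / 0.2
  depths <- ape::node.depth.edgelength(tree)
  heights <- max(depths) - depths          # leaf height 0, root max
  internal <- (s + 1):(s + tree$Nnode)
  ord <- internal[order(heights[internal])]
  # k-th merge event: S - k lineages remain above it
  new_h <- pmin(0.5, log(s / (s - seq_len(tree$Nnode) + 1e-12)) / rate)
  heights[ord] <- new_h
  heights[seq_len(s)] <- 0
  tree$edge.length <- heights[tree$edge[, 1]] - heights[tree$edge[, 2]]
  tree
}

# Brownian motion from root to leaves: each edge adds Normal(0, edge length).
# Returns a named vector over tip labels.
brownian_leaf_values <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  val <- numeric(n_node)
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  steps <- stats::rnorm(nrow(ord$edge), 0, sqrt(pmax(ord$edge.length, 0)))
  for (e in seq_len(nrow(ord$edge))) {
    val[ord$edge[e, 2]] <- val[ord$edge[e, 1]] + steps[e]
  }
  stats::setNames(val[seq_len(n_tip)], tree$tip.label)
}

#' Simulate read counts from Gaussian niche responses
#'
#' Expected relative abundance of species `j` in sample `i` is proportional
#' to `h_j * exp(-(g_i - u_j)^2 / (2 t_j^2))`, normalized within the sample;
#' reads are then drawn `Multinomial(depth, p_i.)` independently per sample.
#'
#' @param pool A `species_pool` from [simulate_species_pool()].
#' @param gradient Tibble with columns `sample` and `g`.
#' @param depth Reads per sample.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so the draw is reproducible in isolation.
#' @return Wide count table: tibble `sample` + one integer column per
#'   species, attribute `sst = 100` (no merging yet).
#' @export
simulate_counts <- function(pool, gradient, depth, seed = NULL) {
  stopifnot(inherits(pool, "species_pool"),
            all(c("sample", "g") %in% names(gradient)), depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  sp <- pool$species
  lambda <- outer(gradient$g, sp$u, function(g, u) g - u)
  expab <- sweep(exp(-sweep(lambda^2, 2, 2 * sp$t^2, "/")), 2, sp$h, "*")
  totals <- rowSums(expab)
  bad <- which(totals <= 0 | !is.finite(totals))
  if (length(bad) > 0) {
    abort(paste0("expected abundance underflows to zero for sample(s) ",
                 paste(gradient$sample[bad], collapse = ", "),
                 "; widen niche breadths or narrow the gradient"))
  }
  p <- expab / totals
  counts <- matrix(0, nrow(p), ncol(p),
                   dimnames = list(gradient$sample, sp$species))
  for (i in seq_len(nrow(p))) {
    counts[i, ] <- stats::rmultinom(1, depth, p[i, ])[, 1]
  }
  rownames(counts) <- gradient$sample
  out <- matrix_to_table(counts)
  attr(out, "sst") <- 100
  out
}

#' Merge a count table to a coarser clustering resolution
#'
#' Cuts the ultrametric merge tree at height `c = 1 - sst/100`: each OTU is
#' the set of leaves of a maximal clade whose node heights are all `<= c`,
#' and member columns are summed. Per-sample read totals are unchanged, and
#' the partitions are nested across thresholds (coarser as `sst` decreases).
#'
#' At `sst = 100` (cut height 0) the table is returned unchanged, every leaf
#' its own OTU. Merged OTU columns are named `OTU_<k>` in order of first
#' appearance of each cluster among the input columns; the leaf-to-OTU map
#' is attached as attribute `otu_map`.
#'
#' @param table Wide count table whose columns are leaves of `tree`.
#' @param tree Ultrametric `phylo` (e.g. `pool$tree`).
#' @param sst Sequence similarity threshold in percent, `0 < sst <= 100`.
#' @return Wide count table with attribute `sst` set.
#' @export
merge_to_sst <- function(table, tree, sst) {
  stopifnot(is.data.frame(table), inherits(tree, "phylo"))
  if (!(sst > 0 && sst <= 100)) abort("sst must satisfy 0 < sst <= 100")
  leaves <- setdiff(names(table), "sample")
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("table columns not found among tree leaves: ",
                 paste(unknown, collapse = ", ")))
  }
  h <- 1 - sst / 100
  memb <- cut_merge_tree(tree, h)[leaves]
  if (length(unique(memb)) == length(leaves)) {
    out <- table
    attr(out, "sst") <- sst
    attr(out, "otu_map") <- stats::setNames(leaves, leaves)
    return(out)
  }
  cluster_ids <- unique(memb) # order of first appearance among input columns
  otu_names <- stats::setNames(sprintf("OTU_%04d", seq_along(cluster_ids)),
                               cluster_ids)
  m <- otu_matrix(table)
  merged <- t(rowsum(t(m), group = otu_names[as.character(memb)],
                     reorder = FALSE))
  out <- matrix_to_table(merged)
  attr(out, "sst") <- sst
  attr(out, "otu_map") <- stats::setNames(otu_names[as.character(memb)],
                                          leaves)
  out
}

# Partition tree leaves by cutting at node height h (>= 0): each cluster is
# the leaf set of a maximal subtree whose nodes all sit at height <= h.
# Returns a named integer vector over tip labels. Implemented directly on
# the edge list (preorder, parents first); note hclust cophenetic heights
# are twice the node heights, so cutree is deliberately not used here.
cut_merge_tree <- function(tree, h) {
  n_tip <- length(tree$tip.label)
  if (h <= 0) {
    return(stats::setNames(seq_len(n_tip), tree$tip.label))
  }
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths) - depths
  ord <- ape::reorder.phylo(tree, "cladewise")
  root <- ord$edge[1, 1]
  cluster <- integer(n_tip + tree$Nnode)
  cluster[root] <- if (height[root] <= h + 1e-12) root else 0L
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    cluster[child] <- if (cluster[parent] > 0L) {
      cluster[parent]
    } else if (height[child] <= h + 1e-12) {
      child
    } else 0L
  }
  stats::setNames(match(cluster[seq_len(n_tip)], unique(cluster[seq_len(n_tip)])),
                  tree$tip.label)
}

#' Run every generator stage of a scenario
#'
#' Convenience wrapper: gradient, chemistry, species pool, species-level
#' counts (stage seed `scenario$seed + 4`), then one merged count table per
#' requested SST level.
#'
#' @param scenario An [otu_scenario()].
#' @param sst_grid Integer vector of SST levels (percent).
#' @return List with `gradient`, `chemistry`, `pool`, `counts` and `tables`
#'   (named list of merged count tables, names = SST levels).
#' @export
simulate_dataset <- function(scenario, sst_grid = 80:99) {
  validate_scenario(scenario)
  gradient <- simulate_gradient(scenario)
  chemistry <- simulate_chemistry(gradient, scenario)
  pool <- simulate_species_pool(scenario)
  counts <- simulate_counts(pool, gradient, scenario$depth,
                            seed = scenario$seed + 4L)
  tables <- lapply(sst_grid, function(s) merge_to_sst(counts, pool$tree, s))
  names(tables) <- as.character(sst_grid)
  list(gradient = gradient, chemistry = chemistry, pool = pool,
       counts = counts, tables = tables)
}
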