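## Seeded generator reproducing the statistical structure the analysis
## assumes: a pure-birth (Yule) tree, a continuous trait (ln RBC area)
## evolving by Brownian motion along it, histometric proxies linearly
## coupled to the ln trait with Gaussian noise, and a "fossil" mask that
## removes the response (but not the proxies) from a fraction of tips.

#' Simulation configuration
#'
#' Defaults mirror the structure of the motivating dataset: 40 tips, half
#' masked as fossils, three proxies with unit slope on the ln trait.  The
#' trait is ln RBC area with root state `log(100)` (a 100 square-micron
#' cell) and Brownian rate `sigma2 = 0.05` per unit tree depth, giving a
#' realistic ~2.5-fold spread of cell areas across tips on a Yule tree of
#' this size.  Width and length are derived correlates (half-power scaling
#' of area with small independent noise).
#'
#' @param n_tips Number of tips (>= 4).
#' @param birth_rate Yule speciation rate.
#' @param sigma2 Brownian-motion rate of the ln trait (>= 0).
#' @param root_state Root value of the ln trait.
#' @param proxy_slope Length-3 slopes linking each ln proxy
#'   (osteo_volume, can_harmean, can_min) to the ln trait.
#' @param proxy_intercept Length-3 intercepts of the ln proxies.
#' @param proxy_noise_sd Length-3 Gaussian noise sd of the ln proxies.
#' @param fossil_fraction Fraction of tips masked as fossils, in `[0, 1)`;
#'   `round(fossil_fraction * n_tips)` tips are masked.
#' @param seed Mandatory integer seed; all stochastic draws flow from one
#'   generator seeded once per run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tips = 40L, birth_rate = 1, sigma2 = 0.05,
                       root_state = log(100),
                       proxy_slope = c(1, 1, 1),
                       proxy_intercept = c(1.0, -2.2, -2.4),
                       proxy_noise_sd = c(0.1, 0.1, 0.1),
                       fossil_fraction = 0.5, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory", call. = FALSE)
  if (n_tips < 4L) stop("n_tips must be >= 4", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (fossil_fraction < 0 || fossil_fraction >= 1)
    stop("fossil_fraction must be in [0, 1)", call. = FALSE)
  stopifnot(length(proxy_slope) == 3L, length(proxy_intercept) == 3L,
            length(proxy_noise_sd) == 3L, all(proxy_noise_sd >= 0))
  n_fossil <- round(fossil_fraction * n_tips)
  if (n_tips - n_fossil < 5L)
    stop("fossil_fraction leaves fewer than 5 training tips", call. = FALSE)
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 sigma2 = sigma2, root_state = root_state,
                 proxy_slope = proxy_slope,
                 proxy_intercept = proxy_intercept,
                 proxy_noise_sd = proxy_noise_sd,
                 fossil_fraction = fossil_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_tree <- function(config) {
  tr <- ape::rphylo(config$n_tips, birth = config$birth_rate, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(config$n_tips))
  validate_tree(tr)
}

.sim_traits <- function(tree, config) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  val <- numeric(nn)
  root <- root_node(tree)
  val[root] <- config$root_state
  et <- edge_table(tree)
  for (i in seq_len(nrow(et))) {  # preorder: parent value always set
    inc <- if (config$sigma2 > 0)
      stats::rnorm(1L, 0, sqrt(config$sigma2 * et$length[i])) else 0
    val[et$child[i]] <- val[et$parent[i]] + inc
  }
  ln_area <- val[seq_len(n)]
  ## width/length: half-power correlates of area with small independent
  ## noise (an ellipse of fixed aspect ratio has width, length ~ sqrt(area))
  ln_width <- 0.5 * ln_area - 0.22 + stats::rnorm(n, 0, 0.05)
  ln_length <- 0.5 * ln_area + 0.47 + stats::rnorm(n, 0, 0.05)
  proxies <- vapply(1:3, function(j) {
    config$proxy_intercept[j] + config$proxy_slope[j] * ln_area +
      stats::rnorm(n, 0, config$proxy_noise_sd[j])
  }, numeric(n))
  n_fossil <- round(config$fossil_fraction * n)
  masked <- sort(sample.int(n, n_fossil))
  status <- rep("extant", n)
  status[masked] <- "fossil"
  tab <- data.frame(
    taxon = tree$tip.label,
    status = status,
    lnOsteo_volume = proxies[, 1L],
    lnCan_harmean = proxies[, 2L],
    lnCan_min = proxies[, 3L],
    RBC_width = exp(ln_width),
    RBC_area = exp(ln_area),
    RBC_length = exp(ln_length),
    stringsAsFactors = FALSE
  )
  truth <- tab[masked, c("taxon", "RBC_width", "RBC_area", "RBC_length")]
  truth$ln_RBC_area <- ln_area[masked]
  rownames(truth) <- NULL
  tab[masked, c("RBC_width", "RBC_area", "RBC_length")] <- NA_real_
  attr(tab, "truth") <- truth
  tab
}

#' Simulate a pure-birth tree
#'
#' @param config A [sim_config()].
#' @return An ultrametric `phylo` with `config$n_tips` tips, reproducible
#'   from the seed.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sim_tree(config)
}

#' Simulate a trait table on a tree
#'
#' ln RBC area evolves by Brownian motion (independent normal increments
#' per edge with variance `sigma2 * phi`); width and length are scaled
#' correlates; each ln proxy is `intercept + slope * ln_area + noise`.  A
#' seeded uniform draw without replacement masks the fossil fraction of
#' tips: their responses are removed, proxies kept, and the removed truth
#' is attached as `attr(, "truth")`.
#'
#' @param tree A `phylo` (typically from [simulate_tree()]).
#' @param config A [sim_config()].
#' @param reseed Reset the generator to `config$seed` first (default);
#'   [simulate_dataset()] passes `FALSE` to keep one stream per run.
#' @return A trait-table data frame (ln-scale predictors, raw responses,
#'   `status` column), with masked truth in `attr(, "truth")`.
#' @export
simulate_traits <- function(tree, config, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  .sim_traits(tree, config)
}

#' Simulate tree and traits from one seeded stream
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `table` (see [simulate_traits()]) and `truth`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- .sim_tree(config)
  table <- .sim_traits(tree, config)
  list(tree = tree, table = table, truth = attr(table, "truth"))
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Emits `tree.nwk` (Newick, full precision), `characters.csv` (raw,
#' unlogged character matrix in the documented CLI schema) and `truth.csv`
#' (true responses at masked tips, for tests only).
#'
#' @param tree A `phylo`.
#' @param table A trait table from [simulate_traits()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(tree, table, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory ", directory, call. = FALSE)
  paths <- c(tree = file.path(directory, "tree.nwk"),
             characters = file.path(directory, "characters.csv"),
             truth = file.path(directory, "truth.csv"))
  writeLines(write_newick(tree), paths["tree"])
  write_character_matrix(table, paths["characters"])
  truth <- attr(table, "truth")
  if (is.null(truth))
    truth <- table[table$status == "fossil",
                   c("taxon", "RBC_width", "RBC_area", "RBC_length")]
  .write_csv(truth, paths["truth"])
  invisible(paths)
}
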