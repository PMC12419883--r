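## Shared fixture builders.  All randomness is drawn from the current RNG;
## tests set their own seeds.

## random rooted tree with uniform branch lengths
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  tr
}

## random tree whose branch lengths are small dyadic rationals, so that
## shared-path sums are exact in double arithmetic
dyadic_tree <- function(n) {
  tr <- random_tree(n)
  tr$edge.length <- sample(0:8, length(tr$edge.length), replace = TRUE) / 4
  tr
}

## depth of every tip measured on the tree itself (independent of the
## influence-matrix code path)
tip_depths <- function(tree) diag(path_length_matrix(tree))

## root-to-attachment length of a tip_location, walked along the training
## edge table by hand
attachment_depth <- function(infl, loc) {
  et <- infl$edges
  depth <- loc$traversed
  e <- loc$edge
  parent <- et$parent[e]
  repeat {
    up <- which(et$child == parent)
    if (!length(up)) break
    depth <- depth + et$length[up]
    parent <- et$parent[up]
  }
  depth
}

## small trait table with exact algebraic structure for model tests:
## ln(RBC_area) = beta0 + beta1 * lnCan_min + noise
algebraic_table <- function(tree, beta0 = 1, beta1 = 1, noise = 0) {
  n <- length(tree$tip.label)
  lnmin <- stats::rnorm(n, 2, 0.5)
  ln_area <- beta0 + beta1 * lnmin +
    (if (noise > 0) stats::rnorm(n, 0, noise) else 0)
  data.frame(
    taxon = tree$tip.label, status = "extant",
    lnOsteo_volume = stats::rnorm(n, 5, 0.5),
    lnCan_harmean = stats::rnorm(n, 2, 0.5),
    lnCan_min = lnmin,
    RBC_width = exp(0.5 * ln_area),
    RBC_area = exp(ln_area),
    RBC_length = exp(0.5 * ln_area + 0.7),
    stringsAsFactors = FALSE
  )
}

## independent AICc oracle via stats::logLik on an lm fit
aicc_oracle <- function(fit) {
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}
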