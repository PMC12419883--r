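## Phylogenetic eigenvector map: weighted, column-centered SVD of the
## influence matrix.  The edge weighting w(phi) = sqrt(psi) * phi^((1-a)/2)
## interpolates between Brownian-like gradual change (a = 0, influence
## proportional to sqrt of branch length) and punctuated, length-independent
## change (a = 1).

#' Edge weighting parameters
#'
#' @param a Steepness, in `[0, 1]`.  `a = 0` is the Brownian limit; `a = 1`
#'   makes edge influence independent of branch length.
#' @param psi Global rate, `> 0`.  Downstream predictions are invariant to
#'   `psi` (its scale cancels through the singular values), so the default
#'   of 1 is a pure convention.
#' @return An object of class `edge_weighting`.
#' @export
edge_weighting <- function(a = 0, psi = 1) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop("steepness 'a' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 0)
    stop("rate 'psi' must be a single value > 0", call. = FALSE)
  structure(list(a = a, psi = psi), class = "edge_weighting")
}

#' Apply the PEM edge-weight rule to branch lengths
#'
#' Computes `w = sqrt(psi) * phi^((1 - a) / 2)` elementwise, so that the
#' squared weights along a root path sum to `psi * sum(phi^(1 - a))`.
#'
#' @param lengths Non-negative branch lengths `phi`.
#' @param weighting An [edge_weighting()] object.
#' @return Numeric vector of weights, same length as `lengths`.
#' @export
edge_weights <- function(lengths, weighting = edge_weighting()) {
  if (!inherits(weighting, "edge_weighting"))
    weighting <- do.call(edge_weighting, as.list(weighting))
  if (any(lengths < 0)) stop("branch lengths must be >= 0", call. = FALSE)
  sqrt(weighting$psi) * lengths^((1 - weighting$a) / 2)
}

#' Build a phylogenetic eigenvector map basis
#'
#' Weights the influence matrix column-wise by the edge-weight rule,
#' centers each column on its mean over the training tips, and takes the
#' singular value decomposition.  Components whose singular value falls
#' below `rel_tol` times the largest are discarded (rank cut, not noise
#' filtering).  Each retained left singular vector (eigenvector) has its
#' sign fixed so that its largest-magnitude entry is positive, making the
#' basis bit-reproducible.
#'
#' @param infl An [influence_matrix()] object (at least 3 training tips).
#' @param weighting An [edge_weighting()] object; default Brownian
#'   (`a = 0`, `psi = 1`).
#' @param rel_tol Relative singular-value cutoff (default `1e-10`).
#' @return An object of class `pem_basis`: list with `U` (tips x k,
#'   orthonormal, column sums 0), `d` (singular values, descending), `V`
#'   (edges x k), `means` (column means of the weighted influence matrix),
#'   `weighting`, `tips`, and the `influence_matrix` used.
#' @export
build_pem <- function(infl, weighting = edge_weighting(), rel_tol = 1e-10) {
  stopifnot(inherits(infl, "influence_matrix"))
  if (!inherits(weighting, "edge_weighting"))
    weighting <- do.call(edge_weighting, as.list(weighting))
  n <- nrow(infl$I)
  if (n < 3L) stop("need at least 3 training tips", call. = FALSE)
  w <- edge_weights(infl$lengths, weighting)
  Bw <- sweep(infl$I, 2L, w, `*`)
  m <- colMeans(Bw)
  Bc <- sweep(Bw, 2L, m, `-`)
  sv <- svd(Bc)
  keep <- sv$d > rel_tol * sv$d[1L]
  if (!any(keep))
    stop("degenerate basis: no singular value above tolerance", call. = FALSE)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  ## sign convention: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rownames(U) <- rownames(infl$I)
  colnames(U) <- colnames(V) <- sprintf("V_%d", seq_len(ncol(U)))
  structure(
    list(U = U, d = d, V = V, means = m, weighting = weighting,
         tips = rownames(infl$I), influence = infl, rel_tol = rel_tol),
    class = "pem_basis"
  )
}

#' @export
print.pem_basis <- function(x, ...) {
  cat(sprintf("PEM basis: %d tips, %d eigenvectors (a = %g, psi = %g)\n",
              nrow(x$U), ncol(x$U), x$weighting$a, x$weighting$psi))
  invisible(x)
}

#' Score a tip location against a PEM basis
#'
#' Builds the target's influence row over the training edges — full weight
#' `w(phi)` for every edge completely traversed on the root-to-attachment
#' path, `w(traversed)` for the traversed portion of the attachment edge,
#' zero elsewhere — then centers it with the training column means and
#' projects: `scores = (row - means) %*% V %*% diag(1/d)`.  The pendant
#' edge contributes nothing (it would only add prediction variance).
#'
#' @param basis A [build_pem()] object.
#' @param loc A `tip_location` from [locate_targets()], or a list of them.
#' @return A numeric vector of length `k` (or a matrix, one row per
#'   location) on the same scale as the rows of `basis$U`.
#' @export
location_scores <- function(basis, loc) {
  stopifnot(inherits(basis, "pem_basis"))
  if (inherits(loc, "tip_location")) loc <- list(loc)
  et <- basis$influence$edges
  tree <- basis$influence$tree
  nn <- length(tree$tip.label) + tree$Nnode
  parent <- integer(nn); parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- root_node(tree)
  col_of_child <- integer(nn); col_of_child[et$child] <- et$index
  out <- matrix(NA_real_, length(loc), ncol(basis$U),
                dimnames = list(vapply(loc, `[[`, "", "label"),
                                colnames(basis$U)))
  for (i in seq_along(loc)) {
    l <- loc[[i]]
    e <- l$edge
    if (e < 1L || e > nrow(et))
      stop("attachment edge ", e, " not in training tree", call. = FALSE)
    phi <- et$length[e]
    if (l$traversed < 0 || l$traversed > phi + 1e-9)
      stop(sprintf("traversed length %g outside attachment edge (phi = %g)",
                   l$traversed, phi), call. = FALSE)
    full <- logical(nrow(et))
    v <- et$parent[e]  # edges above the attachment edge are fully traversed
    while (v != root) {
      full[col_of_child[v]] <- TRUE
      v <- parent[v]
    }
    wall <- edge_weights(et$length, basis$weighting)
    row <- numeric(nrow(et))
    row[full] <- wall[full]
    row[e] <- if (l$traversed == 0) 0 else
      edge_weights(min(l$traversed, phi), basis$weighting)
    out[i, ] <- (row - basis$means) %*% basis$V %*% diag(1 / basis$d,
                                                         length(basis$d))
  }
  if (length(loc) == 1L) out[1L, ] else out
}

#' Tip location of a training tip at its own position
#'
#' Convenience constructor used for self-consistency checks: scoring the
#' returned location reproduces that tip's own row of `basis$U`.
#'
#' @param infl An [influence_matrix()] object.
#' @param label A training tip label.
#' @return A `tip_location` with the tip's terminal edge fully traversed.
#' @export
training_tip_location <- function(infl, label) {
  stopifnot(inherits(infl, "influence_matrix"))
  e <- infl$edges$index[!is.na(infl$edges$child_label) &
                          infl$edges$child_label == label]
  if (!length(e)) stop("'", label, "' is not a training tip", call. = FALSE)
  structure(list(label = label, edge = e[1L],
                 traversed = infl$edges$length[e[1L]], pendant = 0),
            class = "tip_location")
}

#' Profile-likelihood estimate of the steepness parameter
#'
#' Maximizes the Gaussian log-likelihood of a centered response under the
#' covariance `sigma2 * Bw %*% t(Bw)` implied by the edge weighting, with
#' `sigma2` profiled out, over `a` in `[0, 1]` (`psi` is not identifiable
#' jointly with `sigma2` and is held at 1).
#'
#' @param infl An [influence_matrix()] object (>= 4 tips).
#' @param y Numeric response, one value per training tip (in `infl` row
#'   order, or named by tip).
#' @return List with `a` (the estimate), `logLik` at the optimum, and the
#'   profiled `sigma2`.
#' @export
estimate_steepness <- function(infl, y) {
  stopifnot(inherits(infl, "influence_matrix"))
  n <- nrow(infl$I)
  if (n < 4L) stop("need at least 4 training tips", call. = FALSE)
  if (!is.null(names(y))) y <- y[rownames(infl$I)]
  if (length(y) != n || anyNA(y) || any(!is.finite(y)))
    stop("y must be finite with one value per training tip", call. = FALSE)
  ll <- function(a) .steepness_loglik(infl, y, a)
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-6)
  ## optimize() never probes the interval ends; accept a boundary if better
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  if (all(!is.finite(vals)))
    stop("steepness estimation failed: singular covariance at all a",
         call. = FALSE)
  best <- which.max(vals)
  a_hat <- cand[best]
  fit <- .steepness_loglik(infl, y, a_hat, details = TRUE)
  list(a = a_hat, logLik = fit$ll, sigma2 = fit$sigma2)
}

.steepness_loglik <- function(infl, y, a, details = FALSE) {
  w <- edge_weights(infl$lengths, edge_weighting(a = a, psi = 1))
  Bw <- sweep(infl$I, 2L, w, `*`)
  S <- tcrossprod(Bw)
  n <- length(y)
  ## GLS-center y under S, then profile sigma2
  ch <- tryCatch(chol(S + diag(1e-12 * max(diag(S)), n)),
                 error = function(e) NULL)
  if (is.null(ch)) return(if (details) list(ll = -Inf, sigma2 = NA) else -Inf)
  Sinv1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Sinvy <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- sum(Sinvy) / sum(Sinv1)
  r <- y - mu
  Sinvr <- backsolve(ch, forwardsolve(t(ch), r))
  q <- sum(r * Sinvr)
  sigma2 <- q / n
  ldet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + ldet + n)
  if (details) list(ll = ll, sigma2 = sigma2) else ll
}
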