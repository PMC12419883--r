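## Candidate models: one optional histometric co-predictor plus forward-
## selected phylogenetic eigenvectors.  Selection adds the eigenvector with
## the lowest resulting AICc at each step and stops when AICc no longer
## improves.  The four-model grid (each single co-predictor + phylogeny,
## and phylogeny alone) is compared on R-squared with a Holm-Sidak
## adjusted overall F-test p-value.

PREDICTOR_COLS <- c("lnOsteo_volume", "lnCan_harmean", "lnCan_min")
RESPONSE_COLS <- c("RBC_width", "RBC_area", "RBC_length")

## Gaussian AICc for an OLS fit: k counts all estimated parameters
## (coefficients + residual variance).  Returns Inf when the small-sample
## correction denominator n - k - 1 is not positive.
.aicc <- function(rss, n, n_coef) {
  k <- n_coef + 1
  if (n - k - 1 <= 0) return(Inf)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.ols <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank,
       fitted = fit$fitted.values)
}

#' Forward stepwise selection of phylogenetic eigenvectors
#'
#' Starting from intercept plus the co-predictor columns `Z` (always
#' retained), greedily adds the eigenvector of `U` whose inclusion gives
#' the lowest AICc, stopping when no addition lowers AICc or `max_k`
#' eigenvectors are selected.  Ties are broken by the lowest eigenvector
#' index.  Selection also stops when the sample size can no longer support
#' the AICc correction term (`n - params - 1 <= 0`).
#'
#' @param U Eigenvector matrix (rows aligned with `y`).
#' @param y Numeric response.
#' @param Z Optional co-predictor matrix (may have 0 columns).
#' @param max_k Maximum number of eigenvectors to select.
#' @param criterion `"aicc"` (default: stop when AICc stops improving) or
#'   `"r2"` (greedy residual-sum-of-squares reduction up to `max_k`, the
#'   fit-maximizing reading of forward selection).
#' @return Integer vector of selected column indices of `U`, in selection
#'   order (possibly empty).
#' @export
forward_select_eigenvectors <- function(U, y, Z = NULL,
                                        max_k = ncol(U),
                                        criterion = c("aicc", "r2")) {
  criterion <- match.arg(criterion)
  n <- length(y)
  if (is.null(Z)) Z <- matrix(numeric(0), n, 0)
  Z <- as.matrix(Z)
  stopifnot(nrow(U) == n, nrow(Z) == n)
  max_k <- min(max_k, ncol(U))
  base <- cbind(`(Intercept)` = rep(1, n), Z)
  selected <- integer(0)
  current <- .aicc(.ols(base, y)$rss, n, ncol(base))
  cur_rss <- .ols(base, y)$rss
  while (length(selected) < max_k) {
    candidates <- setdiff(seq_len(ncol(U)), selected)
    stats_ <- vapply(candidates, function(j) {
      X <- cbind(base, U[, c(selected, j), drop = FALSE])
      f <- .ols(X, y)
      c(.aicc(f$rss, n, ncol(X)), f$rss)
    }, numeric(2L))
    if (criterion == "aicc") {
      aiccs <- stats_[1L, ]
      if (!any(is.finite(aiccs))) break
      best <- which.min(aiccs)  # which.min: first (lowest index) tie wins
      if (aiccs[best] >= current) break
      selected <- c(selected, candidates[best])
      current <- aiccs[best]
    } else {
      rsss <- stats_[2L, ]
      best <- which.min(rsss)
      if (rsss[best] >= cur_rss - 1e-14 * max(cur_rss, 1)) break
      selected <- c(selected, candidates[best])
      cur_rss <- rsss[best]
    }
  }
  selected
}

#' Candidate model specification
#'
#' @param response One of `RBC_width`, `RBC_area`, `RBC_length`.
#' @param co_predictor A single predictor column name (one of
#'   `lnOsteo_volume`, `lnCan_harmean`, `lnCan_min`) or `NULL` for the
#'   phylogeny-only model.
#' @param use_phylogeny Include forward-selected eigenvectors?
#' @param log_response Model the response on the natural-log scale
#'   (default `TRUE`; predictions are back-transformed by `exp`).
#' @return An object of class `candidate_model`.
#' @export
candidate_model <- function(response, co_predictor = NULL,
                            use_phylogeny = TRUE, log_response = TRUE) {
  response <- match.arg(response, RESPONSE_COLS)
  if (!is.null(co_predictor))
    co_predictor <- match.arg(co_predictor, PREDICTOR_COLS)
  structure(list(response = response, co_predictor = co_predictor,
                 use_phylogeny = use_phylogeny,
                 log_response = log_response),
            class = "candidate_model")
}

#' @keywords internal
model_id <- function(spec) {
  cp <- if (is.null(spec$co_predictor)) NULL else spec$co_predictor
  paste(c(cp, if (spec$use_phylogeny) "phylogeny"), collapse = " + ")
}

#' Fit one candidate model
#'
#' Ordinary least squares of the (optionally log-transformed) response on
#' an intercept, the co-predictor, and the forward-selected eigenvectors.
#' Reports R-squared, the overall F-test p-value against the intercept-only
#' model, and AICc.
#'
#' @param table A trait table as returned by [read_character_matrix()] or
#'   [simulate_traits()].
#' @param basis A [build_pem()] object whose tips are the training taxa.
#' @param spec A [candidate_model()].
#' @param max_k Maximum eigenvectors for selection; default
#'   `n - ncol(Z) - 3`, which keeps at least 2 residual degrees of freedom.
#' @param criterion Forward-selection criterion, see
#'   [forward_select_eigenvectors()].
#' @return An object of class `fitted_candidate_model`.
#' @export
fit_candidate_model <- function(table, basis, spec, max_k = NULL,
                                criterion = c("aicc", "r2")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(basis, "pem_basis"), inherits(spec, "candidate_model"))
  train <- basis$tips
  rows <- match(train, table$taxon)
  if (anyNA(rows))
    stop("basis tips missing from trait table: ",
         paste(train[is.na(rows)], collapse = ", "), call. = FALSE)
  y_raw <- table[[spec$response]][rows]
  if (anyNA(y_raw))
    stop("response '", spec$response, "' missing for training taxa: ",
         paste(train[is.na(y_raw)], collapse = ", "), call. = FALSE)
  n <- length(y_raw)
  if (n < 5L) stop("need at least 5 training taxa with the response",
                   call. = FALSE)
  y <- if (spec$log_response) log(y_raw) else y_raw
  Z <- if (is.null(spec$co_predictor)) {
    matrix(numeric(0), n, 0)
  } else {
    zz <- table[[spec$co_predictor]][rows]
    if (anyNA(zz)) stop("co-predictor '", spec$co_predictor,
                        "' missing for training taxa", call. = FALSE)
    matrix(zz, ncol = 1, dimnames = list(NULL, spec$co_predictor))
  }
  if (is.null(max_k)) max_k <- max(0L, n - ncol(Z) - 3L)
  selected <- if (spec$use_phylogeny) {
    forward_select_eigenvectors(basis$U, y, Z, max_k = max_k,
                                criterion = criterion)
  } else integer(0)
  X <- cbind(`(Intercept)` = rep(1, n), Z,
             basis$U[, selected, drop = FALSE])
  if (ncol(X) > 1L) {
    kap <- kappa(X, exact = TRUE)
    if (kap > 1e10)
      stop("collinear design (condition number ", format(kap, digits = 3),
           ") in columns: ", paste(colnames(X), collapse = ", "),
           call. = FALSE)
  }
  fit <- .ols(X, y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) min(max(1 - fit$rss / sst, 0), 1) else NA_real_
  p_model <- ncol(X) - 1L
  p_value <- if (p_model >= 1L && fit$rss > 0 && n - p_model - 1L > 0) {
    f <- (sst - fit$rss) / p_model / (fit$rss / (n - p_model - 1L))
    stats::pf(f, p_model, n - p_model - 1L, lower.tail = FALSE)
  } else if (p_model >= 1L && fit$rss == 0) {
    0
  } else if (p_model == 0L) {
    1  # degenerate to the intercept-only null: nothing to test
  } else NA_real_
  structure(
    list(spec = spec, coefficients = fit$coef, selected = selected,
         r_squared = r2, p_value = p_value,
         aicc = .aicc(fit$rss, n, ncol(X)),
         sigma2 = fit$rss / max(1L, n - ncol(X)),
         fitted = fit$fitted, taxa = train, n = n,
         model_id = model_id(spec)),
    class = "fitted_candidate_model"
  )
}

#' @export
print.fitted_candidate_model <- function(x, ...) {
  cat(sprintf(
    "model [%s] ~ %s: %d eigenvector(s), R2 = %.4f, p = %.4g, AICc = %.2f\n",
    x$spec$response, x$model_id, length(x$selected), x$r_squared,
    x$p_value, x$aicc))
  invisible(x)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Sorts the p-values ascending and applies the Sidak formula with a
#' step-down exponent: adjusted `p_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`,
#' capped at 1, then restores input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
holm_sidak_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ## -expm1(k * log1p(-p)) == 1 - (1 - p)^k, accurate for tiny p
  adj <- -expm1((m - seq_len(m) + 1) * log1p(-ps))
  adj <- pmin(cummax(pmax(adj, ps)), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Fit and compare the four-candidate-model grid
#'
#' Fits, for one response, each single co-predictor combined with the
#' phylogenetic eigenvectors and a phylogeny-only model, then ranks them.
#' The best model is the one with the highest R-squared; raw overall-F
#' p-values are reported alongside their Holm-Sidak adjustment across the
#' grid.
#'
#' @inheritParams fit_candidate_model
#' @param response Response column name.
#' @param log_response Passed to [candidate_model()].
#' @return An object of class `model_comparison`: list with `table` (data
#'   frame: model, r_squared, p_value, p_adjusted, aicc, n_eigenvectors,
#'   best, error) and `fits` (the `fitted_candidate_model` objects, `NULL`
#'   where a fit failed).
#' @export
model_comparison_table <- function(table, basis, response,
                                   log_response = TRUE, max_k = NULL,
                                   criterion = c("aicc", "r2")) {
  criterion <- match.arg(criterion)
  specs <- c(lapply(PREDICTOR_COLS, function(cp)
    candidate_model(response, cp, TRUE, log_response)),
    list(candidate_model(response, NULL, TRUE, log_response)))
  fits <- lapply(specs, function(s) {
    tryCatch(fit_candidate_model(table, basis, s, max_k = max_k,
                                 criterion = criterion),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1L), "error")
  df <- data.frame(
    model = vapply(specs, model_id, character(1L)),
    r_squared = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$r_squared, numeric(1L)),
    p_value = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$p_value, numeric(1L)),
    p_adjusted = NA_real_,
    aicc = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$aicc, numeric(1L)),
    n_eigenvectors = vapply(fits, function(f)
      if (inherits(f, "error")) NA_integer_ else length(f$selected),
      integer(1L)),
    best = FALSE,
    error = vapply(fits, function(f)
      if (inherits(f, "error")) conditionMessage(f) else "", character(1L)),
    stringsAsFactors = FALSE
  )
  sel <- ok & !is.na(df$p_value)
  if (any(sel)) df$p_adjusted[sel] <- holm_sidak_adjust(df$p_value[sel])
  if (any(ok)) {
    best <- which(df$r_squared == max(df$r_squared[ok], na.rm = TRUE))[1L]
    df$best[best] <- TRUE
  }
  fits[!ok] <- list(NULL)
  structure(list(table = df, fits = fits, response = response),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison for", x$response, "\n")
  print(x$table[, c("model", "r_squared", "p_value", "p_adjusted",
                    "aicc", "best")], row.names = FALSE)
  invisible(x)
}

#' Best model of a comparison
#'
#' @param comparison A [model_comparison_table()] result.
#' @return The `fitted_candidate_model` flagged as best.
#' @export
best_model <- function(comparison) {
  stopifnot(inherits(comparison, "model_comparison"))
  i <- which(comparison$table$best)
  if (!length(i)) stop("no successful fit in comparison", call. = FALSE)
  comparison$fits[[i]]
}
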