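#' Simple linear trend model
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], reporting the
#' slope with its standard error, two-sided t-test p-value, and adjusted
#' R-squared — the summary statistics used for every travel-time trend.
#'
#' @param x Predictor vector (nonzero variance, n >= 3).
#' @param y Response vector.
#' @param xname,yname Optional names carried into the result.
#' @return A `regression_result`: list with `terms` (data.frame: term,
#'   estimate, se, p), `intercept`, `adj_r2`, `n`, `response_name`, `model`
#'   (the underlying `lm`).
#' @export
fit_linear <- function(x, y, xname = "x", yname = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate design: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  .regression_result(fit, response_name = yname, term_names = xname)
}

.regression_result <- function(fit, response_name = "y", term_names = NULL) {
  sm <- summary(fit)
  co <- sm$coefficients
  keep <- rownames(co) != "(Intercept)"
  terms <- data.frame(term = rownames(co)[keep],
                      estimate = co[keep, 1L], se = co[keep, 2L],
                      p = co[keep, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (!is.null(term_names) && nrow(terms) == length(term_names))
    terms$term <- term_names
  structure(list(terms = terms,
                 intercept = unname(co["(Intercept)", 1L]),
                 adj_r2 = sm$adj.r.squared,
                 n = length(stats::residuals(fit)),
                 response_name = response_name,
                 model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear model for %s (n = %d, adj R^2 = %.3f)\n",
              x$response_name, x$n, x$adj_r2))
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  %s: %.4g +/- %.3g (p = %.3g)\n", x$terms$term[i],
                x$terms$estimate[i], x$terms$se[i], x$terms$p[i]))
  invisible(x)
}

#' Backward-selection multiple regression
#'
#' Starts from the model containing every candidate predictor and
#' iteratively removes the predictor whose removal most improves the
#' criterion — AIC decrease (default, via [stats::step()]) or the largest
#' p-value above `alpha` — until no removal improves. Collinear designs are
#' rejected with the offending predictors named.
#'
#' @param data data.frame containing response and candidates.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor names.
#' @param criterion `"AIC"` or `"alpha"`.
#' @param alpha Removal threshold when `criterion = "alpha"` (default 0.05).
#' @return A `regression_result` for the final model (its `terms` may be
#'   empty for an intercept-only outcome).
#' @export
backward_select <- function(data, response, candidates,
                            criterion = c("AIC", "alpha"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(candidates %in% names(data)))
  data <- data[stats::complete.cases(data[, c(response, candidates)]), ,
               drop = FALSE]
  n <- nrow(data)
  if (n <= length(candidates) + 2L)
    stop("need n > candidates + 2", call. = FALSE)
  full_formula <- stats::reformulate(candidates, response)
  fit <- stats::lm(full_formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (criterion == "AIC") {
    final <- stats::step(fit, direction = "backward", trace = 0,
                         scope = list(lower = stats::reformulate("1", response)))
  } else {
    current <- candidates
    repeat {
      if (length(current) == 0L) {
        final <- stats::lm(stats::reformulate("1", response), data = data)
        break
      }
      final <- stats::lm(stats::reformulate(current, response), data = data)
      co <- summary(final)$coefficients
      keep <- rownames(co) != "(Intercept)"
      pv <- co[keep, 4L]
      names(pv) <- rownames(co)[keep]
      if (all(pv <= alpha)) break
      current <- setdiff(current, names(pv)[which.max(pv)])
    }
  }
  .regression_result(final, response_name = response)
}

#' Ordination of a dissimilarity matrix
#'
#' Principal coordinates analysis (default: deterministic
#' eigen-decomposition of the double-centred matrix, negative eigenvalues
#' reported) or nonmetric multidimensional scaling by stress minimization
#' from a PCoA start ([vegan::monoMDS()], fixed iteration cap and
#' tolerance).
#'
#' @param D Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k Number of axes (default 2).
#' @param method `"pcoa"` or `"nmds"`.
#' @return An `ordination`: list with `points` (samples x k), `eigenvalues`
#'   (PCoA; NULL for NMDS), `stress` (NMDS; NA for PCoA), `method`.
#' @export
ordinate <- function(D, k = 2L, method = c("pcoa", "nmds")) {
  method <- match.arg(method)
  M <- as.matrix(D)
  if (!isSymmetric(unname(M), tol = 1e-8) || any(abs(diag(M)) > 1e-12))
    stop("`D` must be symmetric with zero diagonal", call. = FALSE)
  if (all(M == 0)) {
    pts <- matrix(0, nrow(M), k,
                  dimnames = list(rownames(M), paste0("axis", seq_len(k))))
    return(structure(list(points = pts, eigenvalues = rep(0, nrow(M)),
                          stress = NA_real_, method = method),
                     class = "ordination"))
  }
  pc <- stats::cmdscale(stats::as.dist(M), k = k, eig = TRUE)
  pts <- pc$points
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  if (method == "pcoa") {
    structure(list(points = pts, eigenvalues = pc$eig, stress = NA_real_,
                   method = "pcoa"),
              class = "ordination")
  } else {
    nm <- vegan::monoMDS(stats::as.dist(M), y = pts, k = k,
                         maxit = 500L, sratmax = 1 - 1e-6)
    pts2 <- nm$points
    colnames(pts2) <- paste0("axis", seq_len(ncol(pts2)))
    structure(list(points = pts2, eigenvalues = NULL, stress = nm$stress,
                   method = "nmds"),
              class = "ordination")
  }
}

#' Fit an environmental vector onto an ordination
#'
#' The squared multiple correlation of the variable regressed on the
#' ordination axes, with a permutation p-value: the fraction of
#' permutations of `v` whose r2 meets or exceeds the observed one, with
#' `(b + 1) / (B + 1)` smoothing. Missing values are dropped pairwise with
#' a warning.
#'
#' @param ord An `ordination` (or a samples x k coordinate matrix).
#' @param v Environmental variable, one value per sample.
#' @param permutations Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return List with `r2`, `p_perm`, `n`, `permutations`.
#' @export
vector_fit <- function(ord, v, permutations = 999L, seed = 1L) {
  pts <- if (inherits(ord, "ordination")) ord$points else as.matrix(ord)
  if (length(v) != nrow(pts)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(v)
  if (!all(ok)) {
    warning(sum(!ok), " missing values dropped pairwise")
    v <- v[ok]; pts <- pts[ok, , drop = FALSE]
  }
  if (stats::var(v) == 0)
    stop("degenerate variable: zero variance", call. = FALSE)
  X <- cbind(1, pts)
  qx <- qr(X)
  r2_of <- function(vv) {
    res <- qr.resid(qx, vv)
    1 - sum(res^2) / sum((vv - mean(vv))^2)
  }
  r2 <- r2_of(v)
  set.seed(derive_seed(seed, "vector_fit"))
  hits <- 0L
  for (b in seq_len(permutations))
    if (r2_of(sample(v)) >= r2) hits <- hits + 1L
  list(r2 = r2, p_perm = (hits + 1) / (permutations + 1),
       n = length(v), permutations = permutations)
}

#' Richness response to discharge doubling
#'
#' Regresses observed ASV richness on log2 of the discharge ratio, so the
#' slope is the richness change per doubling in discharge — the only
#' functional form under which "a doubling in discharge adds s ASVs" is
#' independent of the baseline.
#'
#' @param ratios Discharge ratios (>= 1), from [discharge_ratio()].
#' @param richness Observed ASV counts.
#' @return A `regression_result` with the slope in ASVs per discharge
#'   doubling.
#' @export
discharge_richness_model <- function(ratios, richness) {
  if (any(!is.finite(ratios)) || any(ratios < 1))
    stop("ratios must be >= 1", call. = FALSE)
  fit_linear(log2(ratios), richness,
             xname = "log2_discharge_ratio", yname = "observed_asvs")
}
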