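#' Fit configuration for the LP estimator
#'
#' Settings for [unseen_fit]. The grid spans `[1/(x_min_factor * k), 1]`
#' geometrically; counts up to `i_fit` enter the linear programme while
#' variants observed more often are pinned empirically at frequency `i/k`
#' (their frequency is already well determined). Weights `w_i` stabilize the
#' Poisson-scale variance of the count discrepancies. The second stage
#' minimizes total variant mass among histograms whose discrepancy stays
#' within `1 + slack` of the stage-one optimum; with the default
#' `slack = 0` it acts purely as a tie-break among exact optima, resolving
#' solver degeneracy without trading fit quality for mass reduction (a
#' positive budget strips the sub-`1/k` mass that extrapolation relies on
#' and biases discovery-curve predictions low).
#'
#' @param x_min_factor grid lower-bound factor `r`; grid starts at `1/(r k)`.
#' @param ratio geometric grid step (> 1).
#' @param i_fit largest occurrence count fitted by the LP (>= 1).
#' @param weights `"inv_sqrt"` for `w_i = 1/sqrt(1 + F_i)` or `"uniform"`.
#' @param mass_penalty coefficient (>= 0) on total grid mass added to the
#'   stage-one objective; 0 leaves regularization entirely to stage two.
#' @param slack stage-two tolerance: discrepancy may exceed the stage-one
#'   optimum by this relative amount while total mass is minimized.
#' @param solver_tol numeric tolerance passed to the LP backend.
#' @param approx kernel mode, see [binomial_kernel].
#' @param seed integer seed for stochastic steps (partitioning).
#' @return a list of class `"fit_config"`.
#' @export
fit_config <- function(x_min_factor = 50, ratio = 1.05, i_fit = 50,
                       weights = c("inv_sqrt", "uniform"),
                       mass_penalty = 0, slack = 0,
                       solver_tol = 1e-10, approx = c("auto", "exact", "poisson"),
                       seed = 0) {
  weights <- match.arg(weights)
  approx <- match.arg(approx)
  stopifnot(x_min_factor > 0, ratio > 1, i_fit >= 1, mass_penalty >= 0,
            slack >= 0, solver_tol > 0)
  structure(list(x_min_factor = x_min_factor, ratio = ratio,
                 i_fit = as.integer(i_fit), weights = weights,
                 mass_penalty = mass_penalty, slack = slack,
                 solver_tol = solver_tol, approx = approx,
                 seed = as.integer(seed)),
            class = "fit_config")
}

.fit_weights <- function(F_obs, mode) {
  if (mode == "uniform") rep(1, length(F_obs)) else 1 / sqrt(1 + F_obs)
}

# Two-stage LP over grid masses h >= 0.
# Stage 1: minimize sum_i w_i |(B h)_i - F_i|  (+ mass_penalty * sum h).
# Stage 2: minimize sum h subject to stage-1 objective <= opt * (1 + slack).
# Rows with target F_i <= 0 need no auxiliary variable: since (B h)_i >= 0,
# |(B h)_i - F_i| = (B h)_i + |F_i|, linear in h, so those rows fold into the
# objective. This also removes the degenerate zero-rhs constraints that the
# tableau solver handles poorly.
.solve_histogram_lp <- function(B, F_target, w, config) {
  J <- ncol(B)
  pos <- which(F_target > 0)
  zer <- setdiff(seq_along(F_target), pos)
  a_h <- if (length(zer)) colSums(w[zer] * B[zer, , drop = FALSE]) else numeric(J)
  const <- sum(w[zer] * abs(F_target[zer]))
  n_aux <- length(pos)
  if (n_aux == 0L) {
    # pure linear objective in h; optimum is h = 0
    return(list(h = numeric(J), objective = const,
                status = c("trivial", "trivial")))
  }
  Bp <- B[pos, , drop = FALSE]
  A1 <- cbind(Bp, -diag(n_aux))          # (B h)_i - t_i <= F_i
  A2 <- cbind(Bp, diag(n_aux))           # (B h)_i + t_i >= F_i
  b <- F_target[pos]
  s1 <- boot::simplex(a = c(a_h + config$mass_penalty, w[pos]),
                      A1 = A1, b1 = b, A2 = A2, b2 = b,
                      maxi = FALSE, eps = config$solver_tol,
                      n.iter = 50 * (J + 2 * n_aux))
  if (s1$solved != 1)
    stop("LP stage 1 did not reach an optimum (solver status ",
         s1$solved, ")")
  bound <- s1$value * (1 + config$slack) + config$solver_tol
  s2 <- boot::simplex(a = c(rep(1, J), rep(0, n_aux)),
                      A1 = rbind(A1, c(a_h, w[pos])),
                      b1 = c(b, bound),
                      A2 = A2, b2 = b,
                      maxi = FALSE, eps = config$solver_tol,
                      n.iter = 50 * (J + 2 * n_aux))
  if (s2$solved != 1)
    stop("LP stage 2 did not reach an optimum (solver status ",
         s2$solved, ")")
  h <- s2$soln[seq_len(J)]
  h[h < 0 & h > -config$solver_tol] <- 0
  h <- pmax(h, 0)
  obj <- sum(w[pos] * abs(as.vector(Bp %*% h) - b)) + sum(a_h * h) + const
  list(h = h, objective = obj, status = c("optimal", "optimal"))
}

#' Recover a frequency histogram from an observed SFS
#'
#' The core estimator: finds non-negative grid masses `h_j` minimizing the
#' weighted discrepancy `sum_i w_i | sum_j h_j bin(x_j, k, i) - F_i |` over
#' occurrence counts `i = 1..i_fit`, by linear programming (absolute values
#' linearized with auxiliary variables). Variants observed more than `i_fit`
#' times are handled empirically: they are placed in the histogram's
#' frequent part at frequency `i/k` with count `F_i`, and their expected
#' contribution to the fitted counts is subtracted from the LP target. A
#' second LP stage minimizes the total recovered mass subject to keeping the
#' discrepancy within `1 + slack` of its optimum (by default among exact
#' optima only), breaking ties among the otherwise under-determined
#' solutions toward the smallest consistent total.
#'
#' @param x an [sfs] object.
#' @param config a [fit_config].
#' @return An object of class `"unseen_fit"`: list with `histogram`
#'   ([freq_histogram]), `objective_value` (achieved weighted discrepancy
#'   over the fitted counts), `sfs`, `config`, and `diagnostics` (solver
#'   status, per-count residuals, fitted count range).
#' @examples
#' k <- 200
#' F_i <- round(500 * dbinom(1:20, k, 0.02))
#' fit <- unseen_fit(sfs(setNames(F_i, 1:20), k), fit_config(i_fit = 20))
#' total_variants(fit$histogram)
#' @export
unseen_fit <- function(x, config = fit_config()) {
  stopifnot(inherits(x, "sfs"), inherits(config, "fit_config"))
  k <- x$k
  i_fit <- config$i_fit
  if (i_fit > k) {
    warning("i_fit lowered to k = ", k)
    i_fit <- k
  }
  grid <- build_grid(1 / (config$x_min_factor * k), 1, config$ratio)
  if (sfs_total(x) == 0) {
    warning("empty SFS: returning zero histogram")
    h <- freq_histogram(grid, numeric(length(grid$points)))
    return(structure(list(histogram = h, objective_value = 0,
                          sfs = x, config = config,
                          diagnostics = list(status = "empty",
                                             residuals = numeric(0),
                                             i_fit = i_fit)),
                     class = "unseen_fit"))
  }
  F_obs <- sfs_vector(x, i_max = i_fit)
  # empirical frequent part: counts above i_fit
  high <- x$i > i_fit
  frequent <- if (any(high))
    data.frame(freq = x$i[high] / k, count = x$n[high])
  F_target <- F_obs
  if (any(high)) {
    for (m in which(high))
      F_target <- F_target -
        x$n[m] * binomial_kernel(x$i[m] / k, k, 1:i_fit, config$approx)
  }
  w <- .fit_weights(F_obs, config$weights)
  B <- mixing_matrix(grid, k, i_fit, config$approx)[-1, , drop = FALSE]  # rows i=1..i_fit
  sol <- .solve_histogram_lp(B, F_target, w, config)
  h <- freq_histogram(grid, sol$h, frequent = frequent)
  resid <- expected_sfs(h, k, i_fit, config$approx)[-1] - F_obs
  structure(list(histogram = h,
                 objective_value = sum(w * abs(resid)),
                 sfs = x, config = config,
                 diagnostics = list(status = sol$status,
                                    residuals = resid,
                                    i_fit = i_fit)),
            class = "unseen_fit")
}

#' @export
print.unseen_fit <- function(x, ...) {
  cat("LP frequency-distribution fit\n",
      " k =", x$sfs$k, "alleles; D =", format(sfs_total(x$sfs), big.mark = ","),
      "observed variants\n",
      " recovered T =", format(round(total_variants(x$histogram)), big.mark = ","),
      "variants; objective =", format(x$objective_value, digits = 4), "\n")
  invisible(x)
}

#' Weighted SFS discrepancy of a histogram
#'
#' The objective the LP minimizes, as a pure function: the weighted absolute
#' difference between the expected SFS of `h` (grid plus frequent part) and
#' the observed counts, over `i = 1..i_fit`. Weights are computed from the
#' observed `F_i`, so the value is comparable across candidate histograms
#' and can certify LP optimality.
#'
#' @param h a [freq_histogram].
#' @param x an [sfs] object.
#' @param config a [fit_config].
#' @return the non-negative discrepancy.
#' @export
sfs_objective <- function(h, x, config = fit_config()) {
  stopifnot(inherits(h, "freq_histogram"), inherits(x, "sfs"))
  i_fit <- min(config$i_fit, x$k)
  F_obs <- sfs_vector(x, i_max = i_fit)
  w <- .fit_weights(F_obs, config$weights)
  e <- expected_sfs(h, x$k, i_fit, config$approx)[-1]
  sum(w * abs(e - F_obs))
}

#' Discovery curve predicted from a fit
#'
#' Evaluates the expected number of distinct variants at a set of cohort
#' sizes, `N = ploidy * individuals` alleles each.
#'
#' @param fit an [unseen_fit] (or a bare [freq_histogram]).
#' @param cohort_sizes numbers of individuals (non-negative).
#' @param ploidy alleles per individual (2 for autosomal human data).
#' @return data.frame with columns `individuals`, `alleles`,
#'   `expected_distinct`; non-decreasing in cohort size.
#' @export
predict_discovery_curve <- function(fit, cohort_sizes, ploidy = 2) {
  h <- if (inherits(fit, "unseen_fit")) fit$histogram else fit
  stopifnot(inherits(h, "freq_histogram"), all(cohort_sizes >= 0), ploidy >= 1)
  data.frame(individuals = cohort_sizes,
             alleles = ploidy * cohort_sizes,
             expected_distinct = expected_unique(h, ploidy * cohort_sizes))
}

#' Fit with partition-based uncertainty
#'
#' Fits each of a family of SFS independently (for example the 10 disjoint
#' allele partitions produced by [split_alleles]) and summarizes the
#' predicted discovery curves by their mean and standard deviation across
#' partitions — the SD band is the uncertainty estimate.
#'
#' @param sfs_list list of [sfs] objects, one per partition (at least 2
#'   usable: partitions whose SFS is empty are skipped with a warning).
#' @param cohort_sizes numbers of individuals at which to evaluate curves.
#' @param config a [fit_config].
#' @param ploidy alleles per individual.
#' @return list of class `"uncertain_fit"`: `curve` (data.frame
#'   `individuals`, `alleles`, `mean`, `sd`), `fits` (per-partition
#'   [unseen_fit]s), `predictions` (partitions x sizes matrix).
#' @export
fit_with_uncertainty <- function(sfs_list, cohort_sizes,
                                 config = fit_config(), ploidy = 2) {
  stopifnot(is.list(sfs_list), length(sfs_list) >= 2)
  usable <- vapply(sfs_list, function(s) sfs_total(s) > 0, logical(1))
  if (!all(usable))
    warning(sum(!usable), " empty partition(s) skipped")
  sfs_list <- sfs_list[usable]
  if (length(sfs_list) < 2)
    stop("fewer than 2 usable partitions")
  fits <- lapply(sfs_list, unseen_fit, config = config)
  preds <- t(vapply(fits, function(f)
    predict_discovery_curve(f, cohort_sizes, ploidy)$expected_distinct,
    numeric(length(cohort_sizes))))
  structure(list(curve = data.frame(individuals = cohort_sizes,
                                    alleles = ploidy * cohort_sizes,
                                    mean = colMeans(preds),
                                    sd = apply(preds, 2, stats::sd)),
                 fits = fits, predictions = preds),
            class = "uncertain_fit")
}
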