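#' Jackknife input summary
#'
#' The sufficient statistics of the third-order jackknife extrapolator: the
#' numbers of variants observed exactly once, twice and three times, the
#' total observed distinct count, and the sampled allele number. The
#' prediction depends on nothing else — which variants are the singletons is
#' irrelevant.
#'
#' @param F1,F2,F3 counts of variants observed exactly 1, 2, 3 times.
#' @param D total observed distinct variants (`>= F1 + F2 + F3`).
#' @param k sampled alleles (`>= 3`).
#' @return list of class `"jackknife_input"`.
#' @export
jackknife_input <- function(F1, F2, F3, D, k) {
  stopifnot(F1 >= 0, F2 >= 0, F3 >= 0, D >= F1 + F2 + F3, k >= 3)
  structure(list(F1 = F1, F2 = F2, F3 = F3, D = D, k = as.integer(k)),
            class = "jackknife_input")
}

#' @rdname jackknife_input
#' @param x an [sfs] object.
#' @export
as_jackknife_input <- function(x) {
  stopifnot(inherits(x, "sfs"))
  f <- sfs_vector(x, i_max = 3L)
  jackknife_input(f[1], f[2], f[3], sfs_total(x), x$k)
}

#' Default jackknife coefficient rule
#'
#' The coefficient functions `g_m(N, k)` of the third-order jackknife,
#' reconstructed from first principles (the published form lives in the
#' species-richness literature, not in a closed form here): the exact
#' rarefaction identity gives the expected distinct count at subsample sizes
#' `k - j` for `j = 0..3` purely in terms of `D, F1, F2, F3`
#' (`U(k-1) = D - F1/k`, `U(k-2) = D - 2 F1/k - F2/C(k,2)`, ...), and a
#' cubic polynomial in `1/n` through those four points is extrapolated to
#' `n = N` by Lagrange interpolation. The rule is exact for any discovery
#' curve polynomial of degree at most 3 in `1/n`, and self-consistency
#' `g_m(k, k) = 0` holds by construction. This reconstruction is a declared
#' default, exposed so alternative published rules can be plugged in.
#'
#' @param N target alleles (`>= k`).
#' @param k sampled alleles.
#' @return numeric `c(g1, g2, g3)`.
#' @export
jackknife_coefficients_rarefaction <- function(N, k) {
  u <- 1 / c(k, k - 1, k - 2, k - 3)   # interpolation nodes in 1/n
  ut <- 1 / N
  L <- vapply(1:4, function(j) prod((ut - u[-j]) / (u[j] - u[-j])), numeric(1))
  # U(k-j) = D + c1_j F1 + c2_j F2 + c3_j F3 (exact rarefaction)
  c1 <- c(0, -1 / k, -2 / k, -3 / k)
  c2 <- c(0, 0, -1 / choose(k, 2), -3 / choose(k, 2))
  c3 <- c(0, 0, 0, -1 / choose(k, 3))
  # sum(L) == 1, so the D term carries through with coefficient 1
  c(g1 = sum(L * c1), g2 = sum(L * c2), g3 = sum(L * c3))
}

#' Third-order jackknife extrapolation of distinct variants
#'
#' Predicts the total number of distinct variants in `N >= k` alleles as
#' `D + g1(N,k) F1 + g2(N,k) F2 + g3(N,k) F3`: the observed count plus a
#' parametric estimate of new discoveries driven by the rare tail of the
#' SFS. This is the classic comparator to the LP estimator; its parametric
#' form tends to underestimate when the frequency distribution is more
#' skewed toward ultra-rare variants than the cubic accumulation model
#' allows.
#'
#' @param input a [jackknife_input] (or an [sfs], converted automatically).
#' @param N target alleles, `N >= k` (extrapolation only).
#' @param coefficients coefficient rule `function(N, k) -> c(g1, g2, g3)`;
#'   any admissible rule must satisfy `g_m(k, k) = 0` so that the prediction
#'   at `N = k` equals `D` exactly.
#' @return predicted distinct-variant count (vectorized over `N`).
#' @examples
#' jackknife_predict(jackknife_input(100, 40, 20, 500, 1000), N = 10000)
#' @export
jackknife_predict <- function(input, N,
                              coefficients = jackknife_coefficients_rarefaction) {
  if (inherits(input, "sfs")) input <- as_jackknife_input(input)
  stopifnot(inherits(input, "jackknife_input"))
  if (any(N < input$k))
    stop("'N' must be >= k (the jackknife is extrapolation-only)")
  vapply(N, function(n) {
    g <- coefficients(n, input$k)
    input$D + g[1] * input$F1 + g[2] * input$F2 + g[3] * input$F3
  }, numeric(1))
}
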