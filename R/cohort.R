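#' Hypergeometric downsampling of an allele count
#'
#' Reduces an observed count of `ac` alternate alleles among `an` called
#' alleles to a subsample of `n_target` alleles drawn without replacement.
#' `"sampled"` mode draws from the hypergeometric law; `"expected"` mode
#' returns the mean `ac * n_target / an` (variance-free, useful for
#' deterministic tests and expected-value pipelines).
#'
#' @param ac alternate allele count(s), `0 <= ac <= an` (vectorized).
#' @param an total called alleles (vectorized).
#' @param n_target alleles to keep, `<= an`.
#' @param mode `"expected"` or `"sampled"`.
#' @param seed optional integer seed for sampled mode (`NULL` uses the
#'   current RNG stream).
#' @return downsampled count(s): real in expected mode, integer in sampled
#'   mode.
#' @examples
#' downsample_count(4, 100, 50)  # 2
#' @export
downsample_count <- function(ac, an, n_target, mode = c("expected", "sampled"),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (any(ac < 0) || any(ac > an)) stop("'ac' must satisfy 0 <= ac <= an")
  if (any(n_target > an)) stop("'n_target' must be <= an")
  if (mode == "expected") return(ac * n_target / an)
  draw <- function() stats::rhyper(length(ac), ac, an - ac, n_target)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Census cohort specification
#'
#' Describes a demographically weighted cohort: the fraction of individuals
#' drawn from each ancestry population, the total cohort size, and the
#' ploidy. The shipped default weights in examples and the command line are
#' placeholders — any claim about a real demography must supply the actual
#' proportions.
#'
#' @param weights named non-negative fractions summing to 1; names are
#'   population codes matching the variant records.
#' @param individuals total cohort size (> 0).
#' @param ploidy alleles per individual.
#' @return list of class `"census_spec"`.
#' @export
census_spec <- function(weights, individuals, ploidy = 2) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(weights >= 0), individuals > 0, ploidy >= 1)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1")
  structure(list(weights = weights, individuals = individuals,
                 ploidy = ploidy),
            class = "census_spec")
}

#' Census-matched SFS from multi-population records
#'
#' Synthesizes the SFS of a demographically weighted cohort: each
#' population's allele counts are hypergeometrically downsampled to that
#' population's target allele share (`weight * individuals * ploidy`),
#' summed across populations, and binned into an SFS with
#' `k = individuals * ploidy`. Records whose summed count reaches 0 drop
#' out — they become part of the unseen set the estimator infers. If some
#' population cannot supply its share, the whole cohort is scaled down to
#' the binding constraint with a warning.
#'
#' @param records a [read_sites_vcf] data.frame.
#' @param census a [census_spec]; weight names must match record populations.
#' @param filter optional [class_filter].
#' @param mode `"sampled"` (a realized subcohort) or `"expected"`
#'   (variance-free, counts rounded).
#' @param seed integer seed for sampled mode.
#' @param label provenance tag.
#' @return an [sfs] object with `k = individuals * ploidy` (after any
#'   scale-down).
#' @export
census_matched_sfs <- function(records, census, filter = NULL,
                               mode = c("sampled", "expected"), seed = 0,
                               label = "census-matched") {
  mode <- match.arg(mode)
  stopifnot(inherits(census, "census_spec"))
  records <- filter_records(records, filter)
  pops <- names(census$weights)
  have <- attr(records, "populations")
  missing_p <- setdiff(pops, have)
  if (length(missing_p))
    stop("population(s) absent from records: ", paste(missing_p, collapse = ", "))
  an_pop <- vapply(pops, function(p) min(records[[paste0("an_", p)]]), numeric(1))
  total_alleles <- census$individuals * census$ploidy
  targets <- census$weights * total_alleles
  scale <- min(ifelse(targets > 0, an_pop / targets, Inf))
  if (scale < 1) {
    warning("requested cohort exceeds available alleles; scaling total by ",
            format(scale, digits = 3))
    targets <- targets * scale
  }
  targets <- largest_remainder_round(targets)
  k <- sum(targets)
  ac_sum <- numeric(nrow(records))
  doit <- function() {
    for (j in seq_along(pops)) {
      p <- pops[j]
      if (targets[j] == 0) next
      ac_p <- records[[paste0("ac_", p)]]
      an_p <- records[[paste0("an_", p)]]
      d <- downsample_count(ac_p, an_p, targets[j], mode = mode)
      ac_sum <<- ac_sum + if (mode == "expected") round(d) else d
    }
  }
  if (mode == "sampled") with_seed(seed, doit()) else doit()
  ac_sum <- ac_sum[ac_sum > 0]
  sfs(table(ac_sum), k = k, label = label)
}

#' Randomly partition cohort alleles into disjoint groups
#'
#' Splits the `k` alleles of a cohort into `n_groups` disjoint subsets of
#' (near-)equal size — any remainder alleles go one each to the first
#' groups — and distributes every variant's allele count across the groups
#' by a multivariate hypergeometric draw (sampling alleles without
#' replacement). The per-variant group counts sum back to the original
#' count exactly.
#'
#' @param ac vector of observed per-variant allele counts (all `>= 1`).
#' @param k total cohort alleles.
#' @param n_groups number of partitions, `2 <= n_groups <= k`.
#' @param seed integer seed.
#' @return list of class `"allele_partition"`: `counts` (variants x groups
#'   integer matrix), `k_g` (per-group allele numbers), `sfs_list` (one
#'   [sfs] per group, built from its nonzero counts).
#' @export
split_alleles <- function(ac, k, n_groups, seed = 0) {
  if (inherits(ac, "sim_cohort")) { k <- ac$k; ac <- ac$ac[ac$ac > 0] }
  stopifnot(all(ac >= 1), all(ac <= k))
  if (n_groups < 2) stop("'n_groups' must be >= 2")
  if (n_groups > k) stop("'n_groups' must be <= k")
  k_g <- rep(k %/% n_groups, n_groups)
  extra <- k %% n_groups
  if (extra > 0) k_g[seq_len(extra)] <- k_g[seq_len(extra)] + 1L
  counts <- matrix(0L, length(ac), n_groups)
  with_seed(seed, {
    a_rem <- ac
    alleles_rem <- k
    for (g in seq_len(n_groups - 1L)) {
      x <- stats::rhyper(length(a_rem), a_rem, alleles_rem - a_rem, k_g[g])
      counts[, g] <- x
      a_rem <- a_rem - x
      alleles_rem <- alleles_rem - k_g[g]
    }
    counts[, n_groups] <- a_rem
  })
  sfs_list <- lapply(seq_len(n_groups), function(g) {
    cg <- counts[counts[, g] > 0, g]
    sfs(table(cg), k = k_g[g], label = sprintf("partition %d/%d", g, n_groups))
  })
  structure(list(counts = counts, k_g = k_g, sfs_list = sfs_list),
            class = "allele_partition")
}

#' Partition-based validation of the estimator
#'
#' The validation protocol: randomly partition the cohort's alleles into
#' `n_groups` groups, train the estimator on each group's SFS alone (a
#' `1/n_groups` fraction of the alleles), predict the number of distinct
#' variants in the full cohort, and compare the predictions with the
#' observed full-cohort count. The spread (SD) of the per-group predictions
#' is the uncertainty estimate.
#'
#' @param ac per-variant allele counts of the full cohort (or a
#'   `"sim_cohort"` from [sample_cohort], from which `ac > 0` and `k` are
#'   taken).
#' @param k total cohort alleles (ignored when `ac` is a cohort object).
#' @param n_groups number of partitions (default 10).
#' @param config a [fit_config]; its `seed` drives the partitioning.
#' @return list of class `"partition_validation"`: `predicted` (per-group
#'   predicted distinct count at the full `k`), `mean`, `sd`, `observed`
#'   (the full-cohort distinct count), `k`, `k_g`, `fits`.
#' @export
validate_by_partition <- function(ac, k = NULL, n_groups = 10,
                                  config = fit_config()) {
  if (inherits(ac, "sim_cohort")) { k <- ac$k; ac <- ac$ac[ac$ac > 0] }
  stopifnot(!is.null(k), all(ac >= 1))
  part <- split_alleles(ac, k, n_groups, seed = config$seed)
  fits <- lapply(part$sfs_list, unseen_fit, config = config)
  predicted <- vapply(fits, function(f) expected_unique(f$histogram, k),
                      numeric(1))
  structure(list(predicted = predicted, mean = mean(predicted),
                 sd = stats::sd(predicted), observed = length(ac),
                 k = k, k_g = part$k_g, fits = fits),
            class = "partition_validation")
}

#' @export
print.partition_validation <- function(x, ...) {
  cat("Partition validation (", length(x$predicted), " groups)\n",
      "  observed distinct variants at k = ", x$k, ": ",
      format(x$observed, big.mark = ","), "\n",
      "  mean prediction from 1/", length(x$predicted), " of the alleles: ",
      format(round(x$mean), big.mark = ","),
      "  (SD ", format(round(x$sd)), ", rel. error ",
      sprintf("%+.1f%%", 100 * (x$mean - x$observed) / x$observed), ")\n",
      sep = "")
  invisible(x)
}
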