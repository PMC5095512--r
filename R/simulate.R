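#' Simulation scenario
#'
#' Describes a synthetic population of variants with known true frequencies,
#' to be binomially sampled into cohorts. Models:
#' \describe{
#'   \item{`pointmass`}{all `n_variants` at one frequency `x`.}
#'   \item{`mixture`}{explicit `components` data.frame (`freq`, `count`).}
#'   \item{`neutral_like`}{mass proportional to `1/x` on a geometric grid —
#'     the standard constant-size coalescent shape, a stand-in for
#'     selectively neutral (synonymous-like) variation.}
#'   \item{`beta`}{mass proportional to a Beta(`shape1`, `shape2`) density
#'     on the grid; the default `(0.5, 1000)` is heavily skewed toward
#'     ultra-rare frequencies, a stand-in for deleterious (LoF-like)
#'     variation kept rare by selection.}
#' }
#'
#' @param model one of `"pointmass"`, `"mixture"`, `"neutral_like"`, `"beta"`.
#' @param n_variants total number of variants (or genes) `T`.
#' @param k cohort alleles to sample.
#' @param seed integer seed; identical scenario + seed gives byte-identical
#'   output everywhere downstream.
#' @param x point-mass frequency (model `"pointmass"`).
#' @param components data.frame `freq`, `count` (model `"mixture"`; counts
#'   must sum to `n_variants`).
#' @param shape1,shape2 Beta parameters (model `"beta"`).
#' @param x_min_factor,ratio grid construction for the density models; the
#'   default matches [default_grid], so simulated truths lie exactly on the
#'   estimator's default grid.
#' @param populations optional named weights (summing to 1) describing
#'   ancestry groups for VCF fixtures; variant alleles are split across
#'   groups without replacement.
#' @param annotation optional annotation profile for VCF fixtures: a list
#'   with `consequence` (named fractions over synonymous/missense/lof/other),
#'   `lof_hc_frac`, `mutation` (named fractions over CpG_transition/
#'   nonCpG_transition/transversion), `n_genes`. Missing pieces take the
#'   documented defaults.
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(model = c("neutral_like", "beta", "pointmass", "mixture"),
                         n_variants, k, seed = 0,
                         x = NULL, components = NULL,
                         shape1 = 0.5, shape2 = 1000,
                         x_min_factor = 50, ratio = 1.05,
                         populations = NULL, annotation = NULL) {
  model <- match.arg(model)
  stopifnot(n_variants > 0, k >= 1)
  if (model == "pointmass") {
    if (is.null(x) || x <= 0 || x > 1)
      stop("'pointmass' needs a frequency 'x' in (0, 1]")
  }
  if (model == "mixture") {
    stopifnot(is.data.frame(components),
              all(c("freq", "count") %in% names(components)),
              all(components$freq > 0), all(components$freq <= 1),
              abs(sum(components$count) - n_variants) < 1e-9)
  }
  if (!is.null(populations)) {
    stopifnot(!is.null(names(populations)), all(populations >= 0),
              abs(sum(populations) - 1) < 1e-9)
  }
  ann_default <- list(
    consequence = c(synonymous = 0.3, missense = 0.5, lof = 0.15, other = 0.05),
    lof_hc_frac = 0.8,
    mutation = c(CpG_transition = 0.2, nonCpG_transition = 0.4,
                 transversion = 0.4),
    n_genes = 50)
  if (is.null(annotation)) annotation <- list()
  annotation <- utils::modifyList(ann_default, annotation)
  stopifnot(abs(sum(annotation$consequence) - 1) < 1e-9,
            abs(sum(annotation$mutation) - 1) < 1e-9)
  structure(list(model = model, n_variants = n_variants, k = as.integer(k),
                 seed = as.integer(seed), x = x, components = components,
                 shape1 = shape1, shape2 = shape2,
                 x_min_factor = x_min_factor, ratio = ratio,
                 populations = populations, annotation = annotation),
            class = "sim_scenario")
}

#' True frequency histogram of a scenario
#'
#' Deterministic given the scenario: the generating truth against which
#' estimates are judged. Density models distribute mass proportionally to
#' the model density times the geometric bin width, normalized so the total
#' equals `n_variants` exactly.
#'
#' @param scenario a [sim_scenario].
#' @return a [freq_histogram] with total mass `n_variants`.
#' @export
make_true_histogram <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  T_tot <- scenario$n_variants
  if (scenario$model == "pointmass")
    return(freq_histogram(scenario$x, T_tot))
  if (scenario$model == "mixture") {
    comp <- scenario$components[order(scenario$components$freq), ]
    return(freq_histogram(comp$freq, comp$count))
  }
  grid <- build_grid(1 / (scenario$x_min_factor * scenario$k), 1,
                     scenario$ratio)
  xs <- grid$points
  if (scenario$model == "neutral_like") {
    # point mass directly proportional to 1/x_j: the bulk of the variants
    # sit at the rarest representable frequencies
    mass <- 1 / xs
  } else {
    # beta: density integrated over geometric bins (midpoints between
    # neighbours), approximating frequencies drawn from Beta(shape1, shape2)
    dens <- stats::dbeta(xs, scenario$shape1, scenario$shape2)
    mid <- sqrt(xs[-1] * xs[-length(xs)])
    lo <- c(xs[1] / sqrt(scenario$ratio), mid)
    hi <- c(mid, xs[length(xs)] * sqrt(scenario$ratio))
    mass <- dens * (hi - lo)
  }
  mass <- mass / sum(mass) * T_tot
  freq_histogram(grid, mass)
}

#' Sample a cohort from a true histogram
#'
#' Realizes the binomial observation model: the histogram is rounded to an
#' integer number of variants per frequency (largest-remainder, preserving
#' the total exactly), and each variant's allele count in the cohort is an
#' independent `Binomial(k, x)` draw. Variants drawn at count 0 are the
#' unseen truth for recovery tests.
#'
#' @param h_true a [freq_histogram] (typically from [make_true_histogram]).
#' @param k cohort alleles.
#' @param seed integer seed.
#' @return list of class `"sim_cohort"`: `freq` (true per-variant
#'   frequencies), `ac` (per-variant counts, zeros included), `k`, `sfs`
#'   (from the nonzero counts), `n_unseen`, `n_variants`.
#' @export
sample_cohort <- function(h_true, k, seed = 0) {
  stopifnot(inherits(h_true, "freq_histogram"), k >= 1)
  xs <- h_true$grid$points
  ms <- h_true$mass
  if (!is.null(h_true$frequent)) {
    xs <- c(xs, h_true$frequent$freq)
    ms <- c(ms, h_true$frequent$count)
  }
  nv <- largest_remainder_round(ms)
  freq <- rep(xs, nv)
  ac <- with_seed(seed, stats::rbinom(length(freq), k, freq))
  obs <- ac[ac > 0]
  structure(list(freq = freq, ac = ac, k = as.integer(k),
                 sfs = sfs(table(obs), k = k, label = "simulated cohort"),
                 n_unseen = sum(ac == 0), n_variants = length(freq),
                 seed = as.integer(seed)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: k =", x$k, "alleles;",
      format(x$n_variants, big.mark = ","), "true variants,",
      format(x$n_variants - x$n_unseen, big.mark = ","), "observed,",
      format(x$n_unseen, big.mark = ","), "unseen\n")
  invisible(x)
}

#' Write a synthetic annotated sites VCF
#'
#' Serializes the observed variants of a simulated cohort as a minimal but
#' well-formed sites-level VCF with per-population `AC`/`AN` INFO fields, a
#' VEP-style `CSQ` field (`Allele|Consequence|SYMBOL|LoF`), and a `CONTEXT`
#' key carrying the reference trinucleotide, so that [read_sites_vcf]
#' round-trips it exactly. Consequence and mutation classes are assigned
#' deterministically so the class fractions in the file match the scenario's
#' annotation profile exactly (up to rounding to whole variants); gene
#' symbols cycle through `n_genes` synthetic genes.
#'
#' @param cohort a [sample_cohort] result.
#' @param scenario the generating [sim_scenario] (for populations and the
#'   annotation profile).
#' @param path output file.
#' @return `invisible(path)`.
#' @export
write_fixture_vcf <- function(cohort, scenario, path) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(scenario, "sim_scenario"))
  ac <- cohort$ac[cohort$ac > 0]
  n <- length(ac)
  k <- cohort$k
  ann <- scenario$annotation
  pops <- scenario$populations
  if (is.null(pops)) pops <- c(ALL = 1)
  an_pop <- largest_remainder_round(pops * k)
  names(an_pop) <- names(pops)

  # deterministic class assignment: exact fractions, assigned cyclically
  cons_n <- largest_remainder_round(ann$consequence * n)
  cons <- rep(names(ann$consequence), cons_n)
  mut_n <- largest_remainder_round(ann$mutation * n)
  mut <- rep(names(ann$mutation), mut_n)
  genes <- sprintf("GENE%03d", (seq_len(n) - 1L) %% ann$n_genes + 1L)
  n_hc <- largest_remainder_round(c(sum(cons == "lof") * ann$lof_hc_frac,
                                    sum(cons == "lof") * (1 - ann$lof_hc_frac)))
  lof_flag <- character(n)
  lof_flag[cons == "lof"] <- rep(c("HC", "LC"), n_hc)

  base_of <- function(class) switch(class,
    CpG_transition    = c(ref = "C", alt = "T", ctx = "ACG"),
    nonCpG_transition = c(ref = "A", alt = "G", ctx = "CAT"),
    transversion      = c(ref = "A", alt = "T", ctx = "CAT"))
  bam <- t(vapply(mut, base_of, character(3)))

  term_of <- c(synonymous = "synonymous_variant", missense = "missense_variant",
               lof = "stop_gained", other = "intron_variant")

  # split each variant's count across populations without replacement
  ac_pop <- matrix(0L, n, length(pops))
  colnames(ac_pop) <- names(pops)
  if (length(pops) > 1L) {
    with_seed(scenario$seed + 1L, {
      a_rem <- ac
      alleles_rem <- k
      for (j in seq_len(length(pops) - 1L)) {
        x <- stats::rhyper(n, a_rem, alleles_rem - a_rem, an_pop[j])
        ac_pop[, j] <- x
        a_rem <- a_rem - x
        alleles_rem <- alleles_rem - an_pop[j]
      }
      ac_pop[, length(pops)] <- a_rem
    })
  } else ac_pop[, 1] <- ac

  key <- function(base, pop) if (pop == "ALL") base else paste0(base, "_", pop)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=A,Type=Integer,Description="Alternate allele count (%s)">',
            vapply(names(pops), function(p) key("AC", p), character(1)), names(pops)),
    sprintf('##INFO=<ID=%s,Number=1,Type=Integer,Description="Total called alleles (%s)">',
            vapply(names(pops), function(p) key("AN", p), character(1)), names(pops)),
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations. Format: Allele|Consequence|SYMBOL|LoF">'),
    '##INFO=<ID=CONTEXT,Number=1,Type=String,Description="Reference trinucleotide context">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(n), function(v) {
    acs <- vapply(names(pops), function(p)
      sprintf("%s=%d", key("AC", p), ac_pop[v, p]), character(1))
    ans <- vapply(names(pops), function(p)
      sprintf("%s=%d", key("AN", p), an_pop[[p]]), character(1))
    csq <- sprintf("CSQ=%s|%s|%s|%s", bam[v, "alt"], term_of[[cons[v]]],
                   genes[v], lof_flag[v])
    paste(c(acs, ans, csq, sprintf("CONTEXT=%s", bam[v, "ctx"])),
          collapse = ";")
  }, character(1))
  body <- sprintf("1\t%d\t.\t%s\t%s\t100\tPASS\t%s",
                  1000L + 10L * seq_len(n), bam[, "ref"], bam[, "alt"], info)
  writeLines(c(header, body), path)
  invisible(path)
}
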