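#' Gene-level LoF spectrum
#'
#' Aggregates loss-of-function records to genes: the gene's allele count is
#' the sum of its LoF sites' alternate allele counts, capped at `k`. (Rare
#' LoF variants essentially never co-occur on one haplotype, and sites-only
#' data carries no phase, so the sum approximates the number of alleles
#' carrying at least one LoF.) The derived SFS — `F_i` = number of genes
#' with LoF count `i` — feeds the same LP estimator, whose histogram then
#' counts genes by their LoF carrier frequency.
#'
#' @param records LoF-filtered [read_sites_vcf] records (apply a
#'   [class_filter] with `lof_confidence = "HC"` first); rows without a gene
#'   label are skipped and counted.
#' @param k cohort allele number.
#' @param population population code, or `NULL` to pool across populations.
#' @return list of class `"gene_lof_spectrum"`: `gene_counts` (named, all
#'   `>= 1`), `sfs` (an [sfs] over genes), `k`, `n_unlabeled`.
#' @export
build_gene_spectrum <- function(records, k, population = NULL) {
  pops <- attr(records, "populations")
  if (nrow(records) > 0) {
    ac <- if (is.null(population))
      rowSums(records[, paste0("ac_", pops), drop = FALSE])
    else records[[paste0("ac_", population)]]
  } else ac <- numeric(0)
  gene <- if (nrow(records) > 0) records$gene else character(0)
  unlabeled <- is.na(gene) | !nzchar(gene)
  n_unlabeled <- sum(unlabeled)
  ac <- ac[!unlabeled]; gene <- gene[!unlabeled]
  gc <- tapply(ac, gene, sum)
  gc <- pmin(gc, k)
  gc <- gc[gc >= 1]
  s <- if (length(gc)) sfs(table(as.vector(gc)), k = k, label = "gene LoF")
  else sfs(numeric(0), k = k, label = "gene LoF")
  structure(list(gene_counts = gc, sfs = s, k = as.integer(k),
                 n_unlabeled = n_unlabeled),
            class = "gene_lof_spectrum")
}

#' Fit the gene-level LoF frequency histogram
#'
#' Runs the LP estimator on the gene SFS; the recovered histogram mass at
#' frequency `x` counts GENES whose LoF carrier allele frequency is `x`,
#' including genes with no LoF yet observed.
#'
#' @param spectrum a [build_gene_spectrum] result.
#' @param config a [fit_config].
#' @return the fitted [freq_histogram].
#' @export
fit_gene_histogram <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "gene_lof_spectrum"))
  unseen_fit(spectrum$sfs, config)$histogram
}

#' Bin histogram mass by frequency
#'
#' Partitions the total mass `T` into half-open frequency bins
#' `[lower, upper)` delimited by `edges`, plus the open bins below the first
#' and at/above the last edge. With the conventional edges
#' `c(1e-5, 1e-4, 1e-3)` this reproduces the standard gene-intolerance
#' bands: genes with LoF carrier frequency below 1e-5 are the strongly
#' LoF-intolerant set.
#'
#' @param h a [freq_histogram].
#' @param edges strictly increasing frequencies in (0, 1).
#' @return named numeric vector of bin masses; sums to `T` exactly.
#' @export
bin_genes <- function(h, edges = c(1e-5, 1e-4, 1e-3)) {
  stopifnot(inherits(h, "freq_histogram"), length(edges) >= 1)
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0) || any(edges >= 1))
    stop("'edges' must be strictly increasing frequencies in (0, 1)")
  brk <- c(0, edges, 1 + 1e-12)
  labels <- c(paste0("<", format(edges[1])),
              if (length(edges) > 1)
                paste0("[", format(edges[-length(edges)]), ",",
                       format(edges[-1]), ")"),
              paste0(">=", format(edges[length(edges)])))
  xs <- h$grid$points
  ms <- h$mass
  if (!is.null(h$frequent)) {
    xs <- c(xs, h$frequent$freq)
    ms <- c(ms, h$frequent$count)
  }
  idx <- findInterval(xs, brk, rightmost.closed = FALSE)  # [lower, upper)
  out <- vapply(seq_along(labels), function(b) sum(ms[idx == b]), numeric(1))
  stats::setNames(out, labels)
}

#' Expected number of genes with at least t LoF alleles
#'
#' For a cohort of `N` alleles, each gene at LoF carrier frequency `x`
#' contributes `P(Binomial(N, x) >= t)`; summed over the histogram (grid and
#' frequent part) this is the expected number of genes observed with at
#' least `t` LoF alleles. At `t = 1` this reduces exactly to the discovery
#' curve [expected_unique]; it is non-decreasing in `N`, non-increasing in
#' `t`, and saturates at the total `T` as `N` grows — the saturation level
#' bounds the number of genes that tolerate heterozygous inactivation.
#'
#' @param h a [freq_histogram] of gene LoF frequencies.
#' @param N_alleles cohort size in alleles (vectorized).
#' @param t LoF allele threshold (`>= 1`; `t <= N`).
#' @return expected gene counts, one per entry of `N_alleles`.
#' @export
genes_with_at_least <- function(h, N_alleles, t = 10) {
  stopifnot(inherits(h, "freq_histogram"), t >= 1)
  if (any(N_alleles < t)) stop("'t' must be <= N_alleles")
  vapply(N_alleles, function(n) {
    u <- sum(h$mass * stats::pbinom(t - 1, n, h$grid$points, lower.tail = FALSE))
    if (!is.null(h$frequent))
      u <- u + sum(h$frequent$count *
                     stats::pbinom(t - 1, n, h$frequent$freq, lower.tail = FALSE))
    u
  }, numeric(1))
}
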