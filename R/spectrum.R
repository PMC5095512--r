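#' Site-frequency spectrum
#'
#' An observed site-frequency spectrum (SFS): the counts `F_i` of variants
#' seen in exactly `i` out of `k` sampled alleles. Only observed classes
#' (`i >= 1`) are stored; the number of unobserved variants (`F_0`) is what
#' the estimator infers.
#'
#' @param counts named non-negative integer vector; names are the occurrence
#'   counts `i`, values are the numbers of variants `F_i`. Entries with
#'   `F_i = 0` are dropped. A `table` (e.g. `table(ac)`) is accepted.
#' @param k total number of sampled alleles (positive integer, `i <= k`).
#' @param label free-text provenance tag.
#' @return An object of class `"sfs"` with elements `i` (sorted occurrence
#'   counts), `n` (the matching `F_i`), `k`, `label`.
#' @examples
#' sfs(c(`1` = 120, `2` = 40, `5` = 3), k = 100)
#' @export
sfs <- function(counts, k, label = "") {
  if (is.table(counts)) counts <- stats::setNames(as.vector(counts), names(counts))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a single positive integer")
  if (length(counts) == 0L) {
    i <- integer(0); n <- numeric(0)
  } else {
    if (is.null(names(counts)))
      stop("'counts' must be named by occurrence count i")
    i <- as.integer(names(counts))
    n <- as.numeric(counts)
    if (anyNA(i)) stop("'counts' names must be integer occurrence counts")
    if (any(i < 1L) || any(i > k))
      stop("occurrence counts must satisfy 1 <= i <= k (F_0 is never stored)")
    if (any(n < 0) || any(n != round(n)))
      stop("all F_i must be non-negative integers")
    keep <- n > 0
    i <- i[keep]; n <- n[keep]
    if (anyDuplicated(i)) stop("duplicate occurrence counts in 'counts'")
    o <- order(i)
    i <- i[o]; n <- n[o]
  }
  structure(list(i = i, n = n, k = k, label = as.character(label)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("Site-frequency spectrum", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n  k =", x$k, "alleles;", length(x$i), "occupied counts; D =",
      format(sfs_total(x), big.mark = ","), "observed variants\n")
  invisible(x)
}

#' Total number of observed distinct variants
#'
#' @param x an [sfs] object.
#' @return `D = sum_i F_i`.
#' @export
sfs_total <- function(x) {
  stopifnot(inherits(x, "sfs"))
  sum(x$n)
}

#' Dense F_i vector of an SFS
#'
#' @param x an [sfs] object.
#' @param i_max largest count to report (default `max(i)` present).
#' @return numeric vector of length `i_max`; position `i` holds `F_i`.
#' @export
sfs_vector <- function(x, i_max = if (length(x$i)) max(x$i) else 0L) {
  stopifnot(inherits(x, "sfs"))
  out <- numeric(i_max)
  keep <- x$i <= i_max
  out[x$i[keep]] <- x$n[keep]
  out
}

#' Geometric frequency grid
#'
#' Builds the discrete set of population frequencies on which a histogram is
#' estimated: a geometric sequence from `x_min` with the given `ratio`,
#' capped at `x_max` (which is appended if not hit exactly). Geometric
#' spacing gives uniform relative resolution, which matters because the
#' unseen-variant mass lives at frequencies far below `1/k`.
#'
#' @param x_min,x_max frequency bounds, `0 < x_min <= x_max <= 1`.
#' @param ratio geometric step, `> 1` (ignored when `x_min == x_max`).
#' @return An object of class `"freq_grid"`: list with `points` (strictly
#'   increasing frequencies) and the construction parameters.
#' @examples
#' build_grid(0.25, 1, 2)$points  # 0.25 0.5 1
#' @export
build_grid <- function(x_min, x_max = 1, ratio = 1.05) {
  if (!is.numeric(x_min) || length(x_min) != 1L || is.na(x_min) || x_min <= 0)
    stop("'x_min' must be a single frequency > 0")
  if (!is.numeric(x_max) || length(x_max) != 1L || is.na(x_max) ||
      x_max > 1 || x_max < x_min)
    stop("'x_max' must satisfy x_min <= x_max <= 1")
  if (x_min == x_max) {
    points <- x_min
  } else {
    if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 1)
      stop("'ratio' must be > 1")
    n_steps <- floor(log(x_max / x_min) / log(ratio) + 1e-9)
    points <- x_min * ratio^(0:n_steps)
    if (points[length(points)] < x_max * (1 - 1e-9))
      points <- c(points, x_max)
    points[length(points)] <- min(points[length(points)], x_max)
  }
  structure(list(points = points, x_min = x_min, x_max = x_max, ratio = ratio),
            class = "freq_grid")
}

#' Default estimation grid for a cohort of k alleles
#'
#' The lower bound is `1 / (x_min_factor * k)`, so that frequencies down to
#' `x_min_factor` times rarer than a singleton are representable; unseen
#' variants live in this sub-`1/k` region.
#'
#' @param k sampled alleles.
#' @param x_min_factor lower-bound factor `r`, grid starts at `1/(r k)`.
#' @param ratio geometric step.
#' @return a [build_grid] result.
#' @export
default_grid <- function(k, x_min_factor = 50, ratio = 1.05) {
  stopifnot(k >= 1, x_min_factor > 0)
  build_grid(1 / (x_min_factor * k), 1, ratio)
}

#' @export
print.freq_grid <- function(x, ...) {
  cat("Frequency grid:", length(x$points), "points in [",
      format(x$points[1]), ",", format(x$points[length(x$points)]),
      "], ratio", x$ratio, "\n")
  invisible(x)
}

#' Frequency histogram
#'
#' The estimator's output and extrapolation's input: the estimated NUMBER of
#' distinct variants `h_j` at each grid frequency `x_j` (unnormalized
#' counts, not fractions), plus an optional `frequent` part listing
#' (frequency, count) pairs for common variants handled empirically outside
#' the linear programme.
#'
#' @param grid a [build_grid] result, or a numeric vector of strictly
#'   increasing frequencies.
#' @param mass non-negative numeric vector, one entry per grid point.
#' @param frequent optional data.frame with columns `freq` and `count`.
#' @return An object of class `"freq_histogram"`.
#' @export
freq_histogram <- function(grid, mass, frequent = NULL) {
  if (!inherits(grid, "freq_grid")) {
    pts <- as.numeric(grid)
    if (any(pts <= 0) || any(pts > 1) || is.unsorted(pts, strictly = TRUE))
      stop("'grid' points must be strictly increasing frequencies in (0, 1]")
    grid <- structure(list(points = pts, x_min = pts[1],
                           x_max = pts[length(pts)], ratio = NA_real_),
                      class = "freq_grid")
  }
  mass <- as.numeric(mass)
  if (length(mass) != length(grid$points))
    stop("'mass' must have one entry per grid point")
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("all masses must be finite and >= 0")
  if (!is.null(frequent)) {
    stopifnot(is.data.frame(frequent), all(c("freq", "count") %in% names(frequent)))
    frequent <- frequent[frequent$count > 0, c("freq", "count")]
    if (nrow(frequent) == 0L) frequent <- NULL
    else if (any(frequent$freq <= 0) || any(frequent$freq > 1))
      stop("frequent-part frequencies must lie in (0, 1]")
  }
  structure(list(grid = grid, mass = mass, frequent = frequent),
            class = "freq_histogram")
}

#' @export
print.freq_histogram <- function(x, ...) {
  cat("Frequency histogram: T =", format(total_variants(x), big.mark = ","),
      "variants on", length(x$grid$points), "grid points",
      if (!is.null(x$frequent))
        paste0("(+", nrow(x$frequent), " frequent classes)"), "\n")
  invisible(x)
}

#' Total variant count of a histogram
#'
#' @param h a [freq_histogram].
#' @return `T = sum_j h_j` plus the frequent-part counts.
#' @export
total_variants <- function(h) {
  stopifnot(inherits(h, "freq_histogram"))
  sum(h$mass) + if (is.null(h$frequent)) 0 else sum(h$frequent$count)
}

#' Binomial sampling kernel
#'
#' Probability that a variant at population frequency `x` is observed in
#' exactly `i` of `k` sampled alleles: the binomial pmf `bin(x, k, i)`.
#' With `approx = "poisson"` the Poisson(`k x`) pmf is used instead;
#' `"auto"` switches to Poisson when `k > 10000` and `k x <= 10`, where the
#' two agree to well under 1e-3 and the Poisson form is cheaper at
#' biobank-scale `k`.
#'
#' @param x frequency in `[0, 1]`.
#' @param k sampled alleles.
#' @param i occurrence count (vectorized), `0 <= i <= k`.
#' @param approx one of `"auto"`, `"exact"`, `"poisson"`.
#' @return probabilities in `[0, 1]`, same length as `i`.
#' @export
binomial_kernel <- function(x, k, i, approx = c("auto", "exact", "poisson")) {
  approx <- match.arg(approx)
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'x' must be a single frequency in [0, 1]")
  if (any(i < 0) || any(i > k)) stop("'i' must satisfy 0 <= i <= k")
  use_pois <- switch(approx,
                     exact = FALSE,
                     poisson = TRUE,
                     auto = (k > 10000 && k * x <= 10))
  if (use_pois) stats::dpois(i, k * x) else stats::dbinom(i, k, x)
}

#' Mixing matrix B[i, j] = bin(x_j, k, i)
#'
#' Maps a frequency histogram to its expected SFS: row `i` (for
#' `i = 0..i_max`), column `j` over the grid. Every column sums to at most 1
#' (exactly 1 when `i_max = k`).
#'
#' @param grid a [build_grid] result or numeric frequency vector.
#' @param k sampled alleles.
#' @param i_max largest occurrence count (row), `<= k`.
#' @inheritParams binomial_kernel
#' @return numeric matrix with `i_max + 1` rows (counts `0..i_max`, in
#'   `rownames`) and one column per grid point; attributes `k`, `i_max`.
#' @export
mixing_matrix <- function(grid, k, i_max, approx = c("auto", "exact", "poisson")) {
  approx <- match.arg(approx)
  pts <- if (inherits(grid, "freq_grid")) grid$points else as.numeric(grid)
  if (i_max > k) stop("'i_max' must be <= k")
  B <- vapply(pts, function(x) binomial_kernel(x, k, 0:i_max, approx),
              numeric(i_max + 1L))
  B <- matrix(B, nrow = i_max + 1L,
              dimnames = list(0:i_max, NULL))
  attr(B, "k") <- k
  attr(B, "i_max") <- i_max
  B
}

#' Expected site-frequency spectrum of a histogram
#'
#' The forward model: `E[F_i] = sum_j h_j bin(x_j, k, i)` plus the same sum
#' over the frequent part. When `i_max = k` the entries sum to the total
#' variant count `T` (conservation).
#'
#' @param h a [freq_histogram].
#' @param k sampled alleles.
#' @param i_max largest count computed (default `k`).
#' @inheritParams binomial_kernel
#' @return numeric vector of length `i_max + 1`, named `0..i_max`.
#' @export
expected_sfs <- function(h, k, i_max = k, approx = c("auto", "exact", "poisson")) {
  stopifnot(inherits(h, "freq_histogram"), k >= 1)
  approx <- match.arg(approx)
  B <- mixing_matrix(h$grid, k, i_max, approx)
  out <- as.vector(B %*% h$mass)
  if (!is.null(h$frequent)) {
    for (m in seq_len(nrow(h$frequent)))
      out <- out + h$frequent$count[m] *
        binomial_kernel(h$frequent$freq[m], k, 0:i_max, approx)
  }
  names(out) <- 0:i_max
  out
}

#' Expected number of distinct variants in N alleles
#'
#' The discovery curve `U(N) = sum_j h_j (1 - (1 - x_j)^N)` (the same
#' functional applied to the frequent part): each variant at frequency `x`
#' is seen in a cohort of `N` alleles unless all `N` draws miss it.
#' `U(0) = 0`, `U` is non-decreasing, and `U(N) -> T` as `N -> Inf`.
#'
#' @param h a [freq_histogram].
#' @param N number of alleles (vectorized, non-negative).
#' @return expected distinct-variant counts, one per entry of `N`.
#' @export
expected_unique <- function(h, N) {
  stopifnot(inherits(h, "freq_histogram"))
  if (any(N < 0)) stop("'N' must be non-negative")
  vapply(N, function(n) {
    u <- sum(h$mass * (1 - (1 - h$grid$points)^n))
    if (!is.null(h$frequent))
      u <- u + sum(h$frequent$count * (1 - (1 - h$frequent$freq)^n))
    u
  }, numeric(1))
}

#' Read / write an SFS table
#'
#' Two-column tab-separated text with header `count<TAB>num_variants`, one
#' row per occupied count, plus a `#k=<alleles>` comment line. The reader
#' tolerates blank lines and `#` comments.
#'
#' @param path file path.
#' @param x an [sfs] object (writer).
#' @return the [sfs] (reader) or `invisible(path)` (writer).
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  kline <- grep("^#k=", lines, value = TRUE)
  if (length(kline) != 1L) stop("SFS file must carry exactly one '#k=' line")
  k <- as.integer(sub("^#k=", "", kline))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("count", "num_variants") %in% names(df)))
    stop("SFS file must have columns 'count' and 'num_variants'")
  sfs(stats::setNames(df$num_variants, df$count), k = k,
      label = basename(path))
}

#' @rdname read_sfs
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d", x$k), con)
  writeLines("count\tnum_variants", con)
  if (length(x$i))
    writeLines(sprintf("%d\t%s", x$i, format(x$n, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' Read / write a frequency histogram table
#'
#' Three-column TSV `frequency<TAB>mass<TAB>source` with
#' `source %in% c("grid", "frequent")` and a `#T=<total>` comment line.
#'
#' @param path file path.
#' @param h a [freq_histogram] (writer).
#' @return the [freq_histogram] (reader) or `invisible(path)` (writer).
#' @export
read_histogram <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  g <- df[df$source == "grid", ]
  f <- df[df$source == "frequent", ]
  freq_histogram(g$frequency, g$mass,
                 frequent = if (nrow(f))
                   data.frame(freq = f$frequency, count = f$mass))
}

#' @rdname read_histogram
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "freq_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#T=%.10g", total_variants(h)), con)
  writeLines("frequency\tmass\tsource", con)
  writeLines(sprintf("%.12g\t%.12g\tgrid", h$grid$points, h$mass), con)
  if (!is.null(h$frequent))
    writeLines(sprintf("%.12g\t%.12g\tfrequent", h$frequent$freq,
                       h$frequent$count), con)
  invisible(path)
}
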