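#' Read an annotated sites-level VCF into variant records
#'
#' Parses a sites-only VCF (no genotypes needed) carrying per-population
#' alternate allele counts / allele numbers in INFO (`AC`/`AN`, or
#' `AC_<POP>`/`AN_<POP>` for each ancestry group) and VEP-style `CSQ`
#' consequence annotations with a LOFTEE confidence subfield. Multi-allelic
#' sites are split into one record per alternate allele; indels and other
#' non-SNV alternates are skipped (with a counter — this toolkit addresses
#' single-nucleotide variants only). An optional `CONTEXT` INFO key holding
#' the reference trinucleotide centered on the site enables CpG
#' classification.
#'
#' @param path VCF file (plain or bgzipped).
#' @param populations character vector of population codes to extract; the
#'   pooled cohort is the population `"ALL"` (INFO keys `AC`/`AN` without
#'   suffix). `NULL` autodetects from the header.
#' @param csq_spec character vector naming the pipe-separated CSQ subfields,
#'   overriding the `Format:` declaration in the header. Must contain
#'   `Allele` and `Consequence`; `SYMBOL` (or `Gene`) and `LoF` are used
#'   when present.
#' @return A data.frame of class `"variant_records"` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `consequence` (`synonymous`/`missense`/`lof`/
#'   `other`), `lof_confidence` (`HC`/`LC`/`none`), `mutation_class`,
#'   `gene`, and `ac_<pop>` / `an_<pop>` per population. Attributes:
#'   `populations`, `skipped` (named counts of dropped alternates).
#' @export
read_sites_vcf <- function(path, populations = NULL, csq_spec = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0L)
    stop("no variant records in ", path)

  info_ids <- sub('^##INFO=<ID=([^,]+),.*$', "\\1",
                  grep("^##INFO=", meta, value = TRUE))
  if (is.null(populations)) {
    ac_ids <- grep("^AC(_|$)", info_ids, value = TRUE)
    populations <- sub("^AC_?", "", ac_ids)
    populations[populations == ""] <- "ALL"
    if (length(populations) == 0L)
      stop("no AC INFO keys found in the VCF header")
  }
  key <- function(base, pop) if (pop == "ALL") base else paste0(base, "_", pop)

  if (is.null(csq_spec)) {
    csq_line <- grep("^##INFO=<ID=CSQ,", meta, value = TRUE)
    if (length(csq_line) == 1L && grepl("Format: ", csq_line)) {
      fmt <- sub('^.*Format: ([^">]+)[">].*$', "\\1", csq_line)
      csq_spec <- strsplit(fmt, "|", fixed = TRUE)[[1]]
    }
  }

  ac_raw <- lapply(populations, function(p) vcfR::extract.info(v, key("AC", p)))
  an_raw <- lapply(populations, function(p) vcfR::extract.info(v, key("AN", p)))
  names(ac_raw) <- names(an_raw) <- populations
  csq_raw <- vcfR::extract.info(v, "CSQ")
  ctx_raw <- vcfR::extract.info(v, "CONTEXT")

  skipped <- c(indel = 0L, missing_an = 0L)
  n_malformed_csq <- 0L
  rows <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    ref <- fix$REF[r]
    acs <- lapply(ac_raw, function(x)
      if (is.na(x[r])) rep(NA_real_, n_alt)
      else as.numeric(strsplit(x[r], ",", fixed = TRUE)[[1]]))
    ans <- vapply(an_raw, function(x) suppressWarnings(as.numeric(x[r])),
                  numeric(1))
    csq_entries <- if (!is.null(csq_raw) && !is.na(csq_raw[r]))
      strsplit(csq_raw[r], ",", fixed = TRUE)[[1]] else character(0)
    ctx <- if (!is.null(ctx_raw)) ctx_raw[r] else NA_character_

    out <- vector("list", n_alt)
    for (a in seq_len(n_alt)) {
      alt <- alts[a]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
        skipped["indel"] <- skipped["indel"] + 1L
        next
      }
      ac_a <- vapply(acs, function(x) x[a], numeric(1))
      if (anyNA(ac_a) || anyNA(ans)) {
        skipped["missing_an"] <- skipped["missing_an"] + 1L
        next
      }
      csq <- .match_csq(csq_entries, alt, csq_spec)
      if (is.null(csq)) {
        n_malformed_csq <- n_malformed_csq + 1L
        csq <- list(consequence = "other", lof = "none", gene = NA_character_)
      }
      out[[a]] <- data.frame(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = ref, alt = alt,
        consequence = csq$consequence, lof_confidence = csq$lof,
        mutation_class = classify_mutation(ref, alt, ctx),
        gene = csq$gene,
        rbind(stats::setNames(ac_a, paste0("ac_", populations))),
        rbind(stats::setNames(ans, paste0("an_", populations))),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    rows[[r]] <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rec))
    rec <- data.frame()
  if (n_malformed_csq > 0L)
    warning(n_malformed_csq,
            " alternate(s) with absent/malformed CSQ kept as consequence 'other'")
  structure(rec, populations = populations, skipped = skipped,
            class = c("variant_records", "data.frame"))
}

# Match one CSQ entry to an alternate allele and extract the fields used.
# Returns NULL when no entry matches or the spec is unusable.
.match_csq <- function(entries, alt, csq_spec) {
  if (length(entries) == 0L || is.null(csq_spec) ||
      !all(c("Allele", "Consequence") %in% csq_spec))
    return(NULL)
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    length(f) <- length(csq_spec)           # pad trailing empties
    names(f) <- csq_spec
    if (identical(unname(f["Allele"]), alt)) {
      terms <- strsplit(f[["Consequence"]], "&", fixed = TRUE)[[1]]
      cons <- if (any(terms %in% c("stop_gained", "splice_donor_variant",
                                   "splice_acceptor_variant"))) "lof"
      else if ("missense_variant" %in% terms) "missense"
      else if ("synonymous_variant" %in% terms) "synonymous"
      else "other"
      lof <- if ("LoF" %in% csq_spec && !is.na(f["LoF"]) &&
                 nzchar(f[["LoF"]])) f[["LoF"]] else "none"
      gene <- if ("SYMBOL" %in% csq_spec && !is.na(f["SYMBOL"]) &&
                  nzchar(f[["SYMBOL"]])) f[["SYMBOL"]]
      else if ("Gene" %in% csq_spec && !is.na(f["Gene"]) &&
               nzchar(f[["Gene"]])) f[["Gene"]]
      else NA_character_
      return(list(consequence = cons, lof = lof, gene = gene))
    }
  }
  NULL
}

#' Classify a single-nucleotide substitution
#'
#' Transition versus transversion by the purine/pyrimidine rule, with CpG
#' transitions separated out: a C>T (or, by reverse-complement symmetry on
#' the reference strand, G>A) transition whose trinucleotide context places
#' the mutated C inside a CG dinucleotide. CpG transitions are the most
#' mutable substitution class; transversions the least. When the context is
#' required but unavailable the class is `"unknown"`.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context optional reference trinucleotide centered on the site.
#' @return character vector: `"CpG_transition"`, `"nonCpG_transition"`,
#'   `"transversion"` or `"unknown"`.
#' @examples
#' classify_mutation("C", "T", "ACG")  # CpG_transition
#' classify_mutation("A", "T")         # transversion
#' @export
classify_mutation <- function(ref, alt, context = NA_character_) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(as.character(context)), n)
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T")))
    stop("ref/alt must be single bases A, C, G or T")
  if (any(ref == alt)) stop("ref and alt must differ")
  pur <- c("A", "G")
  transition <- (ref %in% pur) == (alt %in% pur)
  out <- ifelse(transition, "nonCpG_transition", "transversion")
  cpg_candidate <- transition & ((ref == "C" & alt == "T") | (ref == "G" & alt == "A"))
  has_ctx <- !is.na(context) & nchar(context) == 3L
  is_cpg <- cpg_candidate & has_ctx &
    ((ref == "C" & substr(context, 2, 3) == "CG") |
     (ref == "G" & substr(context, 1, 2) == "CG"))
  out[cpg_candidate & !has_ctx] <- "unknown"
  out[is_cpg] <- "CpG_transition"
  out
}

#' Variant class filter
#'
#' Selection rules applied before building an SFS: functional consequence,
#' LOFTEE confidence (requiring `"HC"` keeps only high-confidence LoF
#' calls), mutational class, and an optional coverage mask of well-covered
#' intervals.
#'
#' @param consequence keep these consequence classes (`NULL` keeps all).
#' @param lof_confidence required LOFTEE flag, e.g. `"HC"` (`NULL`: any).
#'   Requiring a flag implies `consequence = "lof"`.
#' @param mutation_class keep these mutation classes (`NULL` keeps all).
#' @param mask a [read_bed_mask] data.frame of well-covered intervals.
#' @return list of class `"class_filter"`.
#' @export
class_filter <- function(consequence = NULL, lof_confidence = NULL,
                         mutation_class = NULL, mask = NULL) {
  if (!is.null(lof_confidence)) {
    if (is.null(consequence)) consequence <- "lof"
    if (!identical(consequence, "lof"))
      stop("an LoF confidence requirement implies consequence = 'lof'")
  }
  structure(list(consequence = consequence, lof_confidence = lof_confidence,
                 mutation_class = mutation_class, mask = mask),
            class = "class_filter")
}

#' Apply a class filter to variant records
#'
#' @param records a [read_sites_vcf] data.frame.
#' @param filter a [class_filter] (`NULL` is a no-op).
#' @return the filtered records (attributes preserved).
#' @export
filter_records <- function(records, filter = NULL) {
  if (is.null(filter)) return(records)
  stopifnot(inherits(filter, "class_filter"))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(filter$consequence))
    keep <- keep & records$consequence %in% filter$consequence
  if (!is.null(filter$lof_confidence))
    keep <- keep & records$lof_confidence %in% filter$lof_confidence
  if (!is.null(filter$mutation_class))
    keep <- keep & records$mutation_class %in% filter$mutation_class
  if (!is.null(filter$mask))
    keep <- keep & in_mask(records$chrom, records$pos, filter$mask)
  out <- records[keep, , drop = FALSE]
  attributes(out)$populations <- attr(records, "populations")
  class(out) <- class(records)
  out
}

#' Read a BED coverage mask
#'
#' Three-column BED (chrom, start, end), 0-based half-open as the format
#' prescribes. Intervals on one chromosome must be non-overlapping.
#'
#' @param path BED file.
#' @return data.frame of class `"bed_mask"` with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  structure(df[order(df$chrom, df$start), ], class = c("bed_mask", "data.frame"))
}

#' Test VCF positions against a BED mask
#'
#' Coordinate conventions meet here: VCF positions are 1-based inclusive,
#' BED intervals 0-based half-open, so position `pos` is inside
#' `[start, end)` iff `start < pos <= end`.
#'
#' @param chrom,pos vectors of VCF chromosome / 1-based position.
#' @param mask a [read_bed_mask] data.frame.
#' @return logical vector.
#' @export
in_mask <- function(chrom, pos, mask) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    m <- mask[mask$chrom == ch, ]
    sel <- chrom == ch
    if (nrow(m) == 0L) next
    idx <- findInterval(pos[sel] - 1L, m$start)
    hit <- idx >= 1L & (pos[sel] - 1L) < m$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}

#' Build an SFS from variant records
#'
#' Bins records by alternate allele count: `F_i` is the number of passing
#' records with `ac = i`. Real call sets have variable `AN` across sites
#' (missingness), while an SFS needs a single `k`; the policy is: set
#' `k = nominal_an` (default: the maximum `AN` seen), exclude records called
#' in fewer than `min_an_frac * k` alleles, and downsample records with
#' `an > k` to `k` hypergeometrically in expected-value mode (rounded).
#' Records reaching `ac = 0` drop out.
#'
#' @param records a [read_sites_vcf] data.frame.
#' @param filter optional [class_filter].
#' @param population population code, or `NULL` to pool: allele counts and
#'   numbers are summed across all populations per record before binning.
#' @param nominal_an the SFS allele number `k` (`NULL`: max observed `AN`).
#' @param min_an_frac records with `an < min_an_frac * k` are excluded.
#' @param label provenance tag for the SFS.
#' @return an [sfs] object.
#' @export
sfs_from_records <- function(records, filter = NULL, population = NULL,
                             nominal_an = NULL, min_an_frac = 0.8,
                             label = "") {
  records <- filter_records(records, filter)
  pops <- attr(records, "populations")
  if (nrow(records) == 0L) {
    warning("no records pass the filter: returning empty SFS")
    return(sfs(numeric(0), k = if (is.null(nominal_an)) 1L else nominal_an,
               label = label))
  }
  if (is.null(population)) {
    ac <- rowSums(records[, paste0("ac_", pops), drop = FALSE])
    an <- rowSums(records[, paste0("an_", pops), drop = FALSE])
  } else {
    if (!population %in% pops)
      stop("population '", population, "' not present in the records")
    ac <- records[[paste0("ac_", population)]]
    an <- records[[paste0("an_", population)]]
  }
  k <- if (is.null(nominal_an)) max(an) else as.integer(nominal_an)
  keep <- an >= min_an_frac * k
  ac <- ac[keep]; an <- an[keep]
  over <- an > k
  ac[over] <- round(downsample_count(ac[over], an[over], k, mode = "expected"))
  ac <- pmin(ac, k)
  ac <- ac[ac > 0]
  sfs(table(ac), k = k, label = label)
}
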