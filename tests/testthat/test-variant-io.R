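test_that("simulator VCF round-trips through the parser exactly", {
  p <- withr::local_tempfile(fileext = ".vcf")
  fx <- two_pop_fixture(p)
  rec <- read_sites_vcf(p)
  obs <- fx$cohort$ac[fx$cohort$ac > 0]
  expect_equal(nrow(rec), length(obs))
  expect_setequal(attr(rec, "populations"), c("EUR", "AFR"))
  # per-record pooled counts equal the simulated counts
  pooled <- rec$ac_EUR + rec$ac_AFR
  expect_equal(sort(pooled), sort(obs))
  expect_true(all(rec$an_EUR + rec$an_AFR == fx$cohort$k))
  # SFS from records is bit-identical to the simulation's own bookkeeping
  s <- sfs_from_records(rec)
  expect_equal(s$i, fx$cohort$sfs$i)
  expect_equal(s$n, fx$cohort$sfs$n)
  # class fractions match the scenario profile by construction
  ann <- fx$scenario$annotation
  n <- nrow(rec)
  for (cls in names(ann$consequence)) {
    expect_equal(sum(rec$consequence == cls),
                 unseenest:::largest_remainder_round(ann$consequence * n)[
                   match(cls, names(ann$consequence))])
  }
})

test_that("multi-allelic sites split and non-SNV alternates are skipped", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_edge_case_vcf(p)
  rec <- read_sites_vcf(p)
  # 6 alts in the file, 2 indel alts (GA, TTC>T) skipped -> 4 records
  expect_equal(nrow(rec), 4)
  expect_equal(unname(attr(rec, "skipped")["indel"]), 2L)
  multi <- rec[rec$pos == 100, ]
  expect_equal(nrow(multi), 2)
  expect_equal(multi$ac_ALL[multi$alt == "C"], 3)
  expect_equal(multi$ac_ALL[multi$alt == "T"], 5)
  expect_equal(multi$consequence, c("missense", "synonymous"))
  # LoF consequences and LOFTEE flags
  expect_equal(rec$consequence[rec$pos == 200], "lof")
  expect_equal(rec$lof_confidence[rec$pos == 200], "HC")
  expect_equal(rec$lof_confidence[rec$pos == 400], "LC")
})

test_that("mutation classification matches a hand-enumerated truth table", {
  bases <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  contexts <- as.vector(outer(bases, bases, function(l, r) paste0(l, "X", r)))
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (ctx_t in contexts) {
      ctx <- sub("X", ref, ctx_t)
      # independent truth: explicit case analysis
      truth <- if (purine[ref] != purine[alt]) "transversion"
      else if (ref == "C" && alt == "T") {
        if (substr(ctx, 3, 3) == "G") "CpG_transition" else "nonCpG_transition"
      } else if (ref == "G" && alt == "A") {
        if (substr(ctx, 1, 1) == "C") "CpG_transition" else "nonCpG_transition"
      } else "nonCpG_transition"
      expect_equal(classify_mutation(ref, alt, ctx), truth,
                   info = paste(ref, alt, ctx))
    }
    # context-free calls
    no_ctx <- classify_mutation(ref, alt)
    if (purine[ref] != purine[alt]) expect_equal(no_ctx, "transversion")
    else if ((ref == "C" && alt == "T") || (ref == "G" && alt == "A"))
      expect_equal(no_ctx, "unknown")
    else expect_equal(no_ctx, "nonCpG_transition")
  }
  expect_error(classify_mutation("N", "A"), "single bases")
  expect_error(classify_mutation("A", "A"), "must differ")
})

test_that("SFS construction bins allele counts with the stated k policy", {
  rec <- structure(
    data.frame(chrom = "1", pos = c(10, 20, 30), ref = "A", alt = "G",
               consequence = "missense", lof_confidence = "none",
               mutation_class = "nonCpG_transition", gene = "G1",
               ac_ALL = c(1, 1, 2), an_ALL = c(100, 100, 100)),
    populations = "ALL", class = c("variant_records", "data.frame"))
  s <- sfs_from_records(rec)
  expect_equal(s$k, 100)
  expect_equal(sfs_vector(s, 2), c(2, 1))

  # pooled across populations: counts summed per record before binning
  rec2 <- structure(
    data.frame(chrom = "1", pos = c(10, 20), ref = "A", alt = "G",
               consequence = "missense", lof_confidence = "none",
               mutation_class = "nonCpG_transition", gene = "G1",
               ac_P1 = c(1, 2), an_P1 = c(50, 50),
               ac_P2 = c(3, 0), an_P2 = c(50, 50)),
    populations = c("P1", "P2"), class = c("variant_records", "data.frame"))
  s2 <- sfs_from_records(rec2)
  expect_equal(s2$k, 100)
  expect_equal(s2$i, c(2L, 4L))
  s_p1 <- sfs_from_records(rec2, population = "P1")
  expect_equal(s_p1$k, 50)
  expect_equal(s_p1$i, c(1L, 2L))
})

test_that("variable AN policy downsamples high-AN and drops low-AN records", {
  rec <- structure(
    data.frame(chrom = "1", pos = c(1, 2, 3), ref = "C", alt = "T",
               consequence = "synonymous", lof_confidence = "none",
               mutation_class = "unknown", gene = "G1",
               ac_ALL = c(10, 4, 2), an_ALL = c(200, 100, 70)),
    populations = "ALL", class = c("variant_records", "data.frame"))
  s <- sfs_from_records(rec, nominal_an = 100)
  # 200 -> 100 halves ac 10 to 5; an = 70 < 80 excluded; ac 4 kept
  expect_equal(s$k, 100)
  expect_equal(s$i, c(4L, 5L))
  expect_equal(s$n, c(1, 1))
})

test_that("class filters are monotone and masks use BED half-open coordinates", {
  p <- withr::local_tempfile(fileext = ".vcf")
  fx <- two_pop_fixture(p)
  rec <- read_sites_vcf(p)
  s_all <- sfs_from_records(rec)
  s_lof <- sfs_from_records(rec, filter = class_filter(consequence = "lof"))
  s_hc <- sfs_from_records(rec, filter = class_filter(lof_confidence = "HC"))
  m_all <- sfs_vector(s_all, fx$cohort$k)
  expect_true(all(sfs_vector(s_lof, fx$cohort$k) <= m_all))
  expect_true(all(sfs_vector(s_hc, fx$cohort$k) <=
                    sfs_vector(s_lof, fx$cohort$k)))
  # HC count matches the profile the simulator wrote
  n_lof <- sum(rec$consequence == "lof")
  expect_equal(sum(rec$lof_confidence == "HC"),
               unseenest:::largest_remainder_round(
                 c(n_lof * 0.8, n_lof * 0.2))[1])

  # BED 0-based half-open vs VCF 1-based: [99, 100) covers position 100 only
  bp <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t99\t100", bp)
  mask <- read_bed_mask(bp)
  expect_equal(in_mask(c("1", "1", "1", "2"), c(99, 100, 101, 100), mask),
               c(FALSE, TRUE, FALSE, FALSE))
  # mask filtering keeps exactly the covered records
  bp2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("1\t%d\t%d", 1000, 1000 + 10 * 5), bp2)
  rec_m <- filter_records(rec, class_filter(mask = read_bed_mask(bp2)))
  expect_equal(nrow(rec_m), sum(rec$pos <= 1050))

  expect_error(class_filter(consequence = "missense", lof_confidence = "HC"),
               "implies")
})
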