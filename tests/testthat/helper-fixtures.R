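# Shared fixture builders; everything is generated in code at test time.

# Exact expected SFS (rounded) of a one-point histogram, as an sfs object.
pointmass_sfs <- function(x, n_variants, k, i_max = 30) {
  F_i <- round(n_variants * dbinom(seq_len(i_max), k, x))
  sfs(setNames(F_i, seq_len(i_max))[F_i > 0], k = k, label = "pointmass expected")
}

# Random histogram on a modest grid, for property-style loops.
random_histogram <- function(seed, k = 300, n_points = 40) {
  set.seed(seed)
  pts <- sort(exp(runif(n_points, log(1 / (50 * k)), 0)))
  pts <- unique(pts)
  freq_histogram(pts, rexp(length(pts), rate = 1 / 50))
}

# Small two-population fixture VCF written from the simulator.
two_pop_fixture <- function(path, n_variants = 400, k = 200, seed = 7) {
  sc <- sim_scenario("beta", n_variants = n_variants, k = k, seed = seed,
                     shape1 = 0.5, shape2 = 200,
                     populations = c(EUR = 0.6, AFR = 0.4))
  co <- sample_cohort(make_true_histogram(sc), k, seed = seed)
  write_fixture_vcf(co, sc, path)
  list(scenario = sc, cohort = co, path = path)
}

# Hand-written VCF text for parser edge cases (multi-allelic, indels).
write_edge_case_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Alt allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total alleles">',
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations. Format: Allele|Consequence|SYMBOL|LoF">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    # multi-allelic SNV line: two records expected
    "1\t100\t.\tA\tC,T\t50\tPASS\tAC=3,5;AN=100;CSQ=C|missense_variant|G1|,T|synonymous_variant|G1|",
    # indel alt among SNVs: one alt skipped
    "1\t200\t.\tG\tGA,A\t50\tPASS\tAC=2,4;AN=100;CSQ=GA|frameshift_variant|G2|,A|stop_gained|G2|HC",
    # pure indel line: skipped entirely
    "1\t300\t.\tTTC\tT\t50\tPASS\tAC=1;AN=100;CSQ=T|inframe_deletion|G3|",
    # plain SNV
    "1\t400\t.\tC\tG\t50\tPASS\tAC=7;AN=100;CSQ=G|splice_donor_variant|G4|LC")
  writeLines(lines, path)
  path
}
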