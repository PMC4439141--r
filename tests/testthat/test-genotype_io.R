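test_that("tabular round trip preserves dosages and computes MAF from mean dosage", {
  pan <- tiny_panel()
  # maf = min(mean/2, 1 - mean/2) per column
  expect_equal(pan$snps$maf, c(0.5, 0, 0.25))
  tmp <- tempfile(fileext = ".tsv"); info <- tempfile(fileext = ".tsv")
  write_dosage_tabular(pan, tmp, info)
  back <- read_dosage(tmp, "tabular", snp_info = info)
  expect_equal(back$dosage, pan$dosage, tolerance = 1e-9)
  expect_equal(back$snps, pan$snps)
  expect_equal(back$sample_ids, pan$sample_ids)
})

test_that("reader rejects malformed input and imputes missing cells to SNP means", {
  bad <- tempfile(); writeLines(c("sample_id\trs1", "s1\tnot_a_number"), bad)
  expect_error(read_dosage(bad, "tabular"), "non-numeric")
  expect_error(read_dosage(tempfile(), "tabular"), "not found")
  dos <- matrix(c(0, 1, NA, 2), 4, 1, dimnames = list(NULL, "rs1"))
  expect_message(pan <- dosage_panel(dos, data.frame(id = "rs1"), paste0("s", 1:4)),
                 "1 missing")
  expect_equal(pan$dosage[3, 1], 1)  # mean of 0,1,2
})

test_that("VCF input: GP triples give dosage P(het) + 2 P(hom-alt); multi-allelic rejected", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=5>",
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype probabilities">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "5\t100\trs1\tA\tG\t.\tPASS\t.\tGP\t0.81,0.18,0.01\t0.25,0.5,0.25",
    "5\t200\trs2\tC\tT\t.\tPASS\t.\tGP\t1,0,0\t0,0,1"), vcf)
  pan <- read_dosage(vcf, "vcf")
  expect_equal(unname(pan$dosage[, "rs1"]), c(0.20, 1.00), tolerance = 1e-6)
  expect_equal(unname(pan$dosage[, "rs2"]), c(0, 2), tolerance = 1e-9)
  expect_equal(pan$snps$pos, c(100L, 200L))
  multi <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=5>",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA",
    "5\t100\trs1\tA\tG,T\t.\tPASS\t.\tDS\t1.0"), multi)
  expect_error(read_dosage(multi, "vcf"), "multi-allelic")
})

test_that("MAF filter is strict and idempotent", {
  set.seed(4)
  n <- 400
  # columns engineered to MAFs 0.04, 0.05, 0.06 exactly via mean dosage
  dos <- cbind(a = rep(c(0, 1), c(n - 32, 32)),
               b = rep(c(0, 1), c(n - 40, 40)),
               c = rep(c(0, 1), c(n - 48, 48)))
  pan <- dosage_panel(dos, data.frame(id = c("a", "b", "c")), sprintf("x%03d", 1:n))
  expect_equal(pan$snps$maf, c(0.04, 0.05, 0.06))
  kept <- filter_maf(pan, 0.05)
  expect_equal(kept$snps$id, "c")                       # > 5%, strictly
  expect_equal(filter_maf(kept, 0.05)$snps$id, "c")     # idempotent
  expect_equal(ncol(filter_maf(pan, 0)$dosage), 3)      # all polymorphic kept
  mono <- dosage_panel(matrix(0, 4, 1, dimnames = list(NULL, "m")),
                       data.frame(id = "m"), paste0("s", 1:4))
  expect_equal(ncol(filter_maf(mono, 0.05)$dosage), 0)
})

test_that("region extraction uses inclusive +-flank bounds and chromosome match", {
  # ADRB2-like coordinates: gene 148,186,349-148,188,381, flank 5 kb
  pos <- c(148181348L, 148181349L, 148193381L, 148193382L)
  dos <- matrix(rep(c(0, 1), 4), 2, 4, dimnames = list(NULL, paste0("v", 1:4)))
  snps <- data.frame(id = paste0("v", 1:4), chrom = c("5", "5", "5", "5"),
                     pos = pos, ref_allele = "A", alt_allele = "G")
  pan <- dosage_panel(dos, snps, c("s1", "s2"))
  reg <- gene_region("ADRB2", "5", 148186349L, 148188381L, flank_bp = 5000L)
  got <- extract_region(pan, reg)
  expect_equal(got$snps$id, c("v2", "v3"))  # boundary SNPs included
  # same positions, wrong chromosome: excluded
  snps$chrom <- "7"
  pan7 <- dosage_panel(dos, snps, c("s1", "s2"))
  expect_warning(none <- extract_region(pan7, reg), "no SNPs")
  expect_equal(ncol(none$dosage), 0)
  # invariant to SNP order up to ordering
  snps$chrom <- "5"
  shuf <- dosage_panel(dos[, 4:1], snps[4:1, 1:5], c("s1", "s2"))
  expect_setequal(extract_region(shuf, reg)$snps$id, got$snps$id)
})

test_that("BED regions convert from 0-based half-open to 1-based inclusive", {
  bed <- tempfile(fileext = ".bed")
  writeLines("5\t148186348\t148188381\tADRB2", bed)
  reg <- read_regions(bed, "bed")
  expect_equal(reg$start, 148186349L)
  expect_equal(reg$end, 148188381L)
  expect_equal(reg$flank_bp, 5000L)
})

test_that("best_call rounds dosages with ties toward the smaller count and argmaxes probabilities", {
  dos <- matrix(c(0.4, 1.49, 1.51, 0.5, 1.5, 2.0), 6, 1,
                dimnames = list(NULL, "rs1"))
  pan <- dosage_panel(dos, data.frame(id = "rs1"), paste0("s", 1:6))
  expect_equal(unname(best_call(pan)$dosage[, 1]), c(0L, 1L, 2L, 0L, 1L, 2L))
  # already-integer dosages are identity
  ints <- tiny_panel()
  expect_true(all(best_call(ints)$dosage == ints$dosage))
  # probability argmax
  probs <- array(c(0.2, 0.5, 0.3), c(1, 1, 3))
  pp <- dosage_panel(matrix(0.5 + 2 * 0.3, 1, 1, dimnames = list(NULL, "rs1")),
                     data.frame(id = "rs1"), "s1", probs = probs)
  expect_equal(unname(best_call(pp)$dosage[1, 1]), 1L)
})

test_that("inconsistent genotype probabilities are rejected", {
  probs <- array(c(0.5, 0.5, 0.5), c(1, 1, 3))  # sums to 1.5
  expect_error(dosage_panel(matrix(1, 1, 1), data.frame(id = "r"), "s1",
                            probs = probs), "sum to 1")
})

test_that("leading PCs separate simulated subpopulations and respect scaling invariance", {
  set.seed(11)
  p1 <- simulate_genotypes(120, 40, maf_range = c(0.05, 0.15), ld_rho = 0, seed = 21)
  p2 <- simulate_genotypes(120, 40, maf_range = c(0.35, 0.5), ld_rho = 0, seed = 22)
  pan <- dosage_panel(rbind(p1$dosage, p2$dosage), p1$snps[1:5],
                      c(paste0("a", 1:120), paste0("b", 1:120)))
  pcs <- compute_pcs(pan, 2)
  grp <- rep(c(0, 1), each = 120)
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
  # duplicating every SNP column leaves the leading component unchanged up to sign
  dup <- dosage_panel(cbind(pan$dosage, pan$dosage),
                      data.frame(id = c(colnames(pan$dosage),
                                        paste0(colnames(pan$dosage), "_d"))),
                      pan$sample_ids)
  pc_dup <- compute_pcs(dup, 1)
  expect_gt(abs(cor(pcs[, 1], pc_dup[, 1])), 1 - 1e-8)
  expect_equal(ncol(compute_pcs(pan, 0)), 0)
})
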