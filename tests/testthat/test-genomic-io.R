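test_that("BED reader maps rows to calls and enforces invariants", {
  path <- withr::local_tempfile()
  writeLines(c("chr1 100 200 1", "chr2 0 500 4"), path)
  calls <- read_cnv_bed(path)
  expect_equal(calls$chrom, c("chr1", "chr2"))
  expect_equal(calls$start, c(100L, 0L))
  expect_equal(calls$end, c(200L, 500L))
  expect_equal(calls$svtype, c("DEL", "DUP"))
  expect_equal(calls$copy_number, c(1L, 4L))

  writeLines("chr1 200 100 1", path)
  expect_error(read_cnv_bed(path), "start < end")
  writeLines("chr1 100 200 2", path)
  expect_error(read_cnv_bed(path), "not a CNV")
  writeLines(c("chr1 100 200 1", "chr1 300 x 1"), path)
  expect_error(read_cnv_bed(path), "line 2")
})

test_that("BED write/read round-trips exactly", {
  withr::local_seed(11)
  calls <- sort_calls(random_calls(40, sample_id = "S9"))
  path <- withr::local_tempfile()
  write_cnv_bed(calls, path, sample_col = TRUE)
  back <- read_cnv_bed(path)
  expect_equal(back[, c("chrom", "start", "end", "copy_number", "sample_id")],
               calls[, c("chrom", "start", "end", "copy_number", "sample_id")])
  # and byte-identical on rewrite
  path2 <- withr::local_tempfile()
  write_cnv_bed(back, path2, sample_col = TRUE)
  expect_identical(readLines(path), readLines(path2))
})

test_that("CNV VCF reader applies coordinate conventions and skips non-CNV alleles", {
  path <- withr::local_tempfile()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t10001\tv1\tN\t<DEL>\t.\tPASS\tEND=15000\tGT\t0/1\t0/0",
    "chr1\t20001\tv2\tN\t<INV>\t.\tPASS\tEND=25000\tGT\t0/1\t0/1",
    "chr1\t30001\tv3\tN\t<DUP>\t.\tLowQual\tEND=31000\tGT\t1/1\t0/0"
  ), path)
  v <- read_cnv_vcf(path)
  expect_equal(nrow(v$records), 2L)
  expect_equal(v$n_skipped, 1L)
  expect_equal(v$records$start[1], 10000L)
  expect_equal(v$records$end[1], 15000L)
  expect_equal(v$records$end[1] - v$records$start[1], 5000L)
  # failing FILTER retained but marked
  expect_false(v$records$filter_pass[2])
})

test_that("genotype-to-copy-number mapping follows zygosity", {
  path <- withr::local_tempfile()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t101\tdel_het\tN\t<DEL>\t.\tPASS\tEND=300\tGT\t0/1",
    "chr1\t1001\tdel_hom\tN\t<DEL>\t.\tPASS\tEND=1300\tGT\t1/1",
    "chr1\t2001\tdup_het\tN\t<DUP>\t.\tPASS\tEND=2300\tGT\t0/1",
    "chr1\t3001\tdup_hom\tN\t<DUP>\t.\tPASS\tEND=3300\tGT\t1/1",
    "chr1\t4001\tref\tN\t<DEL>\t.\tPASS\tEND=4300\tGT\t0/0"
  ), path)
  v <- read_cnv_vcf(path)
  calls <- vcf_to_sample_calls(v, "S1")
  expect_equal(nrow(calls), 4L)  # 0/0 emits nothing
  expect_equal(calls$copy_number, c(1L, 0L, 3L, 4L))
  expect_equal(calls$end[1] - calls$start[1], 200L)  # DEL 0/1 at [100,300)
  expect_error(vcf_to_sample_calls(v, "nope"), "not present")
})

test_that("per-genotype FT tags and site FILTER both gate PASS extraction", {
  path <- withr::local_tempfile()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Genotype filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t101\ta\tN\t<DEL>\t.\tPASS\tEND=300\tGT:FT\t0/1:PASS",
    "chr1\t1001\tb\tN\t<DEL>\t.\tPASS\tEND=1300\tGT:FT\t0/1:FAIL",
    "chr1\t2001\tc\tN\t<DUP>\t.\tLowQual\tEND=2300\tGT:FT\t0/1:PASS"
  ), path)
  v <- read_cnv_vcf(path)
  calls <- vcf_to_sample_calls(v, "S1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 100L)
  all_calls <- vcf_to_sample_calls(v, "S1", require_pass = FALSE)
  expect_equal(nrow(all_calls), 3L)
})

test_that("PLINK export shifts coordinates, refuses overlaps, and round-trips", {
  calls <- cnv_calls("chr1", 100L, 200L, 1L, sample_id = "S")
  path <- withr::local_tempfile()
  to_plink_cnv(calls, path)
  expect_identical(readLines(path), "S\tS\t1\t101\t200\t1")
  back <- read_plink_cnv(path, chrom_prefix = "chr")
  expect_equal(back[, c("chrom", "start", "end", "copy_number", "sample_id")],
               calls[, c("chrom", "start", "end", "copy_number", "sample_id")])

  overlapping <- cnv_calls(c("chr1", "chr1"), c(100L, 150L), c(300L, 400L),
                           c(1L, 1L), sample_id = "S")
  expect_error(to_plink_cnv(overlapping, path), "overlapping")

  # empty callset: empty file, no header
  to_plink_cnv(cnv_calls(), path)
  expect_length(readLines(path), 0L)

  # family IDs from phenotypes
  phe <- data.frame(sample_id = "S", family_id = "FAM7", status = "case",
                    group = "NHW")
  to_plink_cnv(calls, path, phenotypes = phe)
  expect_identical(readLines(path), "FAM7\tS\t1\t101\t200\t1")
})

test_that("mask reader validates labels and keeps intervals as given", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\tP", "chr1\t100\t150\tN"), path)
  mask <- read_mask(path)
  expect_equal(nrow(mask), 2L)
  expect_equal(sum(mask$end - mask$start), 150L)
  # adjacent same-label rows not auto-merged
  writeLines(c("chr1\t0\t100\tP", "chr1\t100\t150\tP"), path)
  expect_equal(nrow(read_mask(path)), 2L)
  writeLines("chr1\t0\t100\tQ", path)
  expect_error(read_mask(path), "unknown mask class")
  writeLines(c("chr1\t0\t100\tP", "chr1\t50\t150\tN"), path)
  expect_error(read_mask(path), "different labels")
})

test_that("phenotype reader fills defaults and enforces uniqueness", {
  path <- withr::local_tempfile()
  writeLines(c("sample_id\tstatus", "A\tcase", "B\tcontrol"), path)
  phe <- read_phenotypes(path)
  expect_equal(phe$family_id, c("A", "B"))
  expect_equal(phe$group, c("Other", "Other"))
  writeLines(c("sample_id\tstatus", "A\tcase", "A\tcontrol"), path)
  expect_error(read_phenotypes(path), "duplicate")
})

test_that("VCF writer output is parseable and preserves interval lengths", {
  sites <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                      end = c(400L, 900L), svtype = c("DEL", "DUP"))
  gt <- matrix(c("0/1", "1/1", "0/0", "0/1"), nrow = 2,
               dimnames = list(NULL, c("A", "B")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cnv_vcf(sites, path, genotypes = gt)
  v <- read_cnv_vcf(path)
  expect_equal(v$records$start, sites$start)
  expect_equal(v$records$end, sites$end)
  expect_equal(v$samples, c("A", "B"))
  a <- vcf_to_sample_calls(v, "A")
  expect_equal(a$copy_number, c(1L, 4L))
})
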