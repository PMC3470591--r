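test_that("matrix012 files round-trip through all dialect variants", {
  vals <- rbind(c(0L, 1L, 2L, 1L), c(2L, 0L, 1L, 0L), c(1L, 1L, 0L, 2L))
  # bare whitespace-separated, no header, no IDs
  f1 <- withr::local_tempfile(fileext = ".012")
  writeLines(apply(vals, 1, paste, collapse = " "), f1)
  g1 <- read_genotype_matrix(f1, "matrix012")
  expect_equal(dim(g1), c(3L, 4L))
  expect_equal(unname(unclass(g1)), unname(vals))
  # comma-separated with locus header and sample-ID column
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("id", paste0("rs", 1:4)), collapse = ","),
               paste(c("ind_a", vals[1, ]), collapse = ","),
               paste(c("ind_b", vals[2, ]), collapse = ","),
               paste(c("ind_c", vals[3, ]), collapse = ",")), f2)
  g2 <- read_genotype_matrix(f2, "matrix012")
  expect_equal(rownames(g2), c("ind_a", "ind_b", "ind_c"))
  expect_equal(colnames(g2), paste0("rs", 1:4))
  expect_equal(unname(unclass(g2)), unname(vals))
  # sample-ID column without a header: no row may be mistaken for a header
  f3 <- withr::local_tempfile()
  writeLines(c(paste(c("ind_a", vals[1, ]), collapse = " "),
               paste(c("ind_b", vals[2, ]), collapse = " "),
               paste(c("ind_c", vals[3, ]), collapse = " ")), f3)
  g3 <- read_genotype_matrix(f3, "matrix012")
  expect_equal(dim(g3), c(3L, 4L))
  expect_equal(rownames(g3), c("ind_a", "ind_b", "ind_c"))
  expect_equal(unname(unclass(g3)), unname(vals))
})

test_that("matrix012 missing sentinels NA, -9 and . are stored uniformly", {
  f <- withr::local_tempfile()
  writeLines(c("0 NA 2", "-9 1 .", "2 2 0"), f)
  g <- read_genotype_matrix(f, "matrix012")
  expect_equal(sum(is.na(g)), 3L)
  expect_true(is.na(g[1, 2]) && is.na(g[2, 1]) && is.na(g[2, 3]))
})

test_that("malformed and degenerate matrix012 input fails loudly", {
  f <- withr::local_tempfile()
  writeLines(c("0 1 2", "0 5 1"), f)
  expect_error(read_genotype_matrix(f, "matrix012"), "row 2, column 2")
  writeLines(character(), f)
  expect_error(read_genotype_matrix(f, "matrix012"), "empty")
  writeLines("0 1 2", f)
  expect_error(read_genotype_matrix(f, "matrix012"), "fewer than 2 samples")
})

test_that("PLINK raw tables are parsed with metadata columns skipped", {
  f <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_C rs3_G",
               "fam1 i1 0 0 1 -9 0 1 2",
               "fam1 i2 0 0 2 -9 2 NA 0"), f)
  g <- read_genotype_matrix(f, "plink_raw")
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(rownames(g), c("i1", "i2"))
  expect_equal(unname(g[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(g[2, 2]))
})

test_that("VCF genotypes convert to reference-allele counts", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
               "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1"), f)
  g <- read_genotype_matrix(f, "vcf")
  expect_equal(dim(g), c(3L, 2L))
  # GT 0/0 has two reference alleles, 0/1 one, 1/1 none
  expect_equal(unname(g[, "rs1"]), c(2L, 1L, 0L))
  expect_equal(unname(g["s1", "rs2"]), 1L)
  expect_true(is.na(g["s2", "rs2"]))
  # multi-allelic records are rejected
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t1/2"), f)
  expect_error(read_genotype_matrix(f, "vcf"), "multi-allelic")
})

test_that("partition and gap-table TSVs round-trip; Newick structure is forced", {
  part <- stats::setNames(c(1L, 1L, 1L), c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, f)
  expect_equal(read_partition(f), part)
  lines <- readLines(f)
  expect_equal(length(lines), 4L)  # header + one identical label per sample

  S <- block_similarity(c(2, 3))
  tree <- build_tree(S, min_node_size = 2)
  fn <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tree, fn)
  expect_equal(readLines(fn), "(cluster_1(n=2),cluster_2(n=3));")

  sim <- simulate_structured(pop_model("M3", n_per_pop = 10, p = 300), seed = 3)
  set.seed(3)
  core <- ships:::.ships_partitions(sim$genotypes)
  gap <- gap_curve(core$partitions, core$D, n = 30, p = 300, B = 3, k_max = 4)
  fg <- withr::local_tempfile(fileext = ".tsv")
  write_gap_table(gap, fg)
  back <- utils::read.table(fg, header = TRUE, sep = "\t")
  expect_equal(names(back), c("k", "W", "null_mean", "null_sd", "gap", "s", "selected"))
  expect_equal(back$k, gap$ks)
  expect_equal(back$W, gap$W, tolerance = 1e-12)
})

test_that("geno_matrix validates codes and identifiers", {
  expect_error(geno_matrix(rbind(c(0, 3), c(1, 2))), "invalid genotype code '3'")
  expect_error(geno_matrix(rbind(c(0, 1), c(1, 2)), sample_ids = c("x", "x")),
               "unique")
  g <- geno_matrix(rbind(c(0, 1), c(NA, 2)))
  expect_equal(rownames(g), c("sample_1", "sample_2"))
  expect_equal(colnames(g), c("snp_1", "snp_2"))
})
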