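test_that("PED/MAP reader handles a tiny file and its dimensions", {
  f <- write_tiny_ped_map()
  ds <- read_ped_map(f$ped, f$map)
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(ds$snps$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(ds$samples$individual_id, c("I1", "I2"))
  # missing call is both-zero; rs3 for I2
  expect_equal(ds$allele1["I2", "rs3"], "0")
  expect_equal(ds$snps$alleles[[2]], c("A", "G"))
})

test_that("malformed PED rows, half-missing calls and duplicates error", {
  f <- write_tiny_ped_map()
  # 6 + 5 allele fields against a 3-SNP map
  writeLines(c("F1\tI1\t0\t0\t1\t-9\tA\tA\tA\tG\tG"), f$ped)
  expect_error(read_ped_map(f$ped, f$map), "line 1.*expected 12")
  writeLines(c("F1\tI1\t0\t0\t1\t-9\tA\tA\tA\tG\tA\t0"), f$ped)
  expect_error(read_ped_map(f$ped, f$map), "half-missing")
  writeLines(c("F1\tI1\t0\t0\t1\t-9\tA\tA\tA\tG\tG\tG",
               "F2\tI1\t0\t0\t2\t-9\tA\tA\tA\tG\tG\tG"), f$ped)
  expect_error(read_ped_map(f$ped, f$map), "duplicate individual_id")
  writeLines(c("1\trs1\t0\t100", "1\trs1\t0"), f$map)
  expect_error(read_ped_map(f$ped, f$map), "line 2 has 3 fields")
})

test_that("negative-bp MAP rows are dropped and sex chromosomes warned", {
  f <- write_tiny_ped_map()
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t-200", "X\trs3\t0\t300"),
             f$map)
  expect_warning(
    expect_warning(ds <- read_ped_map(f$ped, f$map), "negative position"),
    "sex chromosome")
  expect_equal(ds$snps$snp_id, c("rs1", "rs3"))
  expect_equal(dim(ds$allele1), c(2L, 2L))
})

test_that("fixture writer and reader round-trip a simulated dataset", {
  cfg <- sim_config(seed = 42, missing_rate = 0.03)
  fx <- write_fixture(cfg, withr::local_tempdir())
  ds <- read_ped_map(fx$ped, fx$map, sample_info = fx$sample_info)
  expect_identical(ds$allele1, fx$genotypes$allele1)
  expect_identical(ds$allele2, fx$genotypes$allele2)
  expect_identical(ds$samples, fx$genotypes$samples)
  expect_equal(ds$snps$position_bp, fx$genotypes$snps$position_bp)
  # token-for-token: rewriting the files reproduces them exactly
  dir2 <- withr::local_tempdir()
  write_ped_map(ds, file.path(dir2, "g.ped"), file.path(dir2, "g.map"))
  expect_identical(readLines(file.path(dir2, "g.ped")), readLines(fx$ped))
  expect_identical(readLines(file.path(dir2, "g.map")), readLines(fx$map))
})

test_that("region extraction is inclusive, sorted, and errors when empty", {
  f <- write_tiny_ped_map()
  ds <- read_ped_map(f$ped, f$map)  # SNPs at bp 100, 200, 300
  r <- extract_region(ds, "1", 150, 300)
  expect_equal(r$snps$snp_id, c("rs2", "rs3"))
  expect_equal(extract_region(ds, "1", 100, 100)$snps$snp_id, "rs1")
  expect_error(extract_region(ds, "1", 400, 500), "widen")
  expect_error(extract_region(ds, "2", 100, 300), "widen")
  expect_error(extract_region(ds, "1", 300, 100), "exceeds")
  # nested windows: outer-then-inner equals inner directly
  inner <- extract_region(ds, "1", 150, 250)
  expect_identical(extract_region(r, "1", 150, 250), inner)
})

test_that("region extraction agrees with a brute-force filter on chr4", {
  in_range <- snp_panel(10, "4", 8168000, 8790000)
  out_range <- data.frame(
    snp_id = sprintf("rsout%02d", 1:5),
    chromosome = c("4", "4", "7", "7", "4"),
    position_bp = c(8000000, 9000000, 8200000, 8500000, 8100000),
    maf = 0.3, stringsAsFactors = FALSE)
  cfg <- sim_config(snps = rbind(in_range, out_range), seed = 3)
  ds <- simulate_genotypes(cfg)
  r <- extract_region(ds, "4", 8168000, 8790000)
  brute <- cfg$snps$snp_id[cfg$snps$chromosome == "4" &
                             cfg$snps$position_bp >= 8168000 &
                             cfg$snps$position_bp <= 8790000]
  expect_setequal(r$snps$snp_id, brute)
  expect_equal(nrow(r$snps), 10)
  expect_false(is.unsorted(r$snps$position_bp))
})

test_that("SNP-list extraction keeps map order and reports misses", {
  f <- write_tiny_ped_map()
  ds <- read_ped_map(f$ped, f$map)
  expect_equal(extract_snps(ds, c("rs2", "rs1"))$snps$snp_id,
               c("rs1", "rs2"))
  expect_error(extract_snps(ds, "rsX"), "rsX")
  expect_warning(hit <- extract_snps(ds, c("rs1", "rsX")), "rsX")
  expect_equal(hit$snps$snp_id, "rs1")
  expect_error(extract_snps(ds, character(0)), "non-empty")
})

test_that("founder filter keeps 210 of the 270 HapMap-structured samples", {
  ds <- simulate_genotypes(sim_config(seed = 1))
  expect_equal(nrow(ds$samples), 270)
  founders <- filter_founders(ds)
  expect_equal(nrow(founders$samples), 210)
  # idempotent, and an all-founder set is unchanged
  expect_identical(filter_founders(founders), founders)
  # one trio keeps exactly its two parents
  trio <- subset(ds$samples, family_id == "CEU_T001")
  expect_equal(nrow(trio), 3)
  expect_equal(sum(trio$paternal_id == "0" & trio$maternal_id == "0"), 2)
})

test_that("population filter selects labels and pools on request", {
  ds <- simulate_genotypes(sim_config(seed = 1))
  expect_equal(nrow(filter_population(ds, "CEU")$samples), 90)
  expect_equal(nrow(filter_population(ds, "CHB")$samples), 45)
  expect_equal(nrow(filter_population(ds, "JPT")$samples), 45)
  expect_equal(nrow(filter_population(ds, "YRI")$samples), 90)
  expect_identical(filter_population(ds, "pooled"), ds)
  expect_error(filter_population(ds, "FIN"), "CEU.*CHB.*JPT.*YRI")
})

test_that("retained call columns never gain alleles after subsetting", {
  cfg <- sim_config(seed = 9, missing_rate = 0.05)
  ds <- simulate_genotypes(cfg)
  sub <- filter_population(filter_founders(ds), "CEU")
  for (j in seq_len(nrow(sub$snps))) {
    seen <- setdiff(unique(c(sub$allele1[, j], sub$allele2[, j])), "0")
    expect_true(all(seen %in% ds$snps$alleles[[j]]))
  }
})
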