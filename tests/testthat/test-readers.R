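# hand-written miniature files exercise each reader's decoding rules

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("linkage reader decodes the pre-makeped layout", {
  dat <- write_tmp(c(
    "3 0 0 5", "0 0.0 0.0 0", "1 2 3",
    "1 2  # aff", " 0.99 0.01", " 1", " 0 0 1",
    "3 2  # rs1 chr=1", " 0.6 0.4",
    "3 2  # rs2 chr=1", " 0.5 0.5",
    "0 0", "0", "0.1", "1 0.1 0.45"))
  ped <- write_tmp(c(
    "T1 dad 0 0 1 1 1 2 1 1",
    "T1 mom 0 0 2 2 1 1 2 2",
    "T1 kid dad mom 0 0 0 0 0 0"))
  ds <- read_linkage(ped, dat)
  expect_identical(nrow(ds$ped), 3L)
  expect_identical(ds$loci$name, c("rs1", "rs2"))
  expect_identical(ds$loci$allele_freqs[[1]], c(0.6, 0.4))
  # untyped child excluded from typed rows
  expect_setequal(ds$genotypes$typed_keys, c("T1:dad", "T1:mom"))
  # affection: kid unknown (0), dad unaffected, mom affected
  expect_identical(ds$traits$values$aff, c(1L, 2L, NA))
  # sex 0 decodes to unknown
  expect_identical(ds$ped$sex, c("male", "female", "unknown"))
  # allele pair "0 0" means missing; "1 2" het
  codes <- geno_codes(ds$genotypes)
  expect_identical(unname(codes["T1:dad", ]), c(2L, 1L))
  # column-count mismatch names the line
  bad <- write_tmp("T1 solo 0 0 1 1 1 2")
  expect_error(read_linkage(bad, dat), "line 1")
  expect_error(read_linkage(write_tmp(character(0)), dat), "no individuals")
})

test_that("annotated reader joins roles and reorders markers to map order", {
  pedf <- write_tmp(c(
    "Ped Id Father Mother Sex aff bmi m1 m2 m3",
    "A p1 0 0 1 2 24.1 A/C C/C G/G",
    "A p2 0 0 2 1 . A/A C/T G/T",
    "A p3 p1 p2 1 0 31.0 A/C 0/0 G/T"))
  namesf <- write_tmp(c("aff affection", "bmi quantitative",
                        "m1 marker", "m2 marker", "m3 marker"))
  # map order deliberately (m3, m1, m2)
  mapf <- write_tmp(c("chromosome marker avg_cM bp",
                      "1 m3 0.0 500", "1 m1 2.5 900", "1 m2 7.5 1400"))
  ds <- read_annotated(list(pedigree = pedf, names = namesf, map = mapf))
  expect_identical(ds$loci$name, c("m3", "m1", "m2"))
  expect_identical(ds$map$bp, c(500L, 900L, 1400L))
  expect_identical(ds$traits$defs$kind, c("affection", "quantitative"))
  expect_identical(ds$traits$values$bmi, c(24.1, NA, 31.0))
  lp <- geno_pairs(ds$genotypes)
  # m2 for p3 is missing
  expect_true(is.na(lp$a1["A:p3", 3L]))
  # marker missing from the names file is an error listing it
  ped2 <- write_tmp(c("Ped Id Father Mother Sex m9", "A p1 0 0 1 A/A"))
  expect_error(read_annotated(list(pedigree = ped2, names = namesf,
                                         map = mapf)), "m9")
  # frequency file that does not sum to 1 names the locus
  freqf <- write_tmp(c("m1 A 0.58", "m1 C 0.40"))
  expect_error(read_annotated(list(pedigree = pedf, names = namesf,
                                         map = mapf, freq = freqf)),
               "m1")
  # omit entries (wildcard included) are stored for the transform stage
  omitf <- write_tmp(c("A p1 m1", "A p2 *"))
  ds2 <- read_annotated(list(pedigree = pedf, names = namesf,
                                   map = mapf, omit = omitf))
  expect_identical(nrow(ds2$omit), 2L)
  expect_true(is.na(ds2$omit$marker[2]))
})

test_that("plink text reader infers the phenotype kind from its values", {
  mapf <- write_tmp(c("1 s1 0 100", "1 s2 0 200"))
  pedf <- write_tmp(c("X a 0 0 1 2 A C A A",
                      "X b 0 0 2 1 C C A G",
                      "X c a b 1 -9 0 0 G A"))
  ds <- read_plink_text(pedf, mapf)
  expect_identical(ds$traits$defs$kind, "affection")
  expect_identical(ds$traits$values$pheno, c(2L, 1L, NA))
  # a non-code value forces quantitative
  pedq <- write_tmp(c("X a 0 0 1 37.2 A C A A",
                      "X b 0 0 2 0 C C A G"))
  dq <- read_plink_text(pedq, mapf)
  expect_identical(dq$traits$defs$kind, "quantitative")
  expect_identical(dq$traits$values$pheno, c(37.2, 0))
  # allele labels grow as they are observed
  expect_setequal(ds$loci$allele_labels[[1]], c("A", "C"))
  expect_setequal(ds$loci$allele_labels[[2]], c("A", "G"))
  # allele-column count mismatch is a parse error
  bad <- write_tmp("X a 0 0 1 2 A C")
  expect_error(read_plink_text(bad, mapf), "expected 10")
  # alternate phenotype file replaces the column-6 trait
  phf <- write_tmp(c("FID IID status bmi", "X a 2 20.5", "X b 1 31.2",
                     "X c 1 -9", "X zz 2 19"))
  dp <- read_plink_text(pedf, mapf, phf)
  expect_identical(dp$traits$defs$name, c("status", "bmi"))
  expect_identical(dp$traits$values$bmi, c(20.5, 31.2, NA))
  f <- attr(dp, "findings")
  expect_true(any(grepl("X:zz", f$message)))
})

test_that("plink binary reader is bit-exact per the stated code table", {
  dir <- tempfile(); dir.create(dir)
  # byte 0b11100100 = 0xE4 for 4 samples at one SNP:
  # codes (00,01,10,11) = (hom bim-a1, missing, het, hom bim-a2)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xe4)), file.path(dir, "t.bed"))
  writeLines("1 snp1 0 100 C A", file.path(dir, "t.bim"))
  writeLines(sprintf("F%d I1 0 0 1 -9", 1:4), file.path(dir, "t.fam"))
  ds <- read_plink_binary(file.path(dir, "t.bed"), file.path(dir, "t.bim"),
                          file.path(dir, "t.fam"))
  lp <- dataset_label_pairs(ds)
  expect_identical(unname(lp$l1[, 1]), c("C", NA, "A", "A"))
  expect_identical(unname(lp$l2[, 1]), c("C", NA, "C", "A"))
  # wrong magic
  writeBin(as.raw(c(0x6d, 0x1b, 0x01, 0xe4)), file.path(dir, "bad.bed"))
  expect_error(read_plink_binary(file.path(dir, "bad.bed"),
                                 file.path(dir, "t.bim"),
                                 file.path(dir, "t.fam")),
               "not a binary genotype file")
  # individual-major mode byte is an unsupported dialect
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0xe4)), file.path(dir, "im.bed"))
  expect_error(read_plink_binary(file.path(dir, "im.bed"),
                                 file.path(dir, "t.bim"),
                                 file.path(dir, "t.fam")),
               "unsupported dialect")
  # truncation
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(dir, "tr.bed"))
  expect_error(read_plink_binary(file.path(dir, "tr.bed"),
                                 file.path(dir, "t.bim"),
                                 file.path(dir, "t.fam")),
               "truncated")
  # degenerate: magic+mode only with empty bim/fam reads cleanly
  file.create(file.path(dir, "e.bim"), file.path(dir, "e.fam"))
  ds0 <- read_plink_binary(file.path(dir, "tr.bed"), file.path(dir, "e.bim"),
                           file.path(dir, "e.fam"))
  expect_identical(nrow(ds0$ped), 0L)
  expect_identical(nrow(ds0$loci), 0L)
})

test_that("vcf reader maps GT fields, drops phase, and applies the multiallelic policy", {
  vcf <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1\t1|1\t./.",
    "1\t300\trs3\tC\tG,T\t.\tPASS\t.\tGT\t1/2\t0/0\t0/1",
    "2\t50\t.\tT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), ext = ".vcf")
  ds <- read_vcf(vcf)
  # multi-allelic record dropped under the default policy and counted
  expect_identical(nrow(ds$loci), 2L)
  expect_false("rs3" %in% ds$loci$name)
  expect_true(any(grepl("multi-allelic", ds$provenance)))
  # samples become singleton pedigrees named by sample id
  expect_identical(ds$ped$ped, ds$ped$id)
  codes <- geno_codes(ds$genotypes)
  # 0/1 -> het; 1|1 -> hom ALT with phase discarded; ./. -> missing
  expect_identical(unname(codes["S1:S1", 1]), 2L)
  expect_identical(unname(codes["S2:S2", 1]), 3L)
  expect_identical(unname(codes["S3:S3", 1]), 0L)
  # nameless record gets a chrom:pos name; map carries CHROM/POS
  expect_identical(ds$loci$name[2], "2:50")
  expect_identical(ds$map$bp, c(100L, 50L))
  # keep policy retains the triallelic record in general mode
  dsk <- read_vcf(vcf, multiallelic = "keep")
  expect_identical(nrow(dsk$loci), 3L)
  expect_identical(dsk$genotypes$mode, "general")
  expect_identical(dsk$loci$allele_labels[[2]], c("C", "G", "T"))
  # fam sidecar supplies structure
  fam <- write_tmp(c("P1 S1 0 0 1 2", "P1 S2 0 0 2 1", "P1 S3 S1 S2 1 -9"))
  dsf <- read_vcf(vcf, fam_path = fam)
  expect_identical(unique(dsf$ped$ped), "P1")
  expect_identical(dsf$ped$father[3], "S1")
  expect_identical(dsf$traits$defs$kind, "affection")
})
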