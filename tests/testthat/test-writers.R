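test_that("makeped pointers chain children in id order and mark one proband", {
  trio <- simulate_pedigree(1, "trio", seed = 1)
  ptr <- compute_makeped_pointers(trio)
  expect_identical(ptr$first_offspring[1], "I3")
  expect_true(all(is.na(ptr[3, 1:3])))
  expect_identical(sum(ptr$proband), 1L)
  # sibship of 3: chain c1 -> c2 -> c3 on both parental sides
  sib <- simulate_pedigree(1, "sibship_3", seed = 1)
  ps <- compute_makeped_pointers(sib)
  expect_identical(ps$first_offspring[1:2], c("I3", "I3"))
  expect_identical(ps$next_paternal_sib[3:5], c("I4", "I5", NA))
  expect_identical(ps$next_maternal_sib[3:5], c("I4", "I5", NA))
  # childless individuals carry no pointers
  expect_true(all(is.na(ps[5, 1:3])))
})

test_that("the linkage datafile carries Haldane recombination fractions", {
  ds <- make_dataset(seed = 11, n_families = 1, structure = "trio",
                     freqs = c(0.4, 0.6))
  # markers 10 cM apart -> theta = 0.5 (1 - exp(-0.2))
  ds$map$avg_cM <- c(0, 10)
  dir <- tempfile(); dir.create(dir)
  write_linkage(recode_alleles(ds)$dataset, dir, "lk")
  dat <- readLines(file.path(dir, "lk.dat"))
  theta_line <- dat[length(dat) - 1L]
  expect_equal(as.numeric(strsplit(trimws(theta_line), " ")[[1]]),
               0.5 * (1 - exp(-0.2)), tolerance = 1e-6)
  # founder parents written as 0
  pre <- readLines(file.path(dir, "lk.pre"))
  expect_length(pre, 3L)
  expect_match(pre[1], "^F1 I1 0 0 ")
})

test_that("every writer conserves individual, marker, and missing counts", {
  ds <- make_dataset(seed = 12, n_families = 3, structure = "three_generation",
                     freqs = c(0.25, 0.5, 0.9))
  ds <- apply_omit(ds, data.frame(ped = c("F1", "F2"), id = c("I3", "I1"),
                                  marker = c("M2", NA)))
  rec <- recode_alleles(ds)$dataset
  want <- dataset_counts(rec)
  targets <- c(linkage = "linkage_pre", plink_text = "plink_text",
               plink_binary = "plink_binary", merlin = "merlin",
               solar = "solar", eigenstrat = "eigenstrat",
               structure = "structure", fbat = "fbat",
               annotated = "annotated")
  for (oracle_name in names(targets)) {
    dir <- tempfile(); dir.create(dir)
    write_dataset(rec, targets[[oracle_name]], dir, "x")
    got <- oracle_counts(oracle_name, dir, "x")
    expect_identical(got$n_ind, want$n_ind, label = oracle_name)
    expect_identical(got$n_markers, want$n_markers, label = oracle_name)
    expect_identical(as.integer(got$n_missing), want$n_missing,
                     label = oracle_name)
  }
})

test_that("plink binary output is bit-exact: magic, mode, size, decoding", {
  ds <- make_dataset(seed = 13, n_families = 2, structure = "sibship_3",
                     freqs = c(0.3, 0.6, 0.8))
  dir <- tempfile(); dir.create(dir)
  write_plink_binary(ds, dir, "b")
  bed <- readBin(file.path(dir, "b.bed"), "raw", n = 1e6)
  expect_identical(bed[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  n <- nrow(ds$ped); m <- nrow(ds$loci)
  expect_identical(length(bed), 3L + as.integer(ceiling(n / 4)) * m)
  # independent byte-level decode equals the dataset's genotypes
  got <- oracle_counts("plink_binary", dir, "b")
  expect_identical(as.integer(got$n_missing), dataset_counts(ds)$n_missing)
  back <- read_plink_binary(file.path(dir, "b.bed"), file.path(dir, "b.bim"),
                            file.path(dir, "b.fam"))
  expect_true(isTRUE(dataset_identical(ds, back)))
})

test_that("eigenstrat digits agree with the HWE genotype counts per SNP", {
  ds <- make_dataset(seed = 14, n_families = 4, structure = "sibship_2",
                     freqs = c(0.35, 0.55))
  dir <- tempfile(); dir.create(dir)
  write_eigenstrat(ds, dir, "e")
  geno <- readLines(file.path(dir, "e.geno"))
  hw <- hwe_scan(ds, scope = "all")
  for (j in seq_along(geno)) {
    digits <- as.integer(strsplit(geno[j], "")[[1]])
    expect_identical(sum(digits[digits != 9L]),
                     2L * hw$n_hom1[j] + hw$n_het[j])
  }
  # untyped individuals appear as 9 so line width is the full N
  expect_identical(nchar(geno[1]), nrow(ds$ped))
})

test_that("structure and fbat rows have the documented shapes", {
  ds <- make_dataset(seed = 15, n_families = 1, structure = "trio",
                     freqs = c(0.5, 0.5))
  rec <- recode_alleles(ds)$dataset
  dir <- tempfile(); dir.create(dir)
  write_structure(rec, dir, "s")
  st <- readLines(file.path(dir, "s.structure"))
  expect_identical(length(strsplit(st[2], " ")[[1]]), 2L + 2L * 2L)
  write_fbat(rec, dir, "f")
  fb <- readLines(file.path(dir, "f.ped"))
  expect_length(fb, 4L)   # header + 3 individuals
  expect_identical(strsplit(fb[1], " ")[[1]], rec$loci$name)
  # no affection trait -> error naming the requirement
  ds_no <- make_dataset(seed = 15, n_families = 1, structure = "trio",
                        freqs = c(0.5, 0.5), with_trait = FALSE)
  expect_error(write_fbat(recode_alleles(ds_no)$dataset, dir, "f2"),
               "affection")
})

test_that("solar requires one chromosome per file set and per-chromosome output provides it", {
  ds <- make_dataset(seed = 16, n_families = 2, with_trait = TRUE)
  ds$loci$chromosome <- c("1", "1", "2")
  ds$map$chromosome <- c("1", "1", "2")
  rec <- recode_alleles(ds)$dataset
  dir <- tempfile(); dir.create(dir)
  expect_error(write_solar(rec, dir, "s"), "per-chromosome")
  paths <- write_dataset(rec, "solar", dir, "s", per_chromosome = TRUE)
  expect_true(any(grepl("s_chr1", paths)))
  expect_true(any(grepl("s_chr2", paths)))
  # per-chromosome marker sets partition the full set
  mk1 <- readLines(file.path(dir, "s_chr1.map"))[-1]
  mk2 <- readLines(file.path(dir, "s_chr2.map"))[-1]
  got <- sort(vapply(strsplit(c(mk1, mk2), " "), `[[`, character(1), 1L))
  expect_identical(got, sort(rec$loci$name))
  # founders get empty parent fields in the csv
  ped_csv <- readLines(file.path(dir, "pedigree.csv"))
  expect_match(ped_csv[2], "^F1,I1,,,[12]$")
  # freq lines sum to 1
  fl <- readLines(file.path(dir, "s_chr1.freq"))
  for (ln in fl) {
    parts <- strsplit(ln, " ")[[1]]
    expect_equal(sum(as.numeric(parts[seq(3, length(parts), 2)])), 1)
  }
})

test_that("round trips through every readable format reproduce the dataset", {
  for (s in 1:5) {
    ds <- make_dataset(seed = 100 + s, n_families = 2,
                       structure = c("trio", "sibship_2", "three_generation")[s %% 3 + 1],
                       freqs = c(0.2, 0.5, 0.7))
    inj <- inject_defects(ds, missing_rate = 0.1, seed = s)$dataset
    rec <- recode_alleles(inj)$dataset
    dir <- tempfile(); dir.create(dir)
    write_linkage(rec, dir, "lk")
    expect_true(isTRUE(dataset_identical(
      rec, read_linkage(file.path(dir, "lk.pre"), file.path(dir, "lk.dat")))))
    write_plink_text(rec, dir, "pt")
    expect_true(isTRUE(dataset_identical(
      rec, read_plink_text(file.path(dir, "pt.ped"), file.path(dir, "pt.map")))))
    write_plink_binary(rec, dir, "pb")
    expect_true(isTRUE(dataset_identical(
      rec, read_plink_binary(file.path(dir, "pb.bed"), file.path(dir, "pb.bim"),
                             file.path(dir, "pb.fam")))))
    write_annotated(rec, dir, "an")
    expect_true(isTRUE(dataset_identical(
      rec, read_annotated(list(pedigree = file.path(dir, "an.ped"),
                                     names = file.path(dir, "an.names"),
                                     map = file.path(dir, "an.map"),
                                     freq = file.path(dir, "an.freq"))))))
    # text and binary encodings of the same content read identically
    t1 <- read_plink_text(file.path(dir, "pt.ped"), file.path(dir, "pt.map"))
    t2 <- read_plink_binary(file.path(dir, "pb.bed"), file.path(dir, "pb.bim"),
                            file.path(dir, "pb.fam"))
    expect_true(isTRUE(dataset_identical(t1, t2)))
  }
})
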