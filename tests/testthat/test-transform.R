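test_that("allele recoding orders by descending founder frequency with lexicographic ties", {
  tab <- ped_table(rep("P", 4), paste0("f", 1:4), NA, NA,
                   rep(c("male", "female"), 2))
  a1 <- matrix("C", 4, 2); a2 <- matrix("C", 4, 2)
  # locus 1: A freq 0.25 (one het), C 0.75 -> C becomes allele 1
  a1[1, 1] <- "A"
  # locus 2: A and C at 0.5 each -> lexicographic tie-break, A first
  a1[1:2, 2] <- "A"; a2[1:2, 2] <- "A"
  lab <- list(c("A", "C"), c("A", "C"))
  gm <- geno_matrix(matrix(match(a1, c("A", "C")), 4),
                    matrix(match(a2, c("A", "C")), 4), ped_key(tab))
  ds <- ped_dataset(tab, new_loci(c("m1", "m2"), c("1", "1"), lab),
                    new_map(c("1", "1"), c("m1", "m2"), c(0, 5), c(100L, 200L)),
                    gm)
  rec <- recode_alleles(ds)
  expect_identical(rec$dataset$loci$allele_labels[[1]], c("C", "A"))
  expect_identical(rec$dataset$loci$allele_labels[[2]], c("A", "C"))
  expect_identical(rec$table$code[rec$table$locus == "m1" &
                                    rec$table$label == "C"], 1L)
  # idempotent
  rec2 <- recode_alleles(rec$dataset)
  expect_identical(rec2$dataset$loci$allele_labels,
                   rec$dataset$loci$allele_labels)
  expect_identical(dataset_label_pairs(rec2$dataset),
                   dataset_label_pairs(rec$dataset))
  # recoding never changes the missingness pattern
  ds3 <- make_dataset(seed = 9, with_trait = FALSE)
  inj <- inject_defects(ds3, missing_rate = 0.2, seed = 9)
  before <- is.na(dataset_label_pairs(inj$dataset)$l1)
  after <- is.na(dataset_label_pairs(recode_alleles(inj$dataset)$dataset)$l1)
  expect_identical(before, after)
})

test_that("omission blanks the matched genotypes and elides wholly blanked rows", {
  ds <- make_dataset(seed = 2, n_families = 2, with_trait = FALSE)
  miss0 <- gm_missing_count(ds$genotypes)
  omit <- data.frame(ped = c("F1", "F1", "F2"), id = c("I1", "I2", "I3"),
                     marker = c("M1", "M2", "M3"), stringsAsFactors = FALSE)
  ds2 <- apply_omit(ds, omit)
  # counted over the full individual x marker grid (untyped rows too)
  expect_identical(dataset_counts(ds2)$n_missing,
                   dataset_counts(ds)$n_missing + 3L)
  # wildcard removes the individual from the typed rows
  wc <- data.frame(ped = "F1", id = "I1", marker = NA_character_)
  ds3 <- apply_omit(ds, wc)
  expect_false("F1:I1" %in% ds3$genotypes$typed_keys)
  # unknown individual is an error naming it
  expect_error(apply_omit(ds, data.frame(ped = "F9", id = "I1",
                                         marker = NA_character_)), "F9:I1")
  # omission never decreases the missing count
  expect_gte(dataset_counts(ds3)$n_missing, dataset_counts(ds)$n_missing)
  expect_true(miss0 <= gm_missing_count(ds2$genotypes))
})

test_that("locus subsetting preserves map order and honours inclusive bp bounds", {
  tab <- simulate_pedigree(1, "trio", seed = 3)
  codes <- matrix(2L, 3, 5)
  ds <- make_coded_dataset(tab, codes, chromosomes = c("1", "1", "2", "2", "X"))
  d1 <- subset_loci(ds, locus_selector(chromosomes = "1"))
  expect_identical(d1$loci$name, c("M1", "M2"))
  # bp_range inclusive on both ends: markers at 1000, 2000 on chr 2
  d2 <- subset_loci(ds, locus_selector(bp_range = list(chromosome = "2",
                                                       start = 1000,
                                                       end = 1999)))
  expect_identical(d2$loci$name, "M3")
  d3 <- subset_loci(ds, locus_selector(bp_range = list(chromosome = "2",
                                                       start = 1000,
                                                       end = 2000)))
  expect_identical(d3$loci$name, c("M3", "M4"))
  # shuffled name list comes out in map order
  d4 <- subset_loci(ds, locus_selector(names = c("M4", "M1", "M3")))
  expect_identical(d4$loci$name, c("M1", "M3", "M4"))
  expect_error(subset_loci(ds, locus_selector(names = "M99")), "M99")
  expect_error(subset_loci(ds, locus_selector(chromosomes = "7")), "empty")
  expect_identical(nrow(subset_loci(ds, locus_selector(chromosomes = "7"),
                                    allow_empty = TRUE)$loci), 0L)
})

test_that("chromosome splitting partitions the markers and keeps every invariant", {
  ds <- make_dataset(seed = 4, n_families = 2, with_trait = FALSE)
  ds$loci$chromosome <- c("1", "2", "X")
  ds$map$chromosome <- c("1", "2", "X")
  pieces <- split_by_chromosome(ds)
  expect_identical(names(pieces), c("1", "2", "X"))
  for (p in pieces) check_dataset(p)
  expect_identical(sum(vapply(pieces, function(p) nrow(p$loci), integer(1))),
                   nrow(ds$loci))
  # concatenating split genotypes in chromosome order restores the matrix
  lp <- dataset_label_pairs(ds)
  got <- do.call(cbind, lapply(pieces, function(p) dataset_label_pairs(p)$l1))
  expect_identical(unname(got), unname(lp$l1))
  # split-then-subset commutes with subset-then-split
  sel <- locus_selector(chromosomes = c("1", "X"))
  a <- subset_loci(ds, sel)
  b <- split_by_chromosome(ds)[c("1", "X")]
  expect_identical(unlist(lapply(b, function(p) p$loci$name), use.names = FALSE),
                   a$loci$name)
})

test_that("trait selection restricts and reorders columns", {
  ds <- make_dataset(seed = 5, n_families = 1)
  ds$traits$defs <- data.frame(name = c("aff", "bmi", "age"),
                               kind = c("affection", "quantitative", "covariate"),
                               missing_code = c("0", ".", "."),
                               stringsAsFactors = FALSE)
  ds$traits$values$bmi <- rnorm(nrow(ds$ped), 25)
  ds$traits$values$age <- rnorm(nrow(ds$ped), 40)
  d1 <- select_traits(ds, "bmi")
  expect_identical(names(d1$traits$values), "bmi")
  d2 <- select_traits(ds, c("age", "aff"))
  expect_identical(d2$traits$defs$name, c("age", "aff"))
  d3 <- select_traits(ds, c("aff", "bmi", "age"))
  expect_identical(d3$traits$values, ds$traits$values)
  expect_error(select_traits(ds, "iq"), "iq")
})

test_that("nuclear-family conversion duplicates connectors and drops their parents", {
  # trio: unchanged but renamed
  trio <- make_dataset(seed = 6, n_families = 1, structure = "trio",
                       with_trait = FALSE)
  n1 <- to_nuclear_families(trio)
  expect_identical(unique(n1$ped$ped), "F1_F1")
  expect_identical(nrow(n1$ped), 3L)
  # hand 3-generation pedigree: 2 pedigrees, connector in both
  tab <- make_three_gen_tab()
  ds <- make_coded_dataset(tab, matrix(2L, 6, 2))
  nf <- to_nuclear_families(ds)
  expect_length(unique(nf$ped$ped), 2L)
  expect_identical(sum(nf$ped$id == "C1"), 2L)
  # duplicated parent has no parents in the child family
  c1_parent_row <- nf$ped[nf$ped$id == "C1" & is.na(nf$ped$father), ]
  expect_identical(nrow(c1_parent_row), 1L)
  # genotypes copied to duplicates
  lp <- dataset_label_pairs(nf)
  c1_rows <- which(nf$ped$id == "C1")
  expect_identical(lp$l1[c1_rows[1], ], lp$l1[c1_rows[2], ])
  # no individual retains exactly one recorded parent
  expect_identical(sum(xor(is.na(nf$ped$father), is.na(nf$ped$mother))), 0L)
  # pedigree count equals the nuclear family count
  for (s in 1:3) {
    d <- make_dataset(seed = s, n_families = 2, structure = "three_generation",
                      with_trait = FALSE)
    expect_length(unique(to_nuclear_families(d)$ped$ped),
                  length(enumerate_nuclear_families(d$ped)))
  }
})

test_that("transforms preserve dataset invariants", {
  ds <- make_dataset(seed = 7, n_families = 2, structure = "three_generation")
  steps <- list(
    function(d) recode_alleles(d)$dataset,
    function(d) apply_omit(d, data.frame(ped = "F1", id = "I7",
                                         marker = "M1")),
    function(d) subset_loci(d, locus_selector(names = c("M1", "M3"))),
    function(d) select_traits(d, "aff"),
    function(d) to_nuclear_families(d))
  for (step in steps) {
    ds <- step(ds)
    expect_silent(check_dataset(ds))
  }
})
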