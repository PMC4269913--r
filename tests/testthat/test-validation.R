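test_that("structural validation flags the canonical pedigree defects", {
  # absent father
  t1 <- ped_table(c("P", "P"), c("a", "b"), c(NA, "ghost"), c(NA, "a"),
                  c("female", "male"))
  f1 <- validate_structure(t1)
  expect_identical(sum(f1$severity == "error" &
                         grepl("does not name", f1$message)), 1L)
  # father recorded with female sex
  t2 <- ped_table(rep("P", 3), c("pa", "ma", "kid"), c(NA, NA, "pa"),
                  c(NA, NA, "ma"), c("female", "female", "male"))
  f2 <- validate_structure(t2)
  expect_identical(sum(grepl("recorded as father", f2$message)), 1L)
  # two-node ancestry cycle
  t3 <- ped_table(c("P", "P", "P", "P"), c("a", "b", "u", "v"),
                  c("b", "a", NA, NA), c("u", "v", NA, NA),
                  c("male", "male", "female", "female"))
  f3 <- validate_structure(t3)
  expect_gte(sum(grepl("cycle", f3$message)), 1L)
  # one recorded parent only
  t4 <- ped_table(c("P", "P"), c("pa", "kid"), c(NA, "pa"), c(NA, NA),
                  c("male", "male"))
  expect_identical(sum(grepl("exactly one", validate_structure(t4)$message)), 1L)
  # duplicates
  t5 <- ped_table(c("P", "P"), c("a", "a"), c(NA, NA), c(NA, NA),
                  c("male", "male"))
  expect_identical(sum(grepl("duplicate", validate_structure(t5)$message)), 1L)
  # unknown sex warns; untyped pedigree warns at dataset level
  ds <- make_dataset(seed = 1, n_families = 1, with_trait = FALSE)
  ds$ped$sex[3] <- "unknown"
  f <- validate_structure(ds)
  expect_identical(unique(f$severity), "warning")
  # clean simulated pedigrees validate silently across seeds
  for (s in 1:5) {
    tab <- simulate_pedigree(2, c("trio", "sibship_2", "three_generation")[s %% 3 + 1],
                             seed = s)
    expect_identical(nrow(validate_structure(tab)[
      validate_structure(tab)$severity == "error", ]), 0L)
  }
})

test_that("mendelian check agrees with exhaustive trio enumeration on all 64 configurations", {
  tab <- simulate_pedigree(1, "trio", seed = 1)
  for (f_code in 0:3) for (m_code in 0:3) for (c_code in 0:3) {
    ds <- make_coded_dataset(tab, matrix(c(f_code, m_code, c_code), ncol = 1))
    found <- nrow(check_mendelian(ds)) > 0L
    expected <- !trio_oracle_consistent(f_code, m_code, c_code)
    expect_identical(found, expected,
                     label = sprintf("father=%d mother=%d child=%d found=%s",
                                     f_code, m_code, c_code, found))
  }
})

test_that("mendelian check handles missing-parent sibship logic", {
  tab <- simulate_pedigree(1, "sibship_2", seed = 1)
  # father 1/1, mother missing: children 2/2 and 1/1 jointly impossible?
  # mother would need to give '2' to one child, fine; but child 2/2
  # needs 2 from the 1/1 father -> impossible regardless of mother
  ds <- make_coded_dataset(tab, matrix(c(1, 0, 3, 1), ncol = 1))
  mf <- check_mendelian(ds)
  expect_identical(nrow(mf), 1L)
  expect_identical(mf$reason, "child_allele_absent_from_parent")
  # both parents missing, three+ children can still be jointly impossible
  # only with >2 founder alleles; with 2 alleles any sibship is completable
  ds2 <- make_coded_dataset(tab, matrix(c(0, 0, 1, 3), ncol = 1))
  expect_identical(nrow(check_mendelian(ds2)), 0L)
  # both parents typed and excluded -> parents_exclude_child
  ds3 <- make_coded_dataset(tab, matrix(c(1, 1, 2, 1), ncol = 1))
  mf3 <- check_mendelian(ds3)
  expect_identical(mf3$reason, "parents_exclude_child")
})

test_that("mendelian resolution policies blank the stated genotypes", {
  tab <- simulate_pedigree(1, "trio", seed = 1)
  ds <- make_coded_dataset(tab, matrix(c(1, 1, 2, 2, 2, 2), ncol = 2))
  mf <- check_mendelian(ds)
  expect_identical(nrow(mf), 1L)       # marker 1 only
  miss0 <- gm_missing_count(ds$genotypes)
  r0 <- resolve_mendelian(ds, mf, "report_only")
  expect_identical(gm_missing_count(r0$genotypes), miss0)
  rc <- resolve_mendelian(ds, mf, "zero_child")
  expect_identical(gm_missing_count(rc$genotypes), miss0 + 1L)
  rf <- resolve_mendelian(ds, mf, "zero_family_marker")
  expect_identical(gm_missing_count(rf$genotypes), miss0 + 3L)
  # marker 2 untouched
  expect_identical(geno_codes(rf$genotypes)[, 2], geno_codes(ds$genotypes)[, 2])
  expect_error(resolve_mendelian(ds, mf, "zap_everything"))
})

test_that("zero_family_marker resolution is a fixed point on error-injected data", {
  for (s in 1:3) {
    ds <- make_dataset(seed = s, n_families = 4, structure = "three_generation",
                       with_trait = FALSE)
    inj <- suppressWarnings(inject_defects(ds, mendel_error_rate = 0.08,
                                           seed = s))
    mf <- check_mendelian(inj$dataset)
    fixed <- resolve_mendelian(inj$dataset, mf, "zero_family_marker")
    expect_identical(nrow(check_mendelian(fixed)), 0L)
  }
})

test_that("allele frequency estimation counts the chosen scope", {
  tab <- ped_table(rep("P", 4), c("f1", "f2", "f3", "kid"),
                   c(NA, NA, NA, "f1"), c(NA, NA, NA, "f2"),
                   c("male", "female", "female", "male"))
  # founders 1/1, 1/2, 2/2 -> freq(1) = 0.5 whatever the child has
  ds <- make_coded_dataset(tab, matrix(c(1, 2, 3, 1), ncol = 1))
  fr <- estimate_allele_frequencies(ds, "founders")
  expect_identical(unname(fr[[1]]["1"]), 0.5)
  # scope=all counts the child's 1/1 too: 5 of 8
  fa <- estimate_allele_frequencies(ds, "all")
  expect_identical(unname(fa[[1]]["1"]), 5 / 8)
  # founders untyped -> uniform fallback plus warning finding
  ds2 <- make_coded_dataset(tab, matrix(c(0, 0, 0, 2), ncol = 1))
  f2 <- estimate_allele_frequencies(ds2, "founders")
  expect_identical(unname(f2[[1]]), c(0.5, 0.5))
  expect_identical(attr(f2, "findings")$severity, "warning")
})

test_that("frequency estimates recover simulated truth within 3 binomial SE", {
  tab <- simulate_pedigree(100, "trio", seed = 3)   # 200 founders
  ds <- gene_drop(tab, freqs = 0.3, seed = 17)
  fr <- estimate_allele_frequencies(ds, "founders")
  se <- sqrt(0.3 * 0.7 / (2 * 200))
  expect_lt(abs(unname(fr[[1]]["1"]) - 0.3), 3 * se)
})

test_that("the HWE chi-square matches hand-computed and reference values", {
  # exact HWE proportions
  r <- test_hwe(25, 50, 25)
  expect_identical(r$chi2, 0)
  expect_identical(r$p_value, 1)
  # all-heterozygote extreme: expected (25, 50, 25) -> chi2 = 100
  r2 <- test_hwe(0, 100, 0)
  expect_equal(r2$chi2, 100)
  expect_equal(r2$p_hat, 0.5)
  # monomorphic
  r3 <- test_hwe(10, 0, 0)
  expect_identical(r3$chi2, 0)
  expect_true(r3$monomorphic)
  expect_error(test_hwe(-1, 5, 5), "nonnegative")
  # invariant under count swap / allele relabelling
  r4 <- test_hwe(12, 30, 41)
  r5 <- test_hwe(41, 30, 12)
  expect_equal(r4$chi2, r5$chi2)
  # cross-check against the stock Pearson test on the genotype table
  obs <- c(12, 30, 41)
  n <- sum(obs); p <- (2 * 12 + 30) / (2 * n)
  ref <- suppressWarnings(stats::chisq.test(
    obs, p = c(p^2, 2 * p * (1 - p), (1 - p)^2)))
  expect_equal(r4$chi2, unname(ref$statistic))
})

test_that("the HWE test is calibrated at nominal level under the null", {
  set.seed(97)
  n <- 200; p <- 0.4; n_sim <- 2000
  counts <- stats::rmultinom(n_sim, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  pvals <- vapply(seq_len(n_sim), function(i)
    test_hwe(counts[1, i], counts[2, i], counts[3, i])$p_value, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("male X heterozygotes are flagged and blanked; X skipped in HWE scans", {
  tab <- ped_table(rep("F1", 3), c("I1", "I2", "I3"), c(NA, NA, "I1"),
                   c(NA, NA, "I2"), c("male", "female", "female"))
  ds <- make_coded_dataset(tab, matrix(c(2, 2, 2, 1, 1, 2), ncol = 2),
                           chromosomes = c("X", "1"))
  ds2 <- validate_x_genotypes(ds)
  f <- attr(ds2, "findings")
  expect_identical(nrow(f), 1L)   # father het on X (I1 male); child male 1/1 fine
  expect_identical(unname(geno_codes(ds2$genotypes)[1, 1]), 0L)
  hw <- hwe_scan(ds2, scope = "all")
  expect_false("M1" %in% hw$marker)
  expect_true(any(grepl("X-linked", attr(hw, "findings")$message)))
})

test_that("summaries report rates, typed fractions, and generation counts", {
  tab <- make_three_gen_tab()
  codes <- matrix(1L, 6, 5)
  ds <- make_coded_dataset(tab, codes)
  s <- summarize_dataset(ds)
  expect_true(all(s$markers$call_rate == 1))
  expect_identical(s$pedigrees$n_generations, 3L)
  expect_identical(s$pedigrees$n_founders, 3L)
  # 2 of 10 genotypes missing at a marker -> rate 0.8
  tab2 <- simulate_pedigree(2, "sibship_3", seed = 5)   # 10 individuals
  codes2 <- matrix(2L, 10, 1); codes2[c(3, 7), 1] <- 0L
  ds2 <- make_coded_dataset(tab2, codes2)
  s2 <- summarize_dataset(ds2)
  expect_identical(s2$markers$call_rate, 0.8)
  expect_identical(s2$individuals$typed_fraction[3], 0)
})

test_that("the mendelian check treats simulated clean data as clean", {
  for (s in 1:3) {
    ds <- make_dataset(seed = s, n_families = 3, structure = "three_generation",
                       with_trait = FALSE)
    expect_identical(nrow(check_mendelian(ds)), 0L)
  }
})
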