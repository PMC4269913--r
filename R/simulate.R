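#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination
#' fraction under no interference:
#' theta = (1 - exp(-2 d / 100)) / 2, monotone increasing and bounded
#' by 1/2.
#'
#' @param d_cM nonnegative genetic distance(s) in centimorgans.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_theta <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distances must be nonnegative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Inverse Haldane map function
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @return genetic distance(s) in centimorgans.
#' @export
haldane_cM <- function(theta) {
  if (any(theta < 0 | theta >= 0.5)) {
    stop("recombination fractions must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * theta)
}

# all randomness flows from one seed; per-operation seeds are derived by
# fixed offsets so stages stay independently reproducible
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

#' Simulate pedigree structures
#'
#' Deterministic given the seed (the trio and sibship structures are in
#' fact seed-free; the seed only feeds sex assignment of children).
#' Ids follow the pattern `F<i>` for pedigrees and `I<j>` for
#' individuals; sexes are always consistent with parental roles.
#'
#' Structures: `trio` (father, mother, child), `sibship_k` (two parents
#' and `k` children; `sibship_3` gives families of five), and
#' `three_generation` (a grandparental couple, two of their children
#' married to two founder spouses, and two grandchildren per couple).
#'
#' @param n_families number of replicate families (>= 1).
#' @param structure `"trio"`, `"sibship_<k>"`, or `"three_generation"`.
#' @param seed integer seed.
#' @return a [ped_table()].
#' @export
simulate_pedigree <- function(n_families, structure = "trio", seed = 1L) {
  stopifnot(n_families >= 1L)
  set.seed(derive_seed(seed, 1L))
  rows <- list()
  add <- function(ped, id, fa, mo, sex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ped = ped, id = id, father = fa, mother = mo, sex = sex,
      stringsAsFactors = FALSE)
  }
  rand_sex <- function(k) sample(c("male", "female"), k, replace = TRUE)
  sib_k <- if (grepl("^sibship_[0-9]+$", structure)) {
    as.integer(sub("^sibship_", "", structure))
  } else NA_integer_
  for (i in seq_len(n_families)) {
    fid <- paste0("F", i)
    if (structure == "trio" || !is.na(sib_k)) {
      k <- if (structure == "trio") 1L else sib_k
      add(fid, "I1", NA, NA, "male")
      add(fid, "I2", NA, NA, "female")
      sx <- rand_sex(k)
      for (c in seq_len(k)) add(fid, paste0("I", 2L + c), "I1", "I2", sx[c])
    } else if (structure == "three_generation") {
      add(fid, "I1", NA, NA, "male")        # grandparents
      add(fid, "I2", NA, NA, "female")
      add(fid, "I3", "I1", "I2", "male")    # their two children
      add(fid, "I4", "I1", "I2", "female")
      add(fid, "I5", NA, NA, "female")      # married-in spouses
      add(fid, "I6", NA, NA, "male")
      sx <- rand_sex(4L)
      add(fid, "I7", "I3", "I5", sx[1])     # grandchildren
      add(fid, "I8", "I3", "I5", sx[2])
      add(fid, "I9", "I6", "I4", sx[3])
      add(fid, "I10", "I6", "I4", sx[4])
    } else {
      stop("unknown structure '", structure,
           "' (trio, sibship_<k>, three_generation)")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ped_table", "data.frame")
  out
}

#' Drop genes down a pedigree
#'
#' Founders receive genotypes drawn allele-wise at the stated
#' frequencies (hence in Hardy-Weinberg proportions); each child
#' inherits one haplotype per parent, built by walking the markers with
#' a crossover probability per adjacent interval given by the Haldane
#' function on the map distances.  The construction guarantees zero
#' Mendelian inconsistencies.  Deterministic per seed.
#'
#' @param tab a structure-valid [ped_table()].
#' @param freqs list of per-locus allele-1 frequencies (scalars) *or*
#'   numeric vector, one frequency per locus; loci are biallelic with
#'   labels "1" and "2".
#' @param map a map data frame ([new_map()]); defaults to 5-cM-spaced
#'   markers `M1..Mk` on chromosome 1.
#' @param seed integer seed.
#' @param marker_names names for default-map markers.
#' @return a [ped_dataset()] with true frequencies stored on the loci.
#' @export
gene_drop <- function(tab, freqs, map = NULL, seed = 1L, marker_names = NULL) {
  p1 <- as.numeric(unlist(freqs))
  m <- length(p1)
  stopifnot(m >= 1L, all(p1 >= 0 & p1 <= 1))
  if (is.null(map)) {
    if (is.null(marker_names)) marker_names <- paste0("M", seq_len(m))
    map <- new_map(chromosome = rep("1", m), marker = marker_names,
                   avg_cM = (seq_len(m) - 1L) * 5, bp = seq_len(m) * 100000L)
  }
  stopifnot(nrow(map) == m)
  d <- diff(map$avg_cM)
  d[map$chromosome[-1] != map$chromosome[-m]] <- Inf   # unlinked
  theta <- ifelse(is.infinite(d), 0.5, haldane_theta(pmax(d, 0)))

  set.seed(derive_seed(seed, 2L))
  keys <- ped_key(tab)
  n <- nrow(tab)
  hap1 <- matrix(NA_integer_, n, m)
  hap2 <- hap1
  gen <- ped_generations(tab)
  if (anyNA(gen)) stop("gene_drop requires an acyclic, structure-valid pedigree")
  ord <- order(gen)
  fi <- match(parent_key(tab, "father"), keys)
  mi <- match(parent_key(tab, "mother"), keys)
  draw_founder_hap <- function() {
    ifelse(stats::runif(m) < p1, 1L, 2L)
  }
  gamete <- function(h1, h2) {
    # walk markers; switch strand with prob theta at each interval
    strand <- integer(m)
    strand[1] <- sample.int(2L, 1L)
    if (m > 1L) {
      sw <- stats::runif(m - 1L) < theta
      strand[-1] <- (cumsum(sw) + strand[1]) %% 2L
      strand[strand == 0L] <- 2L
    }
    ifelse(strand == 1L, h1, h2)
  }
  for (i in ord) {
    if (is.na(fi[i])) {
      hap1[i, ] <- draw_founder_hap()
      hap2[i, ] <- draw_founder_hap()
    } else {
      hap1[i, ] <- gamete(hap1[fi[i], ], hap2[fi[i], ])
      hap2[i, ] <- gamete(hap1[mi[i], ], hap2[mi[i], ])
    }
  }
  gm <- geno_matrix(hap1, hap2, keys, mode = "auto")
  loci <- new_loci(map$marker, map$chromosome,
                   rep(list(c("1", "2")), m),
                   lapply(p1, function(p) c(p, 1 - p)))
  ds <- ped_dataset(tab, loci, map, gm)
  add_provenance(ds, sprintf(
    "gene drop: %d individuals, %d markers, seed %d", n, m, as.integer(seed)))
}

#' Inject controlled defects into a dataset
#'
#' Plants Mendelian errors by re-drawing a child genotype to a
#' configuration the nuclear-family consistency oracle marks
#' impossible given the rest of the family (families where no such
#' configuration exists — e.g. both parents heterozygous — are
#' skipped), then applies uniform missingness, then flips the sex of
#' randomly chosen parents.  Every planted defect is recorded in the
#' returned truth tables, which are authoritative when fewer defects
#' than requested could be planted.  Deterministic per seed.
#'
#' @param ds a biallelic [ped_dataset()] (typically from [gene_drop()]).
#' @param mendel_error_rate fraction of (nuclear family, marker) pairs
#'   to corrupt.
#' @param missing_rate fraction of typed genotypes to blank.
#' @param sex_error_count number of parents whose sex to flip.
#' @param seed integer seed.
#' @return list with `dataset` and `truth` (data frames
#'   `mendel`, `missing`, `sex`).
#' @export
inject_defects <- function(ds, mendel_error_rate = 0, missing_rate = 0,
                           sex_error_count = 0L, seed = 1L) {
  stopifnot(mendel_error_rate >= 0, mendel_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(derive_seed(seed, 3L))
  keys <- ped_key(ds$ped)
  p <- dataset_pairs(ds)
  m <- ds$genotypes$n_markers
  fams <- enumerate_nuclear_families(ds$ped)
  truth_mendel <- data.frame(pedigree = character(), father = character(),
                             mother = character(), marker = character(),
                             individual = character(), stringsAsFactors = FALSE)
  # family-marker cells carrying a planted error are shielded from the
  # missingness pass so every plant stays oracle-detectable
  shield <- matrix(FALSE, nrow(ds$ped), max(m, 1L))

  if (mendel_error_rate > 0 && length(fams) > 0L && m > 0L) {
    cells <- expand.grid(f = seq_along(fams), j = seq_len(m))
    n_target <- round(mendel_error_rate * nrow(cells))
    pick <- sample(nrow(cells), min(n_target, nrow(cells)))
    genos <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
    n_skipped <- 0L
    for (r in pick) {
      fam <- fams[[cells$f[r]]]
      j <- cells$j[r]
      fkey <- ped_key(fam$ped, fam$father)
      mkey <- ped_key(fam$ped, fam$mother)
      ckeys <- ped_key(fam$ped, fam$children)
      gof <- function(key) {
        i <- match(key, keys)
        if (is.na(p$a1[i, j])) NULL else c(p$a1[i, j], p$a2[i, j])
      }
      child <- sample(ckeys, 1L)
      others <- setdiff(ckeys, child)
      bad_genos <- Filter(function(g) {
        !family_marker_consistent(gof(fkey), gof(mkey),
                                  c(list(g), Filter(Negate(is.null),
                                                    lapply(others, gof))))
      }, genos)
      if (length(bad_genos) == 0L) { n_skipped <- n_skipped + 1L; next }
      g <- bad_genos[[sample.int(length(bad_genos), 1L)]]
      i <- match(child, keys)
      p$a1[i, j] <- g[1]
      p$a2[i, j] <- g[2]
      shield[match(c(fkey, mkey, ckeys), keys), j] <- TRUE
      truth_mendel[nrow(truth_mendel) + 1L, ] <-
        list(fam$ped, fam$father, fam$mother, ds$loci$name[j],
             ds$ped$id[i])
    }
    if (n_skipped > 0L) {
      warning(n_skipped, " Mendel error(s) could not be planted (no ",
              "inconsistent configuration exists); the truth list is ",
              "authoritative")
    }
  }

  truth_missing <- data.frame(pedigree = character(), individual = character(),
                              marker = character(), stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    typed_cells <- which(!is.na(p$a1) & !shield)
    blank <- typed_cells[stats::runif(length(typed_cells)) < missing_rate]
    if (length(blank)) {
      ij <- arrayInd(blank, dim(p$a1))
      truth_missing <- data.frame(pedigree = ds$ped$ped[ij[, 1]],
                                  individual = ds$ped$id[ij[, 1]],
                                  marker = ds$loci$name[ij[, 2]],
                                  stringsAsFactors = FALSE)
      p$a1[blank] <- NA_integer_
      p$a2[blank] <- NA_integer_
    }
  }

  truth_sex <- data.frame(pedigree = character(), individual = character(),
                          stringsAsFactors = FALSE)
  if (sex_error_count > 0L) {
    parents <- which(keys %in% c(parent_key(ds$ped, "father"),
                                 parent_key(ds$ped, "mother")))
    flip <- parents[sample.int(length(parents),
                               min(sex_error_count, length(parents)))]
    ds$ped$sex[flip] <- ifelse(ds$ped$sex[flip] == "male", "female", "male")
    truth_sex <- data.frame(pedigree = ds$ped$ped[flip],
                            individual = ds$ped$id[flip],
                            stringsAsFactors = FALSE)
  }

  ds <- dataset_set_pairs(ds, p$a1, p$a2)
  ds <- add_provenance(ds, sprintf(
    "defects: %d mendel, %d missing, %d sex flips planted",
    nrow(truth_mendel), nrow(truth_missing), nrow(truth_sex)))
  list(dataset = ds,
       truth = list(mendel = truth_mendel, missing = truth_missing,
                    sex = truth_sex))
}

#' Write a defect truth list as TSV
#'
#' @param truth the `truth` component of [inject_defects()] output.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_truth_tsv <- function(truth, dir, stem = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(truth)) {
    path <- file.path(dir, paste0(stem, "_", nm, ".tsv"))
    utils::write.table(truth[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
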