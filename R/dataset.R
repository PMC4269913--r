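#' Assemble a matched pedigree/locus/map/genotype/trait dataset
#'
#' The dataset is the object every pipeline stage consumes and
#' produces: a pedigree graph, an ordered locus list, a genetic map, a
#' genotype matrix over typed individuals, a trait table, and a
#' provenance trail of the stages it has passed through.
#'
#' @param ped a [ped_table()].
#' @param loci data frame with columns `name`, `chromosome`, and list
#'   columns `allele_labels` (character vectors) and `allele_freqs`
#'   (numeric vectors or `NULL`).
#' @param map data frame with columns `chromosome`, `marker`,
#'   `female_cM`, `male_cM`, `avg_cM`, `bp` (1-based physical position).
#' @param genotypes a [geno_matrix()] whose typed keys are a subset of
#'   the pedigree keys and whose marker count equals `nrow(loci)`.
#' @param traits list with `defs` (data frame: `name`, `kind` in
#'   affection/quantitative/covariate, `missing_code`) and `values`
#'   (data frame, one row per pedigree row, one column per trait;
#'   affection coded 1 = unaffected, 2 = affected, `NA` = unknown).
#' @param provenance character vector of stage descriptions.
#' @return object of class `ped_dataset`.
#' @export
ped_dataset <- function(ped, loci, map, genotypes, traits = empty_traits(nrow(ped)),
                        provenance = character()) {
  ds <- structure(list(ped = ped, loci = loci, map = map,
                       genotypes = genotypes, traits = traits,
                       provenance = provenance),
                  class = "ped_dataset")
  check_dataset(ds)
  ds
}

empty_traits <- function(n) {
  list(defs = data.frame(name = character(), kind = character(),
                         missing_code = character(), stringsAsFactors = FALSE),
       values = as.data.frame(matrix(nrow = n, ncol = 0)))
}

new_loci <- function(name, chromosome, allele_labels, allele_freqs = NULL) {
  if (is.null(allele_freqs)) allele_freqs <- rep(list(NULL), length(name))
  out <- data.frame(name = as.character(name),
                    chromosome = as.character(chromosome),
                    stringsAsFactors = FALSE)
  out$allele_labels <- allele_labels
  out$allele_freqs <- allele_freqs
  out
}

new_map <- function(chromosome, marker, avg_cM, bp,
                    female_cM = avg_cM, male_cM = avg_cM) {
  data.frame(chromosome = as.character(chromosome), marker = as.character(marker),
             female_cM = as.numeric(female_cM), male_cM = as.numeric(male_cM),
             avg_cM = as.numeric(avg_cM), bp = as.integer(bp),
             stringsAsFactors = FALSE)
}

#' Check the internal invariants of a dataset
#'
#' Verifies the cross-component contracts: unique individual keys,
#' locus/map/genotype agreement, typed keys resolving in the pedigree,
#' per-locus allele frequencies summing to one, nondecreasing physical
#' positions within a chromosome, and a trait table covering every
#' individual.  Called by every constructor and transform; raises an
#' error on violation.
#'
#' @param ds a `ped_dataset`.
#' @return `ds`, invisibly.
#' @export
check_dataset <- function(ds) {
  stopifnot(inherits(ds, "ped_dataset"))
  keys <- ped_key(ds$ped)
  if (anyDuplicated(keys)) {
    stop("duplicate (pedigree, individual) ids: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  if (nrow(ds$loci) != ds$genotypes$n_markers) {
    stop("locus list (", nrow(ds$loci), ") and genotype matrix (",
         ds$genotypes$n_markers, ") disagree on marker count")
  }
  if (anyDuplicated(ds$loci$name)) stop("duplicated marker names")
  if (!all(ds$genotypes$typed_keys %in% keys)) {
    stop("genotype matrix references individuals absent from the pedigree")
  }
  if (nrow(ds$map) > 0L) {
    if (!all(ds$loci$name %in% ds$map$marker)) {
      stop("markers missing from the genetic map: ",
           paste(setdiff(ds$loci$name, ds$map$marker), collapse = ", "))
    }
    for (chr in unique(ds$map$chromosome)) {
      bp <- ds$map$bp[ds$map$chromosome == chr]
      if (is.unsorted(bp)) {
        stop("physical positions on chromosome ", chr, " are not nondecreasing")
      }
    }
    if (any(ds$map$bp < 1L)) stop("physical positions must be >= 1")
    if (any(ds$map$female_cM < 0 | ds$map$male_cM < 0 | ds$map$avg_cM < 0)) {
      stop("genetic map positions must be nonnegative")
    }
  }
  for (i in seq_len(nrow(ds$loci))) {
    lab <- ds$loci$allele_labels[[i]]
    if (anyDuplicated(lab)) {
      stop("duplicate allele labels at locus ", ds$loci$name[i])
    }
    fr <- ds$loci$allele_freqs[[i]]
    if (!is.null(fr)) {
      if (length(fr) != length(lab)) {
        stop("allele frequency list length mismatch at locus ", ds$loci$name[i])
      }
      if (abs(sum(fr) - 1) > 1e-6) {
        stop("allele frequencies at locus ", ds$loci$name[i],
             " sum to ", format(sum(fr)), ", not 1")
      }
    }
  }
  if (nrow(ds$traits$values) != nrow(ds$ped)) {
    stop("trait table does not cover every individual")
  }
  if (!identical(as.character(names(ds$traits$values)), ds$traits$defs$name)) {
    stop("trait value columns do not match trait definitions")
  }
  invisible(ds)
}

#' @export
print.ped_dataset <- function(x, ...) {
  cat(sprintf(paste0("<ped_dataset> %d individuals (%d typed) in %d pedigree(s), ",
                     "%d markers, %d trait(s)\n"),
              nrow(x$ped), length(x$genotypes$typed_keys),
              length(unique(x$ped$ped)), nrow(x$loci), nrow(x$traits$defs)))
  cat(sprintf("  genotype storage: %s mode\n", x$genotypes$mode))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    cat(paste0("    - ", x$provenance, "\n"), sep = "")
  }
  invisible(x)
}

add_provenance <- function(ds, msg) {
  ds$provenance <- c(ds$provenance, msg)
  ds
}

# full allele-pair matrices (all individuals x markers), rows keyed
dataset_pairs <- function(ds) {
  geno_pairs_full(ds$genotypes, ped_key(ds$ped))
}

# rebuild the genotype matrix from full allele-pair matrices, keeping mode
# where possible ("auto" drops back to two_bit when biallelic)
dataset_set_pairs <- function(ds, a1, a2, mode = ds$genotypes$mode) {
  half <- ds$genotypes$half_typed_demoted
  gm <- geno_matrix(a1, a2, ped_key(ds$ped), mode = mode)
  gm$half_typed_demoted <- half
  ds$genotypes <- gm
  ds
}

# genotypes as label pairs, a list of n x m character matrices (sorted
# within pair); the representation used for format-independent equality
dataset_label_pairs <- function(ds) {
  p <- dataset_pairs(ds)
  l1 <- matrix(NA_character_, nrow(p$a1), ncol(p$a1))
  l2 <- l1
  for (j in seq_len(ncol(p$a1))) {
    lab <- ds$loci$allele_labels[[j]]
    l1[, j] <- lab[p$a1[, j]]
    l2[, j] <- lab[p$a2[, j]]
  }
  swap <- !is.na(l1) & l1 > l2
  tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
  rownames(l1) <- rownames(l2) <- rownames(p$a1)
  list(l1 = l1, l2 = l2)
}

#' Test two datasets for scientific identity
#'
#' Two datasets are considered identical when they agree on the
#' pedigree structure (ids, parent links, sex), the locus list (names,
#' chromosomes, allele label sets), and every genotype compared as an
#' unordered allele-*label* pair.  Storage mode, allele numbering, map,
#' and provenance are representation details and are not compared.
#'
#' @param a,b `ped_dataset` objects.
#' @return `TRUE` or a character vector describing the first differences.
#' @export
dataset_identical <- function(a, b) {
  diffs <- character()
  pa <- a$ped[order(ped_key(a$ped)), c("ped", "id", "father", "mother", "sex")]
  pb <- b$ped[order(ped_key(b$ped)), c("ped", "id", "father", "mother", "sex")]
  rownames(pa) <- rownames(pb) <- NULL
  if (!identical(pa, pb)) diffs <- c(diffs, "pedigree tables differ")
  if (!identical(a$loci$name, b$loci$name)) {
    diffs <- c(diffs, "marker names differ")
  } else if (!identical(gsub("^chr", "", a$loci$chromosome),
                        gsub("^chr", "", b$loci$chromosome))) {
    diffs <- c(diffs, "chromosome labels differ")
  } else {
    seta <- lapply(a$loci$allele_labels, sort)
    setb <- lapply(b$loci$allele_labels, sort)
    # a label observed in no genotype may be dropped (text formats) or
    # padded with a placeholder (binary formats); the observed label
    # sets must agree in any case
    ga <- dataset_label_pairs(a)
    gb <- dataset_label_pairs(b)
    used <- function(g, j) sort(unique(stats::na.omit(c(g$l1[, j], g$l2[, j]))))
    used_a <- lapply(seq_len(nrow(a$loci)), used, g = ga)
    used_b <- lapply(seq_len(nrow(b$loci)), used, g = gb)
    same_lab <- mapply(function(x, y, ux, uy)
      identical(x, y) || identical(ux, uy), seta, setb, used_a, used_b)
    if (!all(same_lab)) {
      diffs <- c(diffs, paste("allele label sets differ at:",
                              paste(a$loci$name[!same_lab], collapse = ", ")))
    }
    oa <- order(rownames(ga$l1)); ob <- order(rownames(gb$l1))
    if (!(identical(ga$l1[oa, , drop = FALSE], gb$l1[ob, , drop = FALSE]) &&
          identical(ga$l2[oa, , drop = FALSE], gb$l2[ob, , drop = FALSE]))) {
      diffs <- c(diffs, "genotypes differ")
    }
  }
  if (length(diffs) == 0L) TRUE else diffs
}
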