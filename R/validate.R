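#' Structural validation of a pedigree graph
#'
#' The first error-checking stage.  Emits `error` findings for missing
#' referenced parents, individuals with exactly one recorded parent,
#' fathers not male / mothers not female (when sex is known), ancestry
#' cycles, and duplicated (pedigree, individual) ids; `warning`
#' findings for unknown sex and (when a full dataset is supplied) for
#' pedigrees with no typed member.  Error-severity structure findings
#' block conversion in the batch pipeline unless the override flag is
#' set.
#'
#' @param x a [ped_table()] or a [ped_dataset()].
#' @return findings data frame (possibly empty); errors are returned,
#'   never raised.
#' @export
validate_structure <- function(x) {
  tab <- if (inherits(x, "ped_dataset")) x$ped else x
  keys <- ped_key(tab)
  out <- list()
  err <- function(...) finding("error", "structure", ...)
  wrn <- function(...) finding("warning", "structure", ...)

  dup <- unique(keys[duplicated(keys)])
  for (k in dup) out[[length(out) + 1L]] <-
    err(paste0("duplicate individual id ", k), individual = k)

  one_parent <- xor(is.na(tab$father), is.na(tab$mother))
  for (i in which(one_parent)) out[[length(out) + 1L]] <-
    err("individual has exactly one recorded parent",
        pedigree = tab$ped[i], individual = tab$id[i])

  for (which_par in c("father", "mother")) {
    pk <- parent_key(tab, which_par)
    missing_ref <- !is.na(pk) & !(pk %in% keys)
    for (i in which(missing_ref)) out[[length(out) + 1L]] <-
      err(paste0(which_par, " id '", tab[[which_par]][i],
                 "' does not name an individual in the pedigree"),
          pedigree = tab$ped[i], individual = tab$id[i])
    idx <- match(pk, keys)
    want <- if (which_par == "father") "male" else "female"
    role_sex <- tab$sex[idx]
    bad <- !is.na(idx) & !is.na(role_sex) & !(role_sex %in% c(want, "unknown"))
    for (i in unique(idx[bad])) out[[length(out) + 1L]] <-
      err(paste0("recorded as ", which_par, " but sex is ", tab$sex[i]),
          pedigree = tab$ped[i], individual = tab$id[i])
  }

  gen <- ped_generations(tab)
  # unresolved depth with all parent references resolving = ancestry cycle
  fk <- match(parent_key(tab, "father"), keys)
  mk <- match(parent_key(tab, "mother"), keys)
  on_cycle <- is.na(gen)
  for (i in which(on_cycle)) {
    anc_ok <- (is.na(tab$father[i]) || !is.na(fk[i])) &&
      (is.na(tab$mother[i]) || !is.na(mk[i]))
    if (anc_ok) out[[length(out) + 1L]] <-
      err("individual is its own ancestor (pedigree cycle)",
          pedigree = tab$ped[i], individual = tab$id[i])
  }

  for (i in which(tab$sex == "unknown")) out[[length(out) + 1L]] <-
    wrn("sex is unknown", pedigree = tab$ped[i], individual = tab$id[i])

  if (inherits(x, "ped_dataset")) {
    typed_ped <- unique(tab$ped[keys %in% x$genotypes$typed_keys])
    for (p in setdiff(unique(tab$ped), typed_ped)) out[[length(out) + 1L]] <-
      wrn("pedigree has no typed member", pedigree = p)
  }
  f <- do.call(bind_findings, c(out, list(no_findings())))
  if (is.null(f)) no_findings() else f
}

# ---- Mendelian checking -------------------------------------------------

all_genotype_pairs <- function(alleles) {
  n <- length(alleles)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  }
  out
}

child_compatible <- function(cg, f, m) {
  (cg[1] %in% f && cg[2] %in% m) || (cg[2] %in% f && cg[1] %in% m)
}

# Joint consistency of one nuclear family at one marker.  fg/mg are
# length-2 integer vectors or NULL when untyped; children is a list of
# length-2 vectors (typed children only).  Missing parents are completed
# exhaustively over the alleles observed in the family plus one extra
# "anything else" allele, which is sufficient for biparental transmission.
family_marker_consistent <- function(fg, mg, children) {
  if (length(children) == 0L) return(TRUE)
  seen <- sort(unique(c(fg, mg, unlist(children))))
  universe <- c(seen, max(seen, 0L) + 1L)
  f_cands <- if (is.null(fg)) all_genotype_pairs(universe) else list(fg)
  m_cands <- if (is.null(mg)) all_genotype_pairs(universe) else list(mg)
  for (f in f_cands) {
    for (m in m_cands) {
      if (all(vapply(children, child_compatible, logical(1), f = f, m = m))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect Mendelian inconsistencies
#'
#' Checks every nuclear family at every marker for genotype
#' configurations impossible under biparental transmission.  Missing
#' genotypes are unconstrained: a family/marker is flagged only when
#' *no* completion of the missing parental genotypes (drawn from the
#' alleles observed in the family plus one additional allele) permits
#' all typed children.  Checking is per nuclear family; cross-family
#' joint consistency through shared individuals is not attempted.
#'
#' @param ds a structure-valid [ped_dataset()].
#' @return data frame with one row per inconsistent (family, marker):
#'   columns `pedigree`, `father`, `mother`, `marker`, `reason`
#'   (`child_allele_absent_from_parent`, `parents_exclude_child`, or
#'   `sibship_inconsistent`).
#' @export
check_mendelian <- function(ds) {
  fams <- enumerate_nuclear_families(ds$ped)
  out <- data.frame(pedigree = character(), father = character(),
                    mother = character(), marker = character(),
                    reason = character(), stringsAsFactors = FALSE)
  if (length(fams) == 0L || ds$genotypes$n_markers == 0L) return(out)
  keys <- ped_key(ds$ped)
  p <- dataset_pairs(ds)
  get_g <- function(key, j) {
    i <- match(key, keys)
    if (is.na(p$a1[i, j])) NULL else c(p$a1[i, j], p$a2[i, j])
  }
  for (fam in fams) {
    fkey <- ped_key(fam$ped, fam$father)
    mkey <- ped_key(fam$ped, fam$mother)
    ckeys <- ped_key(fam$ped, fam$children)
    for (j in seq_len(ds$genotypes$n_markers)) {
      fg <- get_g(fkey, j)
      mg <- get_g(mkey, j)
      children <- Filter(Negate(is.null), lapply(ckeys, get_g, j = j))
      if (family_marker_consistent(fg, mg, children)) next
      reason <- if (!is.null(fg) && !is.null(mg)) {
        "parents_exclude_child"
      } else {
        solo_bad <- any(vapply(children, function(cg)
          !family_marker_consistent(fg, mg, list(cg)), logical(1)))
        if (solo_bad) "child_allele_absent_from_parent" else "sibship_inconsistent"
      }
      out[nrow(out) + 1L, ] <- list(fam$ped, fam$father, fam$mother,
                                    ds$loci$name[j], reason)
    }
  }
  out
}

#' Resolve Mendelian inconsistencies
#'
#' @param ds the dataset the findings were computed on.
#' @param findings output of [check_mendelian()].
#' @param policy `"report_only"` leaves genotypes untouched;
#'   `"zero_child"` blanks the genotypes of the offending children
#'   (every typed child when no single child can be blamed);
#'   `"zero_family_marker"` (default) blanks father, mother, and all
#'   children at the flagged marker — conservative, and the fixed point
#'   of re-checking.
#' @return the dataset with genotypes zeroed per policy; provenance
#'   records the counts.
#' @export
resolve_mendelian <- function(ds, findings,
                              policy = c("zero_family_marker", "zero_child",
                                         "report_only")) {
  policy <- match.arg(policy)
  if (policy == "report_only" || nrow(findings) == 0L) {
    return(add_provenance(ds, sprintf(
      "mendel: %d inconsistent family-markers, policy %s, 0 genotypes zeroed",
      nrow(findings), policy)))
  }
  keys <- ped_key(ds$ped)
  p <- dataset_pairs(ds)
  marker_idx <- match(findings$marker, ds$loci$name)
  n_zeroed <- 0L
  fams <- enumerate_nuclear_families(ds$ped)
  fam_of <- function(row) {
    for (fam in fams) {
      if (fam$ped == findings$pedigree[row] &&
          fam$father == findings$father[row] &&
          fam$mother == findings$mother[row]) return(fam)
    }
    stop("finding does not resolve to a nuclear family")
  }
  for (r in seq_len(nrow(findings))) {
    fam <- fam_of(r)
    j <- marker_idx[r]
    ckeys <- ped_key(fam$ped, fam$children)
    targets <- if (policy == "zero_family_marker") {
      c(ped_key(fam$ped, fam$father), ped_key(fam$ped, fam$mother), ckeys)
    } else {
      get_g <- function(key) {
        i <- match(key, keys)
        if (is.na(p$a1[i, j])) NULL else c(p$a1[i, j], p$a2[i, j])
      }
      fg <- get_g(ped_key(fam$ped, fam$father))
      mg <- get_g(ped_key(fam$ped, fam$mother))
      typed_ck <- ckeys[!vapply(ckeys, function(k) is.null(get_g(k)), logical(1))]
      solo <- vapply(typed_ck, function(k)
        !family_marker_consistent(fg, mg, list(get_g(k))), logical(1))
      if (any(solo)) typed_ck[solo] else typed_ck
    }
    i <- match(targets, keys)
    n_zeroed <- n_zeroed + sum(!is.na(p$a1[i, j]))
    p$a1[i, j] <- NA_integer_
    p$a2[i, j] <- NA_integer_
  }
  ds <- dataset_set_pairs(ds, p$a1, p$a2)
  add_provenance(ds, sprintf(
    "mendel: %d inconsistent family-markers, policy %s, %d genotypes zeroed",
    nrow(findings), policy, n_zeroed))
}

# ---- allele frequencies -------------------------------------------------

#' Estimate allele frequencies by counting
#'
#' Counting estimator over the non-missing genotypes of the chosen
#' scope.  Founders are the default scope so that large sibships do not
#' overweight their parental alleles.  A locus where no allele can be
#' counted falls back to uniform frequencies with a warning finding
#' (attached as the `"findings"` attribute).
#'
#' @param ds a [ped_dataset()].
#' @param scope `"founders"` (default) or `"all"`.
#' @return named list, one numeric frequency vector per locus (named by
#'   allele label); attribute `"findings"` carries warnings.
#' @export
estimate_allele_frequencies <- function(ds, scope = c("founders", "all")) {
  scope <- match.arg(scope)
  keys <- ped_key(ds$ped)
  use <- if (scope == "founders") keys %in% find_founders(ds$ped) else
    rep(TRUE, length(keys))
  p <- dataset_pairs(ds)
  warns <- list()
  out <- vector("list", nrow(ds$loci))
  names(out) <- ds$loci$name
  for (j in seq_len(nrow(ds$loci))) {
    lab <- ds$loci$allele_labels[[j]]
    cnt <- tabulate(c(p$a1[use, j], p$a2[use, j]), nbins = length(lab))
    if (sum(cnt) == 0L) {
      out[[j]] <- stats::setNames(rep(1 / length(lab), length(lab)), lab)
      warns[[length(warns) + 1L]] <- finding(
        "warning", "frequency", marker = ds$loci$name[j],
        message = paste0("no countable alleles in scope '", scope,
                         "'; uniform frequencies assumed"))
    } else {
      out[[j]] <- stats::setNames(cnt / sum(cnt), lab)
    }
  }
  attr(out, "findings") <- do.call(bind_findings,
                                   c(warns, list(no_findings())))
  out
}

# stamp estimated frequencies into the locus table (loci lacking them only,
# unless overwrite)
set_allele_frequencies <- function(ds, freqs = NULL, scope = "founders",
                                   overwrite = FALSE) {
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(ds, scope)
  for (j in seq_len(nrow(ds$loci))) {
    if (overwrite || is.null(ds$loci$allele_freqs[[j]])) {
      ds$loci$allele_freqs[[j]] <- as.numeric(freqs[[ds$loci$name[j]]])
    }
  }
  check_dataset(ds)
}

# ---- Hardy-Weinberg -----------------------------------------------------

#' Pearson chi-square test for Hardy-Weinberg equilibrium
#'
#' One biallelic marker: observed genotype counts are compared with the
#' expected proportions p^2, 2pq, q^2 at the sample allele frequency
#' p-hat = (2 n_hom1 + n_het) / 2n, on 1 degree of freedom, without
#' continuity correction.  Monomorphic markers return chi2 = 0, p = 1.
#'
#' @param n_hom1,n_het,n_hom2 nonnegative genotype counts.
#' @param marker optional marker name carried into the result.
#' @return list with `marker`, the three counts, `p_hat`, `chi2`, `df`,
#'   `p_value`, and `monomorphic`.
#' @export
test_hwe <- function(n_hom1, n_het, n_hom2, marker = NA_character_) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0)) stop("genotype counts must be nonnegative")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual is required")
  p_hat <- (2 * n_hom1 + n_het) / (2 * n)
  if (p_hat %in% c(0, 1)) {
    return(list(marker = marker, n_hom1 = n_hom1, n_het = n_het,
                n_hom2 = n_hom2, p_hat = p_hat, chi2 = 0, df = 1L,
                p_value = 1, monomorphic = TRUE))
  }
  q_hat <- 1 - p_hat
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(marker = marker, n_hom1 = n_hom1, n_het = n_het, n_hom2 = n_hom2,
       p_hat = p_hat, chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Hardy-Weinberg scan over the markers of a dataset
#'
#' Applies [test_hwe()] to every biallelic autosomal marker, counting
#' genotypes over founders by default.  X-linked markers are skipped
#' unless `include_x = TRUE` (male X heterozygotes must be resolved
#' first, see [validate_x_genotypes()]).
#'
#' @param ds a [ped_dataset()].
#' @param scope `"founders"` or `"all"`.
#' @param include_x test X-linked markers too?
#' @return data frame with one row per tested marker plus an attribute
#'   `"findings"` (info findings for monomorphic or skipped markers).
#' @export
hwe_scan <- function(ds, scope = c("founders", "all"), include_x = FALSE) {
  scope <- match.arg(scope)
  keys <- ped_key(ds$ped)
  use <- if (scope == "founders") keys %in% find_founders(ds$ped) else
    rep(TRUE, length(keys))
  p <- dataset_pairs(ds)
  notes <- list()
  rows <- list()
  chr <- marker_chromosomes(ds)
  for (j in seq_len(nrow(ds$loci))) {
    if (length(ds$loci$allele_labels[[j]]) > 2L) next
    if (is_x_chrom(chr[j]) && !include_x) {
      notes[[length(notes) + 1L]] <- finding(
        "info", "hwe", marker = ds$loci$name[j],
        message = "X-linked marker skipped")
      next
    }
    a1 <- p$a1[use, j]; a2 <- p$a2[use, j]
    ok <- !is.na(a1)
    if (!any(ok)) next
    res <- test_hwe(sum(a1[ok] == 1L & a2[ok] == 1L),
                    sum(a1[ok] == 1L & a2[ok] == 2L),
                    sum(a1[ok] == 2L & a2[ok] == 2L),
                    marker = ds$loci$name[j])
    if (res$monomorphic) notes[[length(notes) + 1L]] <- finding(
      "info", "hwe", marker = ds$loci$name[j],
      message = "monomorphic marker: chi2 = 0, p = 1")
    rows[[length(rows) + 1L]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), n_hom1 = integer(), n_het = integer(),
               n_hom2 = integer(), p_hat = numeric(), chi2 = numeric(),
               df = integer(), p_value = numeric(), monomorphic = logical())
  attr(out, "findings") <- do.call(bind_findings, c(notes, list(no_findings())))
  out
}

marker_chromosomes <- function(ds) {
  if (nrow(ds$map) == 0L) return(ds$loci$chromosome)
  ds$map$chromosome[match(ds$loci$name, ds$map$marker)]
}

is_x_chrom <- function(chr) {
  toupper(gsub("^chr", "", chr)) %in% c("X", "23")
}

#' Detect and blank male X-chromosome heterozygotes
#'
#' A male cannot be heterozygous on the X outside the pseudoautosomal
#' region; such genotypes are flagged as error findings and set to
#' missing so they cannot bias allele-frequency or HWE computation.
#'
#' @param ds a [ped_dataset()].
#' @return the corrected dataset with a `"findings"` attribute.
#' @export
validate_x_genotypes <- function(ds) {
  chr <- marker_chromosomes(ds)
  xj <- which(is_x_chrom(chr))
  males <- ds$ped$sex == "male"
  if (length(xj) == 0L || !any(males)) {
    attr(ds, "findings") <- no_findings()
    return(ds)
  }
  p <- dataset_pairs(ds)
  out <- list()
  for (j in xj) {
    het <- which(males & !is.na(p$a1[, j]) & p$a1[, j] != p$a2[, j])
    for (i in het) out[[length(out) + 1L]] <- finding(
      "error", "structure", pedigree = ds$ped$ped[i],
      individual = ds$ped$id[i], marker = ds$loci$name[j],
      message = "male heterozygous on X chromosome; genotype set to missing")
    p$a1[het, j] <- NA_integer_
    p$a2[het, j] <- NA_integer_
  }
  if (length(out)) ds <- dataset_set_pairs(ds, p$a1, p$a2)
  ds <- add_provenance(ds, sprintf("x-check: %d male X heterozygotes blanked",
                                   length(out)))
  attr(ds, "findings") <- do.call(bind_findings, c(out, list(no_findings())))
  ds
}

# ---- summaries ----------------------------------------------------------

#' Genotype, phenotype, and pedigree summary tables
#'
#' @param ds a [ped_dataset()].
#' @return list of data frames: `markers` (genotyping rate and allele
#'   counts per marker), `individuals` (typed fraction), `traits`
#'   (missingness; affected/unaffected counts for affection traits),
#'   `pedigrees` (size, founder count, generation count).
#' @export
summarize_dataset <- function(ds) {
  keys <- ped_key(ds$ped)
  n <- nrow(ds$ped)
  m <- ds$genotypes$n_markers
  p <- dataset_pairs(ds)

  typed <- !is.na(p$a1)
  markers <- data.frame(
    marker = ds$loci$name, chromosome = marker_chromosomes(ds),
    n_typed = colSums(typed), n_missing = n - colSums(typed),
    call_rate = if (n > 0) colSums(typed) / n else numeric(m),
    n_alleles = vapply(ds$loci$allele_labels, length, integer(1)),
    stringsAsFactors = FALSE)

  individuals <- data.frame(
    pedigree = ds$ped$ped, individual = ds$ped$id,
    typed_fraction = if (m > 0) rowSums(typed) / m else numeric(n),
    stringsAsFactors = FALSE)

  nt <- nrow(ds$traits$defs)
  traits <- data.frame(name = ds$traits$defs$name, kind = ds$traits$defs$kind,
                       n_missing = rep(NA_integer_, nt),
                       n_unaffected = rep(NA_integer_, nt),
                       n_affected = rep(NA_integer_, nt),
                       stringsAsFactors = FALSE)
  for (t in seq_len(nrow(traits))) {
    v <- ds$traits$values[[t]]
    traits$n_missing[t] <- sum(is.na(v))
    if (traits$kind[t] == "affection") {
      traits$n_unaffected[t] <- sum(v == 1, na.rm = TRUE)
      traits$n_affected[t] <- sum(v == 2, na.rm = TRUE)
    }
  }

  gen <- ped_generations(ds$ped)
  founders <- find_founders(ds$ped)
  peds <- unique(ds$ped$ped)
  pedigrees <- data.frame(
    pedigree = peds,
    size = vapply(peds, function(x) sum(ds$ped$ped == x), integer(1)),
    n_founders = vapply(peds, function(x)
      sum(keys %in% founders & ds$ped$ped == x), integer(1)),
    n_generations = vapply(peds, function(x)
      max(gen[ds$ped$ped == x], na.rm = TRUE), integer(1)),
    n_typed = vapply(peds, function(x)
      sum(keys[ds$ped$ped == x] %in% ds$genotypes$typed_keys), integer(1)),
    stringsAsFactors = FALSE)
  rownames(pedigrees) <- NULL
  list(markers = markers, individuals = individuals, traits = traits,
       pedigrees = pedigrees)
}

#' Write summary tables as TSV files
#'
#' @param summaries output of [summarize_dataset()].
#' @param dir output directory; one `summary_<table>.tsv` per table.
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_summary_tsv <- function(summaries, dir, stem = "summary") {
  paths <- character()
  for (nm in names(summaries)) {
    path <- file.path(dir, paste0(stem, "_", nm, ".tsv"))
    utils::write.table(summaries[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}
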