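#' Recode allele labels to numeric indices by descending frequency
#'
#' LINKAGE-family output formats require numeric allele codes.  Alleles
#' are numbered per locus by descending founder frequency (estimated if
#' absent), ties broken lexicographically by label, so that allele 1 is
#' the major allele — the common LINKAGE-era convention.  The operation
#' is idempotent.
#'
#' @param ds a [ped_dataset()].
#' @param scope frequency-estimation scope when frequencies are absent.
#' @return list with `dataset` (recoded) and `table` (data frame
#'   `locus`, `label`, `code` — the audit trail, exportable as TSV).
#' @export
recode_alleles <- function(ds, scope = "founders") {
  ds <- set_allele_frequencies(ds, scope = scope)
  p <- dataset_pairs(ds)
  rows <- list()
  for (j in seq_len(nrow(ds$loci))) {
    lab <- ds$loci$allele_labels[[j]]
    fr <- ds$loci$allele_freqs[[j]]
    ord <- order(-fr, lab)
    perm <- match(seq_along(lab), ord)   # old index -> new code
    ds$loci$allele_labels[[j]] <- lab[ord]
    ds$loci$allele_freqs[[j]] <- fr[ord]
    a1 <- perm[p$a1[, j]]
    a2 <- perm[p$a2[, j]]
    p$a1[, j] <- pmin(a1, a2)
    p$a2[, j] <- pmax(a1, a2)
    rows[[j]] <- data.frame(locus = ds$loci$name[j], label = lab[ord],
                            code = seq_along(lab), stringsAsFactors = FALSE)
  }
  ds <- dataset_set_pairs(ds, p$a1, p$a2)
  ds <- add_provenance(ds, "recode: alleles renumbered by descending frequency")
  list(dataset = check_dataset(ds),
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(locus = character(), label = character(), code = integer()))
}

#' Read an omit file
#'
#' Whitespace-delimited rows `pedigree individual marker`; marker `*`
#' is a wildcard blanking the individual's whole genotype row.  Lines
#' starting with `#` are comments.
#'
#' @param path omit file path.
#' @return data frame `ped`, `id`, `marker` (`NA` = wildcard).
#' @export
read_omit_file <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(ped = character(), id = character(),
                      marker = character(), stringsAsFactors = FALSE))
  }
  tok <- lapply(lines, split_ws)
  bad <- vapply(tok, length, integer(1)) != 3L
  if (any(bad)) stop("omit file: expected 3 columns on line ", which(bad)[1])
  tok <- do.call(rbind, tok)
  data.frame(ped = tok[, 1], id = tok[, 2],
             marker = ifelse(tok[, 3] == "*", NA_character_, tok[, 3]),
             stringsAsFactors = FALSE)
}

#' Set selected genotypes to unknown
#'
#' @param ds a [ped_dataset()].
#' @param omit data frame as from [read_omit_file()]: columns `ped`,
#'   `id`, `marker` (`NA` = all markers of that individual).
#' @return the dataset with the matched genotypes blanked; an
#'   individual whose whole row is blanked leaves the typed set.
#' @export
apply_omit <- function(ds, omit) {
  if (nrow(omit) == 0L) return(ds)
  keys <- ped_key(ds$ped)
  okeys <- ped_key(omit$ped, omit$id)
  unknown <- !(okeys %in% keys)
  if (any(unknown)) {
    stop("omit entries reference unknown individuals: ",
         paste(unique(okeys[unknown]), collapse = ", "))
  }
  bad_marker <- !is.na(omit$marker) & !(omit$marker %in% ds$loci$name)
  if (any(bad_marker)) {
    stop("omit entries reference unknown markers: ",
         paste(unique(omit$marker[bad_marker]), collapse = ", "))
  }
  p <- dataset_pairs(ds)
  n_blanked <- 0L
  for (r in seq_len(nrow(omit))) {
    i <- match(okeys[r], keys)
    j <- if (is.na(omit$marker[r])) seq_len(ncol(p$a1)) else
      match(omit$marker[r], ds$loci$name)
    n_blanked <- n_blanked + sum(!is.na(p$a1[i, j]))
    p$a1[i, j] <- NA_integer_
    p$a2[i, j] <- NA_integer_
  }
  ds <- dataset_set_pairs(ds, p$a1, p$a2)
  add_provenance(ds, sprintf("omit: %d entries applied, %d genotypes blanked",
                             nrow(omit), n_blanked))
}

#' Build a locus selector
#'
#' @param chromosomes character vector of chromosome labels, or
#' @param names character vector of marker names, or
#' @param bp_range list with `chromosome`, `start`, `end` (inclusive on
#'   both ends: marker positions are points, not intervals).
#' @return object of class `locus_selector`.
#' @export
locus_selector <- function(chromosomes = NULL, names = NULL, bp_range = NULL) {
  given <- c(chromosomes = !is.null(chromosomes), names = !is.null(names),
             bp_range = !is.null(bp_range))
  if (sum(given) != 1L) stop("exactly one selector mode must be given")
  mode <- names(given)[given]
  if (mode == "bp_range") {
    stopifnot(!is.null(bp_range$chromosome),
              bp_range$start <= bp_range$end)
  }
  structure(list(mode = mode,
                 payload = switch(mode, chromosomes = as.character(chromosomes),
                                  names = as.character(names),
                                  bp_range = bp_range)),
            class = "locus_selector")
}

norm_chr <- function(x) toupper(gsub("^chr", "", as.character(x)))

#' Restrict a dataset to a subset of loci
#'
#' Loci, map, and genotype columns are restricted; original relative
#' (map) order is preserved regardless of the order names are given in.
#'
#' @param ds a [ped_dataset()].
#' @param selector a [locus_selector()].
#' @param allow_empty allow a selection of zero loci?
#' @return the restricted dataset.
#' @export
subset_loci <- function(ds, selector, allow_empty = FALSE) {
  stopifnot(inherits(selector, "locus_selector"))
  chr <- marker_chromosomes(ds)
  keep <- switch(selector$mode,
    chromosomes = norm_chr(chr) %in% norm_chr(selector$payload),
    names = {
      unknown <- setdiff(selector$payload, ds$loci$name)
      if (length(unknown)) {
        stop("unknown markers in selection: ", paste(unknown, collapse = ", "))
      }
      ds$loci$name %in% selector$payload
    },
    bp_range = {
      bp <- ds$map$bp[match(ds$loci$name, ds$map$marker)]
      norm_chr(chr) == norm_chr(selector$payload$chromosome) &
        !is.na(bp) & bp >= selector$payload$start & bp <= selector$payload$end
    })
  if (!any(keep) && !allow_empty) {
    stop("locus selection is empty (set allow_empty to permit this)")
  }
  j <- which(keep)
  ds$loci <- ds$loci[j, , drop = FALSE]
  rownames(ds$loci) <- NULL
  ds$map <- ds$map[ds$map$marker %in% ds$loci$name, , drop = FALSE]
  rownames(ds$map) <- NULL
  ds$genotypes <- gm_subset_markers(ds$genotypes, j)
  ds <- add_provenance(ds, sprintf("subset: %d of %d loci kept (%s)",
                                   length(j), length(keep), selector$mode))
  check_dataset(ds)
}

#' Split a dataset by chromosome
#'
#' @param ds a [ped_dataset()].
#' @return named list of datasets, one per chromosome in map order;
#'   pedigree and traits are duplicated into each.
#' @export
split_by_chromosome <- function(ds) {
  chr <- marker_chromosomes(ds)
  labels <- unique(chr)
  out <- lapply(labels, function(x)
    subset_loci(ds, locus_selector(chromosomes = x), allow_empty = TRUE))
  names(out) <- labels
  out
}

#' Restrict and reorder the trait table
#'
#' @param ds a [ped_dataset()].
#' @param trait_names traits to keep, in the desired column order.
#' @return the dataset with the trait table restricted.
#' @export
select_traits <- function(ds, trait_names) {
  unknown <- setdiff(trait_names, ds$traits$defs$name)
  if (length(unknown)) {
    stop("unknown traits: ", paste(unknown, collapse = ", "))
  }
  idx <- match(trait_names, ds$traits$defs$name)
  ds$traits$defs <- ds$traits$defs[idx, , drop = FALSE]
  rownames(ds$traits$defs) <- NULL
  ds$traits$values <- ds$traits$values[, idx, drop = FALSE]
  ds <- add_provenance(ds, paste("traits: selected",
                                 paste(trait_names, collapse = ", ")))
  check_dataset(ds)
}

#' Break pedigrees into their nuclear families
#'
#' Each nuclear family becomes its own pedigree named
#' `<origPed>_F<k>` (`k` in enumeration order within the original
#' pedigree).  Connector individuals are duplicated into every family
#' they belong to but keep their individual id, so cross-family
#' identity stays traceable; the parents of duplicated parents are
#' dropped (parents become founders of the child family).  Genotypes
#' and traits are copied to every duplicate.
#'
#' @param ds a structure-valid [ped_dataset()].
#' @return the decomposed dataset.
#' @export
to_nuclear_families <- function(ds) {
  fams <- enumerate_nuclear_families(ds$ped)
  if (length(fams) == 0L) return(add_provenance(ds, "nuclear: 0 families"))
  keys <- ped_key(ds$ped)
  p <- dataset_pairs(ds)
  k_in_ped <- integer()
  rows <- list()
  src <- integer()
  for (fam in fams) {
    k_in_ped[fam$ped] <- (if (is.na(k_in_ped[fam$ped])) 0L else
      k_in_ped[fam$ped]) + 1L
    new_ped <- sprintf("%s_F%d", fam$ped, k_in_ped[fam$ped])
    ids <- c(fam$father, fam$mother, fam$children)
    parent_of <- function(id, which) {
      if (id %in% fam$children) {
        if (which == "father") fam$father else fam$mother
      } else NA_character_   # parents become founders here
    }
    i <- match(ped_key(fam$ped, ids), keys)
    sex <- ds$ped$sex[i]
    # parental roles pin unknown sexes in the copy
    sex[1] <- if (sex[1] == "unknown") "male" else sex[1]
    sex[2] <- if (sex[2] == "unknown") "female" else sex[2]
    rows[[length(rows) + 1L]] <- data.frame(
      ped = new_ped, id = ids,
      father = vapply(ids, parent_of, character(1), which = "father"),
      mother = vapply(ids, parent_of, character(1), which = "mother"),
      sex = sex, stringsAsFactors = FALSE)
    src <- c(src, i)
  }
  new_tab <- do.call(rbind, rows)
  rownames(new_tab) <- NULL
  class(new_tab) <- c("ped_table", "data.frame")
  ds2 <- ds
  ds2$ped <- new_tab
  ds2$traits$values <- ds$traits$values[src, , drop = FALSE]
  rownames(ds2$traits$values) <- NULL
  ds2 <- dataset_set_pairs(ds2, p$a1[src, , drop = FALSE],
                           p$a2[src, , drop = FALSE],
                           mode = ds$genotypes$mode)
  ds2 <- add_provenance(ds2, sprintf(
    "nuclear: %d pedigree(s) decomposed into %d nuclear families",
    length(unique(ds$ped$ped)), length(fams)))
  check_dataset(ds2)
}

#' Export a recode table as TSV
#'
#' @param table the `table` component of [recode_alleles()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recode_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
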