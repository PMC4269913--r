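#' Compute makeped-style offspring/sibling pointers
#'
#' The post-makeped LINKAGE dialect augments each individual with a
#' first-offspring pointer and next-paternal/maternal-sibling pointers,
#' plus a proband flag.  Children are chained in individual-id order;
#' the proband is the first-listed member of each pedigree's first
#' founder couple (deterministic; an explicit proband column can be
#' passed through instead via the writer's `proband` option).
#'
#' @param tab a structure-valid [ped_table()].
#' @return data frame aligned to `tab` rows with columns
#'   `first_offspring`, `next_paternal_sib`, `next_maternal_sib`
#'   (individual ids, `NA` = none) and logical `proband`.
#' @export
compute_makeped_pointers <- function(tab) {
  n <- nrow(tab)
  out <- data.frame(first_offspring = rep(NA_character_, n),
                    next_paternal_sib = rep(NA_character_, n),
                    next_maternal_sib = rep(NA_character_, n),
                    proband = rep(FALSE, n), stringsAsFactors = FALSE)
  keys <- ped_key(tab)
  chain <- function(parent_col) {
    for (p in unique(stats::na.omit(tab[[parent_col]]))) {
      # a parent id is scoped to its pedigree
      for (pp in unique(tab$ped[!is.na(tab[[parent_col]]) & tab[[parent_col]] == p])) {
        kids <- sort(tab$id[tab$ped == pp & !is.na(tab[[parent_col]]) &
                              tab[[parent_col]] == p])
        pi <- match(ped_key(pp, p), keys)
        if (!is.na(pi) && is.na(out$first_offspring[pi])) {
          out$first_offspring[pi] <<- kids[1]
        }
        col <- if (parent_col == "father") "next_paternal_sib" else
          "next_maternal_sib"
        if (length(kids) > 1L) {
          ki <- match(ped_key(pp, kids), keys)
          out[[col]][ki[-length(ki)]] <<- kids[-1]
        }
      }
    }
  }
  chain("father")
  chain("mother")
  fams <- enumerate_nuclear_families(tab)
  for (p in unique(tab$ped)) {
    pf <- Filter(function(f) f$ped == p, fams)
    founder_couples <- Filter(function(f) {
      fi <- match(ped_key(p, f$father), keys)
      mi <- match(ped_key(p, f$mother), keys)
      all(is.na(tab$father[c(fi, mi)]) & is.na(tab$mother[c(fi, mi)]))
    }, pf)
    if (length(founder_couples) == 0L) next
    f1 <- founder_couples[[1]]
    idx <- match(ped_key(p, c(f1$father, f1$mother)), keys)
    out$proband[min(idx)] <- TRUE
  }
  out
}

# full-penetrance placeholder used when an affection trait has no
# penetrance model on file
default_penetrance <- function(trait_name) {
  list(trait_name = trait_name, disease_allele_freq = 0.01,
       penetrances = c(0, 0, 1))
}

penetrance_for <- function(ds, trait_name) {
  for (pm in ds$penetrance) {
    if (identical(pm$trait_name, trait_name)) return(pm)
  }
  default_penetrance(trait_name)
}

#' Write a LINKAGE pedigree + locus file pair
#'
#' Emits the classic pre-makeped pedigree layout (pedigree, individual,
#' father, mother, sex, affection columns, allele pairs; founders'
#' parents coded 0) or, for the post dialect, the pointer-augmented
#' layout from [compute_makeped_pointers()].  The datafile carries the
#' locus count, one affection locus block (disease allele frequencies
#' plus penetrances) per affection trait, numbered-allele marker blocks,
#' and inter-marker recombination fractions derived from adjacent
#' sex-averaged map positions through the inverse Haldane function.
#' Marker names and chromosome labels ride on `#` comments so a
#' round-trip through [read_linkage()] is lossless on loci.
#'
#' @param ds a [ped_dataset()] whose alleles have been numerically
#'   recoded ([recode_alleles()]) and that carries allele frequencies.
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.pre`/`<stem>.ped` and
#'   `<stem>.dat`.
#' @param dialect `"pre"` (default) or `"post"` makeped.
#' @return character vector of written paths, invisibly.
#' @export
write_linkage <- function(ds, dir, stem = "out", dialect = c("pre", "post")) {
  dialect <- match.arg(dialect)
  check_dataset(ds)
  n_all <- vapply(ds$loci$allele_labels, length, integer(1))
  if (any(n_all > 2L) && ds$genotypes$mode == "two_bit") {
    stop("marker(s) with >2 alleles: ",
         paste(ds$loci$name[n_all > 2L], collapse = ", "),
         "; audit the allele recode before LINKAGE export")
  }
  aff <- which(ds$traits$defs$kind == "affection")
  dropped <- ds$traits$defs$name[ds$traits$defs$kind != "affection"]
  if (length(dropped)) {
    warning("LINKAGE output carries affection traits only; dropping: ",
            paste(dropped, collapse = ", "))
  }
  # LINKAGE alleles are numbers 1..k.  A locus whose labels already are
  # the numerals {1..k} keeps them (lossless round trip); any other
  # label set is written by internal allele index (recode order).
  out_num <- lapply(ds$loci$allele_labels, function(lab) {
    num <- suppressWarnings(as.integer(lab))
    if (length(lab) && !anyNA(num) && setequal(num, seq_along(lab))) num else
      seq_along(lab)
  })
  freqs <- lapply(seq_len(nrow(ds$loci)), function(j) {
    fr <- ds$loci$allele_freqs[[j]]
    if (is.null(fr)) stop("allele frequencies required for the LINKAGE ",
                          "datafile; run estimation or recoding first")
    fr[order(out_num[[j]])]   # frequencies in allele-number order
  })

  # datafile
  m <- nrow(ds$loci)
  nloci <- length(aff) + m
  dat <- c(paste(nloci, 0, 0, 5), paste(0, "0.0", "0.0", 0),
           paste(seq_len(nloci), collapse = " "))
  for (t in aff) {
    pm <- penetrance_for(ds, ds$traits$defs$name[t])
    q <- pm$disease_allele_freq
    dat <- c(dat,
             paste("1 2  #", ds$traits$defs$name[t]),
             paste("", fmt_num(1 - q), fmt_num(q)),
             " 1",
             paste("", paste(fmt_num(pm$penetrances), collapse = " ")))
  }
  chr <- marker_chromosomes(ds)
  for (j in seq_len(m)) {
    dat <- c(dat,
             paste0("3 ", length(ds$loci$allele_labels[[j]]), "  # ",
                    ds$loci$name[j], " chr=", chr[j]),
             paste("", paste(fmt_num(freqs[[j]]), collapse = " ")))
  }
  dat <- c(dat, "0 0", "0")
  if (m >= 2L) {
    pos <- ds$map$avg_cM[match(ds$loci$name, ds$map$marker)]
    d <- diff(pos)
    theta <- haldane_theta(pmax(d, 0))
    theta[chr[-1] != chr[-m]] <- 0.5   # unlinked across chromosomes
    dat <- c(dat, paste(fmt_num(theta, digits = 6), collapse = " "))
  }
  dat <- c(dat, "1 0.1 0.45")

  # pedigree
  p <- dataset_pairs(ds)
  tab <- ds$ped
  sex_code <- c(male = "1", female = "2", unknown = "0")[tab$sex]
  cols <- list(tab$ped, tab$id,
               ifelse(is.na(tab$father), "0", tab$father),
               ifelse(is.na(tab$mother), "0", tab$mother))
  if (dialect == "post") {
    ptr <- compute_makeped_pointers(tab)
    na0 <- function(x) ifelse(is.na(x), "0", x)
    cols <- c(cols, list(na0(ptr$first_offspring), na0(ptr$next_paternal_sib),
                         na0(ptr$next_maternal_sib), sex_code,
                         ifelse(ptr$proband, "1", "0")))
  } else {
    cols <- c(cols, list(sex_code))
  }
  for (t in aff) {
    v <- ds$traits$values[[t]]
    cols <- c(cols, list(ifelse(is.na(v), "0", as.character(v))))
  }
  for (j in seq_len(m)) {
    n1 <- out_num[[j]][p$a1[, j]]
    n2 <- out_num[[j]][p$a2[, j]]
    cols <- c(cols, list(ifelse(is.na(n1), "0", as.character(pmin(n1, n2))),
                         ifelse(is.na(n2), "0", as.character(pmax(n1, n2)))))
  }
  ped_lines <- do.call(paste, cols)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped_path <- file.path(dir, paste0(stem, if (dialect == "pre") ".pre" else ".ped"))
  dat_path <- file.path(dir, paste0(stem, ".dat"))
  write_lines_unix(ped_lines, ped_path)
  write_lines_unix(dat, dat_path)
  invisible(c(ped_path, dat_path))
}
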