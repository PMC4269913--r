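# numeric allele codes (recoded datasets) as "a/b" tokens; untyped and
# missing genotypes as "0/0"
numeric_geno_tokens <- function(ds) {
  p <- dataset_pairs(ds)
  tok <- matrix("0/0", nrow(p$a1), ncol(p$a1))
  ok <- !is.na(p$a1)
  tok[ok] <- paste0(p$a1[ok], "/", p$a2[ok])
  tok
}

#' Write a Merlin ped/dat/map file set
#'
#' The dat file declares traits then markers, one per line: `A` for
#' affection, `T` for quantitative, `C` for covariate, `M` for marker.
#' The ped file carries famid, id, father, mother, sex, trait values
#' (`x` missing), then one `a1/a2` token per marker (`0/0` missing).
#' The map carries chromosome, marker, and sex-averaged cM; the
#' sex-specific flag writes female and male positions instead.
#'
#' @param ds a recoded [ped_dataset()].
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.ped/.dat/.map`.
#' @param sex_specific_map emit female/male cM columns?
#' @return character vector of written paths, invisibly.
#' @export
write_merlin <- function(ds, dir, stem = "out", sex_specific_map = FALSE) {
  check_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kind_code <- c(affection = "A", quantitative = "T", covariate = "C")
  dat <- c(paste(kind_code[ds$traits$defs$kind], ds$traits$defs$name),
           paste("M", ds$loci$name))

  cols <- list(ds$ped$ped, ds$ped$id,
               ifelse(is.na(ds$ped$father), "0", ds$ped$father),
               ifelse(is.na(ds$ped$mother), "0", ds$ped$mother),
               plink_sex_code(ds$ped$sex))
  for (t in seq_len(nrow(ds$traits$defs))) {
    v <- ds$traits$values[[t]]
    cols <- c(cols, list(ifelse(is.na(v), "x",
                                if (ds$traits$defs$kind[t] == "affection")
                                  as.character(v) else fmt_num(v))))
  }
  tok <- numeric_geno_tokens(ds)
  for (j in seq_len(nrow(ds$loci))) cols <- c(cols, list(tok[, j]))

  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  map_lines <- if (sex_specific_map) {
    c("CHROMOSOME MARKER FEMALE_POSITION MALE_POSITION",
      paste(mp$chromosome, mp$marker, fmt_num(mp$female_cM), fmt_num(mp$male_cM)))
  } else {
    c("CHROMOSOME MARKER POSITION",
      paste(mp$chromosome, mp$marker, fmt_num(mp$avg_cM)))
  }

  paths <- file.path(dir, paste0(stem, c(".ped", ".dat", ".map")))
  write_lines_unix(do.call(paste, cols), paths[1])
  write_lines_unix(dat, paths[2])
  write_lines_unix(map_lines, paths[3])
  invisible(paths)
}

#' Write a SOLAR file set
#'
#' Emits `pedigree.csv` (famid, id, fa, mo, sex; founders' parent
#' fields empty, SOLAR's own convention), `pheno.csv` (id plus one
#' column per trait, blank missing), a marker file of `a1/a2` tokens
#' (blank missing), an allele-frequency file, and a map file with a
#' chromosome header line.  SOLAR expects one map per chromosome, so a
#' multi-chromosome dataset must be written through the per-chromosome
#' flag of the plan.
#'
#' @param ds a recoded [ped_dataset()] carrying allele frequencies.
#' @param dir output directory.
#' @param stem stem used for the marker/freq/map files.
#' @return character vector of written paths, invisibly.
#' @export
write_solar <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  chr <- unique(marker_chromosomes(ds))
  if (length(chr) > 1L) {
    stop("SOLAR expects one map per chromosome; write with the ",
         "per-chromosome flag (found chromosomes: ",
         paste(chr, collapse = ", "), ")")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sex_code <- c(male = "1", female = "2", unknown = "")[ds$ped$sex]
  ped_lines <- c("famid,id,fa,mo,sex",
                 paste(ds$ped$ped, ds$ped$id,
                       ifelse(is.na(ds$ped$father), "", ds$ped$father),
                       ifelse(is.na(ds$ped$mother), "", ds$ped$mother),
                       sex_code, sep = ","))
  pheno_cols <- lapply(seq_len(nrow(ds$traits$defs)), function(t) {
    v <- ds$traits$values[[t]]
    ifelse(is.na(v), "", if (ds$traits$defs$kind[t] == "affection")
      as.character(v) else fmt_num(v))
  })
  pheno_lines <- c(paste(c("id", ds$traits$defs$name), collapse = ","),
                   do.call(paste, c(list(ds$ped$id), pheno_cols,
                                    list(sep = ","))))
  p <- dataset_pairs(ds)
  mk_cols <- lapply(seq_len(nrow(ds$loci)), function(j) {
    ok <- !is.na(p$a1[, j])
    out <- rep("", nrow(ds$ped))
    out[ok] <- paste0(p$a1[ok, j], "/", p$a2[ok, j])
    out
  })
  marker_lines <- c(paste(c("id", ds$loci$name), collapse = ","),
                    do.call(paste, c(list(ds$ped$id), mk_cols, list(sep = ","))))
  freq_lines <- vapply(seq_len(nrow(ds$loci)), function(j) {
    fr <- ds$loci$allele_freqs[[j]]
    if (is.null(fr)) stop("allele frequencies required for the SOLAR ",
                          "freq file; run estimation or recoding first")
    paste(ds$loci$name[j],
          paste(seq_along(fr), fmt_num(fr), collapse = " "))
  }, character(1))
  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  map_lines <- c(paste("chromosome", if (length(chr)) chr else "0"),
                 paste(mp$marker, fmt_num(mp$avg_cM)))

  paths <- file.path(dir, c("pedigree.csv", "pheno.csv",
                            paste0(stem, c(".marker", ".freq", ".map"))))
  write_lines_unix(ped_lines, paths[1])
  write_lines_unix(pheno_lines, paths[2])
  write_lines_unix(marker_lines, paths[3])
  write_lines_unix(freq_lines, paths[4])
  write_lines_unix(map_lines, paths[5])
  invisible(paths)
}

#' Write an Eigenstrat geno/snp/ind file set
#'
#' geno: one line per SNP, one digit per individual counting copies of
#' allele 1 (0/1/2), 9 missing (untyped individuals included as 9);
#' snp: name, chromosome, genetic position in Morgans, bp; ind: the
#' individual key, sex letter M/F/U, and the pedigree id as the group
#' label.
#'
#' @param ds a biallelic [ped_dataset()].
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.geno/.snp/.ind`.
#' @return character vector of written paths, invisibly.
#' @export
write_eigenstrat <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  n_all <- vapply(ds$loci$allele_labels, length, integer(1))
  if (any(n_all > 2L)) {
    stop("Eigenstrat output requires biallelic markers; offending: ",
         paste(ds$loci$name[n_all > 2L], collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- dataset_pairs(ds)
  digits <- matrix(9L, nrow(ds$ped), nrow(ds$loci))
  ok <- !is.na(p$a1)
  digits[ok] <- (p$a1[ok] == 1L) + (p$a2[ok] == 1L)
  geno_lines <- apply(digits, 2L, paste, collapse = "")
  if (nrow(ds$loci) == 0L) geno_lines <- character(0)
  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  snp_lines <- paste(mp$marker, mp$chromosome, fmt_num(mp$avg_cM / 100), mp$bp)
  sex_letter <- c(male = "M", female = "F", unknown = "U")[ds$ped$sex]
  ind_lines <- paste(ped_key(ds$ped), sex_letter, ds$ped$ped)

  paths <- file.path(dir, paste0(stem, c(".geno", ".snp", ".ind")))
  write_lines_unix(geno_lines, paths[1])
  write_lines_unix(snp_lines, paths[2])
  write_lines_unix(ind_lines, paths[3])
  invisible(paths)
}

#' Write a Structure input matrix
#'
#' Optional header row of marker names, then one row per individual:
#' individual id, pedigree label, and two adjacent integer allele
#' columns per marker (sorted ascending within a genotype), -9 missing.
#'
#' @param ds a recoded [ped_dataset()].
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.structure`.
#' @param header write the marker-name header row?
#' @return the written path, invisibly.
#' @export
write_structure <- function(ds, dir, stem = "out", header = TRUE) {
  check_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- dataset_pairs(ds)
  cols <- list(ds$ped$id, ds$ped$ped)
  for (j in seq_len(nrow(ds$loci))) {
    cols <- c(cols, list(ifelse(is.na(p$a1[, j]), "-9", as.character(p$a1[, j])),
                         ifelse(is.na(p$a2[, j]), "-9", as.character(p$a2[, j]))))
  }
  lines <- do.call(paste, cols)
  if (header) lines <- c(paste(ds$loci$name, collapse = " "), lines)
  path <- file.path(dir, paste0(stem, ".structure"))
  write_lines_unix(lines, path)
  invisible(path)
}

#' Write an FBAT pedigree file
#'
#' Line 1 lists the marker names; each following line carries famid,
#' id, father, mother, sex, the first affection trait
#' (2/1, unknown 0), then two allele columns per marker (0 missing).
#'
#' @param ds a recoded [ped_dataset()] with at least one affection
#'   trait.
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.ped`.
#' @return the written path, invisibly.
#' @export
write_fbat <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  aff <- which(ds$traits$defs$kind == "affection")
  if (length(aff) == 0L) {
    stop("FBAT output requires at least one affection trait")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- ds$traits$values[[aff[1]]]
  p <- dataset_pairs(ds)
  cols <- list(ds$ped$ped, ds$ped$id,
               ifelse(is.na(ds$ped$father), "0", ds$ped$father),
               ifelse(is.na(ds$ped$mother), "0", ds$ped$mother),
               plink_sex_code(ds$ped$sex),
               ifelse(is.na(v), "0", as.character(v)))
  for (j in seq_len(nrow(ds$loci))) {
    cols <- c(cols, list(ifelse(is.na(p$a1[, j]), "0", as.character(p$a1[, j])),
                         ifelse(is.na(p$a2[, j]), "0", as.character(p$a2[, j]))))
  }
  path <- file.path(dir, paste0(stem, ".ped"))
  write_lines_unix(c(paste(ds$loci$name, collapse = " "),
                     do.call(paste, cols)), path)
  invisible(path)
}

write_targets <- c("linkage_pre", "linkage_post", "plink_text", "plink_binary",
                   "merlin", "solar", "eigenstrat", "structure", "fbat",
                   "annotated")

#' Write a dataset in any supported target format
#'
#' Dispatches on `target`; with `per_chromosome = TRUE` the dataset is
#' split by chromosome first and each piece is written with a
#' `_chr<label>` stem suffix.
#'
#' @param ds a [ped_dataset()] (recoded where the target requires it).
#' @param target one of `linkage_pre`, `linkage_post`, `plink_text`,
#'   `plink_binary`, `merlin`, `solar`, `eigenstrat`, `structure`,
#'   `fbat`, `annotated`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @param per_chromosome split the output by chromosome?
#' @param options named list of target-specific options
#'   (`sex_specific_map` for merlin, `header` for structure).
#' @return character vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, target, dir, stem = "out",
                          per_chromosome = FALSE, options = list()) {
  target <- match.arg(target, write_targets)
  if (per_chromosome) {
    pieces <- split_by_chromosome(ds)
    paths <- character()
    for (chr in names(pieces)) {
      paths <- c(paths, write_dataset(pieces[[chr]], target, dir,
                                      stem = paste0(stem, "_chr", chr),
                                      per_chromosome = FALSE, options = options))
    }
    return(invisible(paths))
  }
  paths <- switch(target,
    linkage_pre = write_linkage(ds, dir, stem, dialect = "pre"),
    linkage_post = write_linkage(ds, dir, stem, dialect = "post"),
    plink_text = write_plink_text(ds, dir, stem),
    plink_binary = write_plink_binary(ds, dir, stem),
    merlin = do.call(write_merlin, c(list(ds, dir, stem), options)),
    solar = write_solar(ds, dir, stem),
    eigenstrat = write_eigenstrat(ds, dir, stem),
    structure = do.call(write_structure, c(list(ds, dir, stem), options)),
    fbat = write_fbat(ds, dir, stem),
    annotated = write_annotated(ds, dir, stem))
  invisible(paths)
}
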