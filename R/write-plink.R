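plink_sex_code <- function(sex) c(male = "1", female = "2", unknown = "0")[sex]

# 6th-column phenotype: first affection trait (1/2, missing -9), else -9
plink_pheno_col <- function(ds) {
  aff <- which(ds$traits$defs$kind == "affection")
  if (length(aff) == 0L) return(rep("-9", nrow(ds$ped)))
  v <- ds$traits$values[[aff[1]]]
  ifelse(is.na(v), "-9", as.character(v))
}

plink_fam_lines <- function(ds) {
  paste(ds$ped$ped, ds$ped$id,
        ifelse(is.na(ds$ped$father), "0", ds$ped$father),
        ifelse(is.na(ds$ped$mother), "0", ds$ped$mother),
        plink_sex_code(ds$ped$sex), plink_pheno_col(ds))
}

plink_map_lines <- function(ds) {
  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  paste(mp$chromosome, mp$marker, fmt_num(mp$avg_cM), mp$bp)
}

#' Write a PLINK text ped/map pair
#'
#' Column 6 carries the first affection trait (1/2, unknown as -9) or
#' -9 when the dataset has none; missing genotypes are written `0 0`.
#'
#' @param ds a [ped_dataset()].
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.ped` and `<stem>.map`.
#' @return character vector of written paths, invisibly.
#' @export
write_plink_text <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- dataset_label_pairs(ds)
  cols <- list(plink_fam_lines(ds))
  for (j in seq_len(nrow(ds$loci))) {
    cols <- c(cols, list(ifelse(is.na(lp$l1[, j]), "0", lp$l1[, j]),
                         ifelse(is.na(lp$l2[, j]), "0", lp$l2[, j])))
  }
  ped_path <- file.path(dir, paste0(stem, ".ped"))
  map_path <- file.path(dir, paste0(stem, ".map"))
  write_lines_unix(do.call(paste, cols), ped_path)
  write_lines_unix(plink_map_lines(ds), map_path)
  invisible(c(ped_path, map_path))
}

#' Write a PLINK binary bed/bim/fam triple
#'
#' The bed file is bit-exact SNP-major: magic `0x6c 0x1b`, mode byte
#' `0x01`, then `ceiling(N/4)` bytes per marker with the first sample
#' in the two least-significant bits and codes 00/01/10/11 = homozygous
#' allele-1 / missing / heterozygous / homozygous allele-2 in bim
#' allele order.  Bim column 5 carries the internal code-2
#' (minor-by-recode) allele and column 6 the major allele — a
#' deterministic, documented choice; downstream tools decode either
#' order correctly from the bim.  A marker without a second allele gets
#' the conventional `0` placeholder.
#'
#' @param ds a [ped_dataset()]; all loci must be biallelic.
#' @param dir output directory.
#' @param stem file-name stem; writes `<stem>.bed/.bim/.fam`.
#' @return character vector of written paths, invisibly.
#' @export
write_plink_binary <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  n_all <- vapply(ds$loci$allele_labels, length, integer(1))
  if (any(n_all > 2L)) {
    stop("multiallelic marker(s): ", paste(ds$loci$name[n_all > 2L], collapse = ", "),
         "; subset loci or export through a general-mode text format")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(ds$ped)
  m <- nrow(ds$loci)
  # internal codes (all individuals; untyped -> 0) -> bed codes
  p <- dataset_pairs(ds)
  codes <- matrix(0L, n, max(m, 0L))
  if (n > 0L && m > 0L) {
    ok <- !is.na(p$a1)
    codes[ok] <- ifelse(p$a1[ok] == 1L, ifelse(p$a2[ok] == 1L, 1L, 2L), 3L)
  }
  bed_lut <- c(1L, 3L, 2L, 0L)   # internal 0,1,2,3 -> bed 01,11,10,00
  bed_codes <- matrix(bed_lut[codes + 1L], n, max(m, 0L))
  packed <- pack_codes_matrix(bed_codes)

  bed_path <- file.path(dir, paste0(stem, ".bed"))
  con <- file(bed_path, open = "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (length(packed)) writeBin(as.vector(packed), con)
  close(con)

  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  minor <- vapply(ds$loci$allele_labels, function(lab)
    if (length(lab) >= 2L) lab[2] else "0", character(1))
  major <- vapply(ds$loci$allele_labels, function(lab)
    if (length(lab) >= 1L) lab[1] else "0", character(1))
  bim_path <- file.path(dir, paste0(stem, ".bim"))
  write_lines_unix(paste(mp$chromosome, mp$marker, fmt_num(mp$avg_cM), mp$bp,
                         minor, major), bim_path)
  fam_path <- file.path(dir, paste0(stem, ".fam"))
  write_lines_unix(plink_fam_lines(ds), fam_path)
  invisible(c(bed_path, bim_path, fam_path))
}
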