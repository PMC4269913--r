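# PLINK input: text ped/map pairs and bed/bim/fam binary triples, with
# optional alternate phenotype files.

plink_decode_sex <- function(x) x  # file codes 1/2/0 handled by ped_table

# Infer the trait kind of a 6th-column phenotype: all values in
# {0, 1, 2, -9} means an affection trait (0 and -9 both missing, both
# conventions circulate); anything else is quantitative (-9 missing).
plink_decode_pheno <- function(v) {
  vn <- suppressWarnings(as.numeric(v))
  if (all(is.na(vn) | vn %in% c(0, 1, 2, -9))) {
    vi <- as.integer(vn)
    vi[!vi %in% 1:2] <- NA_integer_
    list(kind = "affection", values = vi, missing_code = "-9")
  } else {
    vn[!is.na(vn) & vn == -9] <- NA_real_
    list(kind = "quantitative", values = vn, missing_code = "-9")
  }
}

read_plink_map <- function(map_path) {
  tok <- tokenize_lines(read_clean_lines(map_path))
  bad <- which(!vapply(tok, length, integer(1)) %in% c(3L, 4L))
  if (length(bad)) {
    stop("plink map file: expected 'chr marker [cM] bp' on line ", bad[1])
  }
  tok <- lapply(tok, function(t) if (length(t) == 3L) c(t[1:2], "0", t[3]) else t)
  tok <- do.call(rbind, tok)
  new_map(chromosome = tok[, 1], marker = tok[, 2],
          avg_cM = as.numeric(tok[, 3]), bp = as.integer(tok[, 4]))
}

# apply an alternate phenotype file (header "FID IID <names>" optional)
apply_pheno_file <- function(ds, pheno_path) {
  lines <- read_clean_lines(pheno_path)
  tok <- tokenize_lines(lines)
  has_header <- toupper(tok[[1]][1]) %in% c("FID", "FAMID")
  pnames <- if (has_header) tok[[1]][-(1:2)] else
    paste0("PHENO", seq_len(length(tok[[1]]) - 2L))
  rows <- if (has_header) tok[-1] else tok
  bad <- which(vapply(rows, length, integer(1)) != 2L + length(pnames))
  if (length(bad)) stop("phenotype file: wrong column count on line ", bad[1])
  rows <- do.call(rbind, rows)
  keys <- ped_key(ds$ped)
  rkeys <- ped_key(rows[, 1], rows[, 2])
  unknown <- !(rkeys %in% keys)
  warns <- no_findings()
  if (any(unknown)) {
    warns <- bind_findings(warns, finding(
      "warning", "structure",
      message = paste0("phenotype file ids not present in pedigree: ",
                       paste(unique(rkeys[unknown]), collapse = ", "))))
  }
  tvals <- as.data.frame(matrix(nrow = nrow(ds$ped), ncol = 0))
  defs <- data.frame(name = character(), kind = character(),
                     missing_code = character(), stringsAsFactors = FALSE)
  idx <- match(keys, rkeys)
  for (k in seq_along(pnames)) {
    col <- rows[idx, 2L + k]
    dec <- plink_decode_pheno(col)
    tvals[[pnames[k]]] <- dec$values
    defs[nrow(defs) + 1L, ] <- list(pnames[k], dec$kind, dec$missing_code)
  }
  ds$traits <- list(defs = defs, values = tvals)
  attr(ds, "findings") <- bind_findings(attr(ds, "findings"), warns)
  ds
}

#' Read a PLINK text ped/map pair
#'
#' The ped file carries family id, individual id, father, mother, sex,
#' one phenotype column, then two allele columns per map marker.  The
#' phenotype kind is inferred from its values (see Details); an
#' alternate phenotype file, when given, replaces it.
#'
#' @details Column 6 values all within \{0, 1, 2, -9\} are read as an
#'   affection trait (0 and -9 missing); any other value makes the
#'   trait quantitative (-9 missing).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param pheno_path optional alternate phenotype file, joined on
#'   (family id, individual id); header `FID IID name...` optional.
#' @param mode genotype storage mode passed to [geno_matrix()].
#' @return a [ped_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, pheno_path = NULL,
                            mode = "auto") {
  map <- read_plink_map(map_path)
  m <- nrow(map)
  lines <- read_clean_lines(ped_path)
  if (length(lines) == 0L) stop("no individuals in ped file ", ped_path)
  tok <- tokenize_lines(lines)
  want <- 6L + 2L * m
  bad <- which(vapply(tok, length, integer(1)) != want)
  if (length(bad)) {
    stop("ped file line ", bad[1], ": ", length(tok[[bad[1]]]),
         " columns, expected ", want, " (6 + 2 x ", m, " map markers)")
  }
  tok <- do.call(rbind, tok)
  tab <- ped_table(tok[, 1], tok[, 2], tok[, 3], tok[, 4], tok[, 5])
  dec <- plink_decode_pheno(tok[, 6])
  traits <- list(defs = data.frame(name = "pheno", kind = dec$kind,
                                   missing_code = dec$missing_code,
                                   stringsAsFactors = FALSE),
                 values = stats::setNames(data.frame(dec$values), "pheno"))

  a1 <- matrix(NA_integer_, nrow(tab), m)
  a2 <- a1
  labels <- vector("list", m)
  for (j in seq_len(m)) {
    g1 <- tok[, 5L + 2L * j]
    g2 <- tok[, 6L + 2L * j]
    g1[g1 == "0"] <- NA_character_
    g2[g2 == "0"] <- NA_character_
    idx <- index_alleles(g1, g2)
    labels[[j]] <- idx$labels
    a1[, j] <- idx$a1
    a2[, j] <- idx$a2
  }
  gm <- geno_matrix(a1, a2, ped_key(tab), mode = mode)
  loci <- new_loci(map$marker, map$chromosome, labels)
  ds <- ped_dataset(tab, loci, map, gm, traits)
  if (!is.null(pheno_path)) ds <- apply_pheno_file(ds, pheno_path)
  add_provenance(ds, sprintf(
    "read plink text: %d individuals (%d typed), %d markers",
    nrow(tab), n_typed(gm), m))
}

read_fam_file <- function(fam_path) {
  tok <- tokenize_lines(read_clean_lines(fam_path))
  bad <- which(vapply(tok, length, integer(1)) != 6L)
  if (length(bad)) stop("fam file: expected 6 columns on line ", bad[1])
  do.call(rbind, tok)
}

read_bim_file <- function(bim_path) {
  tok <- tokenize_lines(read_clean_lines(bim_path))
  bad <- which(vapply(tok, length, integer(1)) != 6L)
  if (length(bad)) stop("bim file: expected 6 columns on line ", bad[1])
  do.call(rbind, tok)
}

#' Read a PLINK binary bed/bim/fam triple
#'
#' Bit-exact reader for the SNP-major binary genotype dialect: magic
#' bytes `0x6c 0x1b`, mode byte `0x01`, then one row of
#' `ceiling(N/4)` bytes per bim marker, first sample in the two
#' least-significant bits, with codes 00 = homozygous bim-allele-1,
#' 01 = missing, 10 = heterozygous, 11 = homozygous bim-allele-2.
#' Internally allele 1 is taken from bim column 6 (the major allele by
#' this package's writer convention) and allele 2 from column 5.
#'
#' @param bed_path,bim_path,fam_path paths to the three files.
#' @param pheno_path optional alternate phenotype file.
#' @param mode genotype storage mode.
#' @return a [ped_dataset()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path, pheno_path = NULL,
                              mode = "auto") {
  fam <- if (file.size(fam_path) > 0) read_fam_file(fam_path) else
    matrix(character(), ncol = 6)
  bim <- if (file.size(bim_path) > 0) read_bim_file(bim_path) else
    matrix(character(), ncol = 6)
  n <- nrow(fam)
  m <- nrow(bim)
  bytes <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(bytes) < 3L || bytes[1] != as.raw(0x6c) || bytes[2] != as.raw(0x1b)) {
    stop(bed_path, " is not a binary genotype file (bad magic bytes)")
  }
  if (bytes[3] == as.raw(0x00)) {
    stop("individual-major binary files are an unsupported dialect; ",
         "re-export in SNP-major mode")
  }
  if (bytes[3] != as.raw(0x01)) stop("unknown bed mode byte: ", bytes[3])
  row_bytes <- ceiling(n / 4)
  if (length(bytes) != 3L + row_bytes * m) {
    stop(bed_path, " is truncated: ", length(bytes), " bytes, expected ",
         3L + row_bytes * m)
  }
  tab <- ped_table(fam[, 1], fam[, 2], fam[, 3], fam[, 4], fam[, 5])
  dec <- plink_decode_pheno(fam[, 6])
  traits <- list(defs = data.frame(name = "pheno", kind = dec$kind,
                                   missing_code = dec$missing_code,
                                   stringsAsFactors = FALSE),
                 values = stats::setNames(data.frame(
                   if (n == 0L) numeric(0) else dec$values), "pheno"))

  a1 <- matrix(NA_integer_, n, m)
  a2 <- a1
  labels <- vector("list", m)
  if (m > 0L && n > 0L) {
    packed <- matrix(bytes[-(1:3)], nrow = row_bytes, ncol = m)
    bedcodes <- unpack_codes_matrix(packed, n)
    for (j in seq_len(m)) {
      labels[[j]] <- unique(c(bim[j, 6], bim[j, 5]))
      lut1 <- c(2L, NA_integer_, 1L, 1L)   # bed 00,01,10,11 -> internal a1
      lut2 <- c(2L, NA_integer_, 2L, 1L)
      a1[, j] <- lut1[bedcodes[, j] + 1L]
      a2[, j] <- lut2[bedcodes[, j] + 1L]
      # swap so a1 <= a2 handled by geno_matrix; indices refer to labels
    }
  } else {
    labels <- rep(list(character(0)), m)
  }
  gm <- geno_matrix(a1, a2, ped_key(tab), mode = mode)
  loci <- new_loci(if (m > 0L) bim[, 2] else character(),
                   if (m > 0L) bim[, 1] else character(), labels)
  map <- if (m > 0L) {
    new_map(chromosome = bim[, 1], marker = bim[, 2],
            avg_cM = as.numeric(bim[, 3]), bp = as.integer(bim[, 4]))
  } else new_map(character(), character(), numeric(), integer())
  ds <- ped_dataset(tab, loci, map, gm, traits)
  if (!is.null(pheno_path)) ds <- apply_pheno_file(ds, pheno_path)
  add_provenance(ds, sprintf(
    "read plink binary: %d individuals (%d typed), %d markers",
    n, n_typed(gm), m))
}
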