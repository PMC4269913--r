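#' Read a VCF file into a dataset
#'
#' Parses GT genotypes (via the vcfR parser) into one locus per
#' biallelic record, REF as allele 1 and ALT as allele 2.  Phase
#' separators (`|`) are accepted and phase is discarded; `./.` and `.`
#' are missing; a half-called genotype is demoted to missing by the
#' storage layer.  Samples become one singleton pedigree each (family
#' id equal to sample id, sex unknown) unless a fam-format sidecar file
#' supplies pedigree structure.  Multi-allelic records are dropped
#' (default) or kept with general-mode storage, per `multiallelic`;
#' splitting them into biallelic records is out of scope.  Records
#' whose FORMAT lacks GT are skipped and counted.
#'
#' @param vcf_path path to a VCF (v4.x) file, plain or bgzipped.
#' @param fam_path optional 6-column fam-format sidecar supplying
#'   pedigree structure, sex, and phenotype for the samples.
#' @param multiallelic `"drop"` (default) or `"keep"` (general mode).
#' @param mode genotype storage mode (forced to `"general"` when
#'   multi-allelic records are kept).
#' @return a [ped_dataset()]; map positions come from CHROM/POS with
#'   cM = 0; parse problems are attached as a `"findings"` attribute.
#' @export
read_vcf <- function(vcf_path, fam_path = NULL,
                     multiallelic = c("drop", "keep"), mode = "auto") {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  n_rec <- nrow(fix)
  samples <- if (ncol(gt) > 1L) colnames(gt)[-1L] else character(0)
  warns <- list()

  if (!is.null(fam_path)) {
    fam <- read_fam_file(fam_path)
    missing_s <- setdiff(samples, fam[, 2])
    if (length(missing_s)) {
      stop("sidecar fam file lacks samples: ", paste(missing_s, collapse = ", "))
    }
    fam <- fam[match(samples, fam[, 2]), , drop = FALSE]
    tab <- ped_table(fam[, 1], fam[, 2], fam[, 3], fam[, 4], fam[, 5])
    dec <- plink_decode_pheno(fam[, 6])
    traits <- list(defs = data.frame(name = "pheno", kind = dec$kind,
                                     missing_code = dec$missing_code,
                                     stringsAsFactors = FALSE),
                   values = stats::setNames(data.frame(dec$values), "pheno"))
  } else {
    tab <- ped_table(samples, samples, rep(NA_character_, length(samples)),
                     rep(NA_character_, length(samples)),
                     rep("unknown", length(samples)))
    traits <- empty_traits(length(samples))
  }

  has_gt <- if (n_rec > 0L) {
    vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
           function(f) "GT" %in% f, logical(1))
  } else logical(0)
  n_no_gt <- sum(!has_gt)
  if (n_no_gt > 0L) {
    warns[[length(warns) + 1L]] <- finding(
      "warning", "structure",
      message = sprintf("%d record(s) without GT skipped", n_no_gt))
  }
  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                        ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  multi <- n_alt > 1L
  keep <- has_gt & (!multi | multiallelic == "keep")
  n_multi_dropped <- sum(has_gt & multi & multiallelic == "drop")
  if (n_multi_dropped > 0L) {
    warns[[length(warns) + 1L]] <- finding(
      "warning", "structure",
      message = sprintf("%d multi-allelic record(s) dropped", n_multi_dropped))
  }
  idx <- which(keep)
  m <- length(idx)
  n <- length(samples)
  a1 <- matrix(NA_integer_, n, m)
  a2 <- a1
  labels <- vector("list", m)
  for (jj in seq_len(m)) {
    r <- idx[jj]
    labels[[jj]] <- unname(c(fix[r, "REF"], alt_split[[r]]))
    tokens <- gt[r, -1L]
    gt_field <- vapply(strsplit(tokens, ":", fixed = TRUE), function(x)
      if (length(x)) x[1] else ".", character(1))
    gt_field[is.na(tokens)] <- "."
    parts <- strsplit(gt_field, "[/|]")
    bad <- !vapply(parts, function(p)
      length(p) %in% 1:2 && all(p == "." | grepl("^[0-9]+$", p)), logical(1))
    if (any(bad)) {
      warns[[length(warns) + 1L]] <- finding(
        "error", "structure", marker = marker_name_vcf(fix, r),
        message = sprintf("malformed GT token '%s' in %d sample(s); set missing",
                          gt_field[which(bad)[1]], sum(bad)))
      parts[bad] <- list(".")
    }
    al <- t(vapply(parts, function(p) {
      p <- c(p, p)[1:2]               # haploid calls doubled
      suppressWarnings(as.integer(ifelse(p == ".", NA, p))) + 1L
    }, integer(2)))
    over <- !is.na(al) & al > length(labels[[jj]])
    if (any(over)) {
      warns[[length(warns) + 1L]] <- finding(
        "error", "structure", marker = marker_name_vcf(fix, r),
        message = "GT allele index beyond ALT list; set missing")
      al[cbind(which(rowSums(over) > 0L), 1L)] <- NA_integer_
      al[cbind(which(rowSums(over) > 0L), 2L)] <- NA_integer_
    }
    a1[, jj] <- al[, 1L]
    a2[, jj] <- al[, 2L]
  }
  if (m > 0L && multiallelic == "keep" && any(n_alt[idx] > 1L)) mode <- "general"
  gm <- geno_matrix(a1, a2, ped_key(tab), mode = mode)
  mnames <- vapply(idx, function(r) marker_name_vcf(fix, r), character(1))
  loci <- new_loci(mnames, if (m > 0L) fix[idx, "CHROM"] else character(), labels)
  map <- if (m > 0L) {
    new_map(chromosome = fix[idx, "CHROM"], marker = mnames,
            avg_cM = rep(0, m), bp = as.integer(fix[idx, "POS"]))
  } else new_map(character(), character(), numeric(), integer())
  ds <- ped_dataset(tab, loci, map, gm, traits)
  attr(ds, "findings") <- do.call(bind_findings, c(warns, list(no_findings())))
  add_provenance(ds, sprintf(
    "read vcf: %d samples (%d typed), %d of %d records kept (%d without GT, %d multi-allelic dropped)",
    n, n_typed(gm), m, n_rec, n_no_gt, n_multi_dropped))
}

marker_name_vcf <- function(fix, r) {
  id <- fix[r, "ID"]
  if (is.na(id) || id == ".") paste0(fix[r, "CHROM"], ":", fix[r, "POS"]) else id
}
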