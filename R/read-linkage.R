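# LINKAGE-format input: a pre-makeped pedigree file plus a locus
# ("data") file.  The datafile parsed here is the classic layout
# (locus count / mutation line / locus order / per-locus blocks /
# recombination fractions); locus names and chromosome labels, which
# the classic format cannot carry, are recovered from "# name chr=c"
# trailing comments when present (this package's writer emits them)
# and default to M1..Mm otherwise.

parse_linkage_datafile <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  comment_of <- function(ln) {
    hash <- regexpr("#", ln, fixed = TRUE)
    if (hash > 0) trimws(substring(ln, hash + 1)) else ""
  }
  code_of <- function(ln) {
    hash <- regexpr("#", ln, fixed = TRUE)
    if (hash > 0) substring(ln, 1, hash - 1) else ln
  }
  i <- 0L
  next_tokens <- function() {
    i <<- i + 1L
    if (i > length(raw)) stop("linkage datafile ", path, ": truncated")
    list(tok = split_ws(code_of(raw[i])), comment = comment_of(raw[i]))
  }
  hdr <- next_tokens()$tok
  if (length(hdr) < 1L) stop("linkage datafile: bad header")
  nloci <- as.integer(hdr[1])
  next_tokens()                      # mutation line, ignored
  ord <- as.integer(next_tokens()$tok)
  if (length(ord) != nloci) {
    stop("linkage datafile: locus order line has ", length(ord),
         " entries, expected ", nloci)
  }
  traits <- list()
  markers <- list()
  for (l in seq_len(nloci)) {
    head <- next_tokens()
    type <- as.integer(head$tok[1])
    nall <- as.integer(head$tok[2])
    cmt <- split_ws(head$comment)
    nm <- if (length(cmt) >= 1L) cmt[1] else NA_character_
    chr <- if (length(cmt) >= 2L && grepl("^chr=", cmt[2])) {
      sub("^chr=", "", cmt[2])
    } else NA_character_
    freqs <- as.numeric(next_tokens()$tok)
    if (length(freqs) != nall) {
      stop("linkage datafile: locus ", l, " expects ", nall, " frequencies")
    }
    if (type == 1L) {
      nliab <- as.integer(next_tokens()$tok[1])
      pen <- as.numeric(next_tokens()$tok)
      if (nliab != 1L || length(pen) != 3L) {
        stop("linkage datafile: only single-liability affection loci supported")
      }
      traits[[length(traits) + 1L]] <- list(
        name = if (is.na(nm)) paste0("TRAIT", length(traits) + 1L) else nm,
        disease_allele_freq = freqs[2], penetrances = pen)
    } else if (type == 3L) {
      markers[[length(markers) + 1L]] <- list(
        name = if (is.na(nm)) paste0("M", length(markers) + 1L) else nm,
        chromosome = if (is.na(chr)) "0" else chr,
        n_alleles = nall, freqs = freqs)
    } else {
      stop("linkage datafile: unsupported locus type ", type,
           " (affection [1] and numbered-allele [3] loci are supported)")
    }
  }
  next_tokens()                      # sex-difference line
  next_tokens()                      # interference line
  thetas <- numeric(0)
  if (length(markers) >= 2L) thetas <- as.numeric(next_tokens()$tok)
  list(traits = traits, markers = markers, thetas = thetas)
}

#' Read a LINKAGE-format pedigree + locus file pair
#'
#' The pedigree file is whitespace-delimited pre-makeped layout:
#' pedigree, individual, father, mother, sex, one column per affection
#' trait declared in the datafile, then two allele columns per marker.
#' Sex codes 1/2/0 and affection codes 1 = unaffected / 2 = affected /
#' 0 = unknown are decoded; allele code 0 means missing.
#'
#' @param pedigree_path path to the pedigree file.
#' @param datafile_path path to the locus (data) file.
#' @param mode genotype storage mode passed to [geno_matrix()].
#' @return a [ped_dataset()].
#' @export
read_linkage <- function(pedigree_path, datafile_path, mode = "auto") {
  df <- parse_linkage_datafile(datafile_path)
  m <- length(df$markers)
  n_tr <- length(df$traits)
  lines <- read_clean_lines(pedigree_path)
  if (length(lines) == 0L) stop("no individuals in pedigree file ", pedigree_path)
  tok <- tokenize_lines(lines)
  want <- 5L + n_tr + 2L * m
  bad <- which(vapply(tok, length, integer(1)) != want)
  if (length(bad)) {
    stop("pedigree file line ", bad[1], ": ", length(tok[[bad[1]]]),
         " columns, expected ", want, " for ", n_tr, " trait(s) and ",
         m, " marker(s) declared in the datafile")
  }
  tok <- do.call(rbind, tok)
  tab <- ped_table(tok[, 1], tok[, 2], tok[, 3], tok[, 4], tok[, 5])

  tvals <- as.data.frame(matrix(nrow = nrow(tab), ncol = 0))
  for (t in seq_len(n_tr)) {
    v <- as.integer(tok[, 5L + t])
    v[!v %in% 1:2] <- NA_integer_
    tvals[[df$traits[[t]]$name]] <- v
  }
  traits <- list(defs = data.frame(
    name = vapply(df$traits, `[[`, character(1), "name"),
    kind = rep("affection", n_tr), missing_code = rep("0", n_tr),
    stringsAsFactors = FALSE), values = tvals)

  a1 <- matrix(NA_integer_, nrow(tab), m)
  a2 <- a1
  for (j in seq_len(m)) {
    c1 <- as.integer(tok[, 5L + n_tr + 2L * j - 1L])
    c2 <- as.integer(tok[, 5L + n_tr + 2L * j])
    c1[c1 == 0L] <- NA_integer_
    c2[c2 == 0L] <- NA_integer_
    a1[, j] <- c1
    a2[, j] <- c2
  }
  gm <- geno_matrix(a1, a2, ped_key(tab), mode = mode)

  loci <- new_loci(
    name = vapply(df$markers, `[[`, character(1), "name"),
    chromosome = vapply(df$markers, `[[`, character(1), "chromosome"),
    allele_labels = lapply(df$markers, function(x) as.character(seq_len(x$n_alleles))),
    allele_freqs = lapply(df$markers, `[[`, "freqs"))

  # genetic map from adjacent recombination fractions (inverse Haldane);
  # physical positions are not representable in LINKAGE files, so bp is
  # the marker index
  cm <- c(0, cumsum(haldane_cM(pmin(df$thetas, 0.4999))))
  if (m > 0L && length(cm) != m) cm <- rep(0, m)
  map <- if (m > 0L) {
    new_map(chromosome = loci$chromosome, marker = loci$name,
            avg_cM = cm, bp = seq_len(m))
  } else new_map(character(), character(), numeric(), integer())

  ds <- ped_dataset(tab, loci, map, gm, traits)
  ds$penetrance <- lapply(df$traits, function(t)
    list(trait_name = t$name, disease_allele_freq = t$disease_allele_freq,
         penetrances = t$penetrances))
  add_provenance(ds, sprintf(
    "read linkage: %d individuals (%d typed), %d markers, %d affection trait(s)",
    nrow(tab), n_typed(gm), m, n_tr))
}
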