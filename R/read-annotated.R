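# Annotated-format input: a header-bearing pedigree file, a locus
# names file, and a genetic map file, optionally joined by omit,
# allele-frequency, and penetrance files.  The exact column layout is
# this package's documented dialect:
#   pedigree: header "Ped Id Father Mother Sex <traits...> <markers...>",
#             genotypes as "a/b" tokens ("0/0" missing, labels arbitrary)
#   names:    rows "<name> <kind>", kind in
#             marker|affection|quantitative|covariate
#   map:      header "chromosome marker [female_cM male_cM] avg_cM bp"
#   freq:     rows "<marker> <allele> <frequency>"
#   penetrance: rows "<trait> <disease_allele_freq> <f0> <f1> <f2>"

read_names_file <- function(path) {
  tok <- tokenize_lines(read_clean_lines(path))
  bad <- which(vapply(tok, length, integer(1)) != 2L)
  if (length(bad)) stop("names file: expected 'name kind' on line ", bad[1])
  tok <- do.call(rbind, tok)
  kinds <- c("marker", "affection", "quantitative", "covariate")
  if (!all(tok[, 2] %in% kinds)) {
    stop("names file: unknown kind(s): ",
         paste(setdiff(tok[, 2], kinds), collapse = ", "))
  }
  data.frame(name = tok[, 1], kind = tok[, 2], stringsAsFactors = FALSE)
}

read_map_file <- function(path) {
  lines <- read_clean_lines(path)
  hdr <- split_ws(lines[1])
  tok <- tokenize_lines(lines[-1])
  ncol <- length(hdr)
  if (!ncol %in% c(4L, 6L)) {
    stop("map file: expected 4 columns (chromosome marker avg_cM bp) or 6 ",
         "(with female_cM male_cM)")
  }
  bad <- which(vapply(tok, length, integer(1)) != ncol)
  if (length(bad)) stop("map file: wrong column count on line ", bad[1] + 1L)
  tok <- do.call(rbind, tok)
  if (ncol == 4L) {
    new_map(chromosome = tok[, 1], marker = tok[, 2],
            avg_cM = as.numeric(tok[, 3]), bp = as.integer(tok[, 4]))
  } else {
    new_map(chromosome = tok[, 1], marker = tok[, 2],
            female_cM = as.numeric(tok[, 3]), male_cM = as.numeric(tok[, 4]),
            avg_cM = as.numeric(tok[, 5]), bp = as.integer(tok[, 6]))
  }
}

read_freq_file <- function(path) {
  tok <- tokenize_lines(read_clean_lines(path))
  bad <- which(vapply(tok, length, integer(1)) != 3L)
  if (length(bad)) stop("frequency file: expected 'marker allele freq' on line ",
                        bad[1])
  tok <- do.call(rbind, tok)
  data.frame(marker = tok[, 1], allele = tok[, 2],
             freq = as.numeric(tok[, 3]), stringsAsFactors = FALSE)
}

read_penetrance_file <- function(path) {
  tok <- tokenize_lines(read_clean_lines(path))
  bad <- which(vapply(tok, length, integer(1)) != 5L)
  if (length(bad)) stop("penetrance file: expected ",
                        "'trait q f0 f1 f2' on line ", bad[1])
  lapply(tok, function(t) {
    pm <- list(trait_name = t[1], disease_allele_freq = as.numeric(t[2]),
               penetrances = as.numeric(t[3:5]))
    if (any(pm$penetrances < 0 | pm$penetrances > 1)) {
      stop("penetrance file: penetrances for ", t[1], " must lie in [0, 1]")
    }
    if (pm$disease_allele_freq <= 0 || pm$disease_allele_freq >= 1) {
      stop("penetrance file: disease allele frequency for ", t[1],
           " must lie in (0, 1)")
    }
    pm
  })
}

split_geno_token <- function(tok, what) {
  parts <- strsplit(tok, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(what, ": malformed genotype token '", tok[bad][1],
         "' (expected 'a/b')")
  }
  a1 <- vapply(parts, `[[`, character(1), 1L)
  a2 <- vapply(parts, `[[`, character(1), 2L)
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  list(a1 = a1, a2 = a2)
}

# map observed allele label strings to indices in order of first appearance
index_alleles <- function(l1, l2, preset = NULL) {
  seen <- unique(stats::na.omit(as.vector(rbind(l1, l2))))
  labels <- unique(c(preset, seen))
  if (length(labels) == 0L) labels <- character(0)
  list(labels = labels,
       a1 = match(l1, labels), a2 = match(l2, labels))
}

#' Read an annotated-format file bundle
#'
#' @param bundle named list of paths: `pedigree`, `names`, `map`
#'   required; `omit`, `freq`, `penetrance` optional.
#' @param mode genotype storage mode passed to [geno_matrix()].
#' @return a [ped_dataset()] with loci reordered to map order; omit
#'   entries (if any) are stored on the dataset as `$omit` for the
#'   transform stage, frequencies and penetrance models are attached to
#'   the loci / dataset.
#' @export
read_annotated <- function(bundle, mode = "auto") {
  for (role in c("pedigree", "names", "map")) {
    if (is.null(bundle[[role]])) stop("annotated input requires a ", role, " file")
  }
  names_tab <- read_names_file(bundle$names)
  if (anyDuplicated(names_tab$name)) {
    stop("duplicated names in names file: ",
         paste(unique(names_tab$name[duplicated(names_tab$name)]), collapse = ", "))
  }
  map <- read_map_file(bundle$map)
  lines <- read_clean_lines(bundle$pedigree)
  if (length(lines) < 1L) stop("no individuals in pedigree file")
  hdr <- split_ws(lines[1])
  if (length(hdr) < 5L) stop("annotated pedigree file: missing header row")
  col_names <- hdr[-(1:5)]
  known <- col_names %in% names_tab$name
  if (!all(known)) {
    stop("pedigree columns absent from names file: ",
         paste(col_names[!known], collapse = ", "))
  }
  kinds <- names_tab$kind[match(col_names, names_tab$name)]
  marker_cols <- which(kinds == "marker")
  trait_cols <- which(kinds != "marker")
  in_map <- col_names[marker_cols] %in% map$marker
  if (!all(in_map)) {
    stop("markers absent from map file: ",
         paste(col_names[marker_cols][!in_map], collapse = ", "))
  }

  tok <- tokenize_lines(lines[-1])
  if (length(tok) == 0L) stop("no individuals in pedigree file")
  bad <- which(vapply(tok, length, integer(1)) != length(hdr))
  if (length(bad)) {
    stop("annotated pedigree file line ", bad[1] + 1L,
         ": column count does not match header")
  }
  tok <- do.call(rbind, tok)
  tab <- ped_table(tok[, 1], tok[, 2], tok[, 3], tok[, 4], tok[, 5])

  tvals <- as.data.frame(matrix(nrow = nrow(tab), ncol = 0))
  defs <- data.frame(name = character(), kind = character(),
                     missing_code = character(), stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    v <- tok[, 5L + tc]
    if (kinds[tc] == "affection") {
      vi <- suppressWarnings(as.integer(v))
      vi[!vi %in% 1:2] <- NA_integer_
      tvals[[col_names[tc]]] <- vi
      defs[nrow(defs) + 1L, ] <- list(col_names[tc], "affection", "0")
    } else {
      vn <- suppressWarnings(as.numeric(v))
      vn[v == "."] <- NA_real_
      tvals[[col_names[tc]]] <- vn
      defs[nrow(defs) + 1L, ] <- list(col_names[tc], kinds[tc], ".")
    }
  }

  # markers reordered to map order
  mnames <- map$marker[map$marker %in% col_names[marker_cols]]
  m <- length(mnames)
  a1 <- matrix(NA_integer_, nrow(tab), m)
  a2 <- a1
  labels <- vector("list", m)
  for (j in seq_len(m)) {
    col <- 5L + marker_cols[match(mnames[j], col_names[marker_cols])]
    g <- split_geno_token(tok[, col], paste0("marker ", mnames[j]))
    idx <- index_alleles(g$a1, g$a2)
    labels[[j]] <- idx$labels
    a1[, j] <- idx$a1
    a2[, j] <- idx$a2
  }
  chr <- map$chromosome[match(mnames, map$marker)]
  loci <- new_loci(mnames, chr, labels)

  if (!is.null(bundle$freq)) {
    ft <- read_freq_file(bundle$freq)
    unknown <- setdiff(ft$marker, mnames)
    if (length(unknown)) {
      stop("frequency file names unknown markers: ",
           paste(unknown, collapse = ", "))
    }
    for (mk in unique(ft$marker)) {
      j <- match(mk, mnames)
      sub <- ft[ft$marker == mk, , drop = FALSE]
      lab <- unique(c(loci$allele_labels[[j]], sub$allele))
      fr <- rep(0, length(lab))
      fr[match(sub$allele, lab)] <- sub$freq
      if (abs(sum(fr) - 1) > 1e-6) {
        stop("allele frequencies for marker ", mk, " sum to ",
             format(sum(fr)), ", not 1")
      }
      loci$allele_labels[[j]] <- lab
      loci$allele_freqs[[j]] <- fr
    }
  }

  gm <- geno_matrix(a1, a2, ped_key(tab), mode = mode)
  ds <- ped_dataset(tab, loci, map[match(mnames, map$marker), , drop = FALSE],
                    gm, list(defs = defs, values = tvals))
  if (!is.null(bundle$penetrance)) {
    ds$penetrance <- read_penetrance_file(bundle$penetrance)
  }
  if (!is.null(bundle$omit)) ds$omit <- read_omit_file(bundle$omit)
  add_provenance(ds, sprintf(
    "read annotated: %d individuals (%d typed), %d markers, %d trait(s)",
    nrow(tab), n_typed(gm), m, nrow(defs)))
}

#' Write an annotated-format file bundle
#'
#' Emits the pedigree/names/map trio (plus a frequency file when
#' frequencies are present and a penetrance file when models are
#' attached) in the dialect read by [read_annotated()].
#'
#' @param ds a [ped_dataset()].
#' @param dir output directory.
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_annotated <- function(ds, dir, stem = "out") {
  check_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- dataset_label_pairs(ds)
  sex_code <- c(male = "1", female = "2", unknown = "0")[ds$ped$sex]
  cols <- list(ds$ped$ped, ds$ped$id,
               ifelse(is.na(ds$ped$father), "0", ds$ped$father),
               ifelse(is.na(ds$ped$mother), "0", ds$ped$mother), sex_code)
  for (t in seq_len(nrow(ds$traits$defs))) {
    v <- ds$traits$values[[t]]
    cols <- c(cols, list(
      if (ds$traits$defs$kind[t] == "affection") {
        ifelse(is.na(v), "0", as.character(v))
      } else ifelse(is.na(v), ".", fmt_num(v))))
  }
  for (j in seq_len(nrow(ds$loci))) {
    g1 <- ifelse(is.na(lp$l1[, j]), "0", lp$l1[, j])
    g2 <- ifelse(is.na(lp$l2[, j]), "0", lp$l2[, j])
    cols <- c(cols, list(paste0(g1, "/", g2)))
  }
  header <- paste(c("Ped", "Id", "Father", "Mother", "Sex",
                    ds$traits$defs$name, ds$loci$name), collapse = " ")
  ped_path <- file.path(dir, paste0(stem, ".ped"))
  write_lines_unix(c(header, do.call(paste, cols)), ped_path)

  names_path <- file.path(dir, paste0(stem, ".names"))
  write_lines_unix(c(paste(ds$traits$defs$name, ds$traits$defs$kind),
                     paste(ds$loci$name, "marker")), names_path)

  map_path <- file.path(dir, paste0(stem, ".map"))
  mp <- ds$map[match(ds$loci$name, ds$map$marker), , drop = FALSE]
  write_lines_unix(c("chromosome marker female_cM male_cM avg_cM bp",
                     paste(mp$chromosome, mp$marker, fmt_num(mp$female_cM),
                           fmt_num(mp$male_cM), fmt_num(mp$avg_cM), mp$bp)),
                   map_path)
  paths <- c(ped_path, names_path, map_path)

  has_freq <- !vapply(ds$loci$allele_freqs, is.null, logical(1))
  if (any(has_freq)) {
    fl <- character()
    for (j in which(has_freq)) {
      fl <- c(fl, paste(ds$loci$name[j], ds$loci$allele_labels[[j]],
                        fmt_num(ds$loci$allele_freqs[[j]])))
    }
    freq_path <- file.path(dir, paste0(stem, ".freq"))
    write_lines_unix(fl, freq_path)
    paths <- c(paths, freq_path)
  }
  if (!is.null(ds$penetrance) && length(ds$penetrance)) {
    pl <- vapply(ds$penetrance, function(pm)
      paste(pm$trait_name, fmt_num(pm$disease_allele_freq),
            paste(fmt_num(pm$penetrances), collapse = " ")), character(1))
    pen_path <- file.path(dir, paste0(stem, ".pen"))
    write_lines_unix(pl, pen_path)
    paths <- c(paths, pen_path)
  }
  invisible(paths)
}
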