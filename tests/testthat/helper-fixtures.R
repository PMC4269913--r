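# fixture builders and independent oracles shared across the suite

# a gene-dropped dataset with an affection trait attached
make_dataset <- function(seed = 1, n_families = 3, structure = "sibship_3",
                         freqs = c(0.3, 0.5, 0.7), with_trait = TRUE) {
  tab <- simulate_pedigree(n_families, structure, seed = seed)
  ds <- gene_drop(tab, freqs = freqs, seed = seed + 1000)
  if (with_trait) {
    set.seed(seed + 2000)
    ds$traits <- list(
      defs = data.frame(name = "aff", kind = "affection", missing_code = "0",
                        stringsAsFactors = FALSE),
      values = data.frame(aff = sample(c(1L, 2L, NA), nrow(ds$ped),
                                       replace = TRUE)))
  }
  check_dataset(ds)
  ds
}

# hand-built three-generation pedigree of 6 with 2 married-in spouses:
# founder couple (GF, GM), their child C1 married to spouse S1 with
# children K1, K2
make_three_gen_tab <- function() {
  ped_table(ped = rep("P1", 6),
            id = c("GF", "GM", "C1", "S1", "K1", "K2"),
            father = c(NA, NA, "GF", NA, "C1", "C1"),
            mother = c(NA, NA, "GM", NA, "S1", "S1"),
            sex = c("male", "female", "male", "female", "female", "male"))
}

# dataset over an explicit codes matrix (rows = individuals of `tab`,
# one column per marker, codes 0..3 over alleles "1","2")
make_coded_dataset <- function(tab, codes, chromosomes = NULL, traits = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  g <- decode_genotype(codes)
  a1 <- matrix(g$a1, nrow(tab), m)
  a2 <- matrix(g$a2, nrow(tab), m)
  gm <- geno_matrix(a1, a2, ped_key(tab))
  if (is.null(chromosomes)) chromosomes <- rep("1", m)
  loci <- new_loci(paste0("M", seq_len(m)), chromosomes,
                   rep(list(c("1", "2")), m))
  bp <- integer(m)
  for (chr in unique(chromosomes)) {
    sel <- chromosomes == chr
    bp[sel] <- seq_len(sum(sel)) * 1000L
  }
  map <- new_map(chromosome = chromosomes, marker = loci$name,
                 avg_cM = ave(seq_len(m), chromosomes, FUN = seq_along) * 5,
                 bp = bp)
  ds <- ped_dataset(tab, loci, map, gm,
                    if (is.null(traits)) empty_traits(nrow(tab)) else traits)
  ds
}

# --- independent Mendelian trio oracle -----------------------------------
# Enumerates, over a biallelic locus, every completion of missing
# genotypes to {1/1, 1/2, 2/2} and every parental transmission; written
# from the definition of biparental inheritance, independent of
# check_mendelian's search.
trio_oracle_consistent <- function(f_code, m_code, c_code) {
  expand <- function(code) switch(as.character(code),
    "0" = list(c(1L, 1L), c(1L, 2L), c(2L, 2L)),
    "1" = list(c(1L, 1L)), "2" = list(c(1L, 2L)), "3" = list(c(2L, 2L)))
  for (fg in expand(f_code)) for (mg in expand(m_code)) {
    for (cg in expand(c_code)) {
      for (from_f in fg) for (from_m in mg) {
        if (identical(sort(c(from_f, from_m)), sort(cg))) return(TRUE)
      }
    }
  }
  FALSE
}

# --- per-format file-parsing oracles -------------------------------------
# Each oracle reads a written file set with nothing but base R string
# operations (independent of the package's readers) and reports the
# conserved quantities: individual count, marker count, missing-genotype
# count over all individuals.
oracle_counts <- function(target, dir, stem) {
  rl <- function(f) readLines(file.path(dir, f), warn = FALSE)
  toks <- function(lines) lapply(trimws(lines), function(x)
    strsplit(x, "[ \t]+")[[1]])
  switch(target,
    plink_text = {
      ped <- toks(rl(paste0(stem, ".ped")))
      map <- rl(paste0(stem, ".map"))
      gcols <- lapply(ped, function(t) t[-(1:6)])
      list(n_ind = length(ped), n_markers = length(map),
           n_missing = sum(vapply(gcols, function(g)
             sum(g[c(TRUE, FALSE)] == "0"), numeric(1))))
    },
    plink_binary = {
      fam <- rl(paste0(stem, ".fam"))
      bim <- rl(paste0(stem, ".bim"))
      n <- length(fam); m <- length(bim)
      bytes <- readBin(file.path(dir, paste0(stem, ".bed")), "raw",
                       n = 3 + ceiling(n / 4) * m)
      body <- as.integer(bytes[-(1:3)])
      two_bit <- unlist(lapply(body, function(b)
        c(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, b %/% 64)))
      per_marker <- matrix(two_bit, nrow = 4 * ceiling(n / 4))
      list(n_ind = n, n_markers = m,
           n_missing = sum(per_marker[seq_len(n), , drop = FALSE] == 1L))
    },
    linkage = {
      pre <- toks(rl(paste0(stem, ".pre")))
      dat <- rl(paste0(stem, ".dat"))
      nloci <- as.integer(strsplit(trimws(dat[1]), "[ \t]+")[[1]][1])
      # locus blocks start after header/mutation/order lines; affection
      # loci are the type-1 blocks
      n_aff <- sum(grepl("^1 2( |$)", trimws(dat[-(1:3)])))
      m <- nloci - n_aff
      gcols <- lapply(pre, function(t) t[-seq_len(5 + n_aff)])
      list(n_ind = length(pre), n_markers = m,
           n_missing = sum(vapply(gcols, function(g)
             sum(g[c(TRUE, FALSE)] == "0"), numeric(1))))
    },
    merlin = {
      ped <- toks(rl(paste0(stem, ".ped")))
      dat <- rl(paste0(stem, ".dat"))
      m <- sum(grepl("^M ", dat))
      n_tr <- sum(!grepl("^M ", dat))
      gcols <- lapply(ped, function(t) t[-seq_len(5 + n_tr)])
      list(n_ind = length(ped), n_markers = m,
           n_missing = sum(vapply(gcols, function(g)
             sum(g == "0/0"), numeric(1))))
    },
    eigenstrat = {
      geno <- rl(paste0(stem, ".geno"))
      list(n_ind = length(rl(paste0(stem, ".ind"))),
           n_markers = length(geno),
           n_missing = sum(vapply(strsplit(geno, ""), function(d)
             sum(d == "9"), numeric(1))))
    },
    structure = {
      lines <- rl(paste0(stem, ".structure"))
      rows <- toks(lines[-1])
      m <- length(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
      list(n_ind = length(rows), n_markers = m,
           n_missing = sum(vapply(rows, function(t)
             sum(t[-(1:2)][c(TRUE, FALSE)] == "-9"), numeric(1))))
    },
    fbat = {
      lines <- rl(paste0(stem, ".ped"))
      m <- length(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
      rows <- toks(lines[-1])
      list(n_ind = length(rows), n_markers = m,
           n_missing = sum(vapply(rows, function(t)
             sum(t[-(1:6)][c(TRUE, FALSE)] == "0"), numeric(1))))
    },
    solar = {
      marker <- rl(paste0(stem, ".marker"))
      hdr <- strsplit(marker[1], ",", fixed = TRUE)[[1]]
      rows <- strsplit(marker[-1], ",", fixed = TRUE)
      list(n_ind = length(rl("pedigree.csv")) - 1L,
           n_markers = length(hdr) - 1L,
           n_missing = sum(vapply(rows, function(t)
             sum(c(t, rep("", length(hdr) - length(t)))[-1] == ""),
             numeric(1))))
    },
    annotated = {
      lines <- rl(paste0(stem, ".ped"))
      names_f <- toks(rl(paste0(stem, ".names")))
      m <- sum(vapply(names_f, function(t) t[2] == "marker", logical(1)))
      rows <- toks(lines[-1])
      nt <- length(names_f) - m
      list(n_ind = length(rows), n_markers = m,
           n_missing = sum(vapply(rows, function(t)
             sum(t[-seq_len(5 + nt)] == "0/0"), numeric(1))))
    },
    stop("no oracle for target ", target))
}

# dataset-side conserved quantities, computed over ALL individuals
dataset_counts <- function(ds) {
  p <- geno_pairs_full(ds$genotypes, ped_key(ds$ped))
  list(n_ind = nrow(ds$ped), n_markers = nrow(ds$loci),
       n_missing = sum(is.na(p$a1)))
}
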