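#' Encode an unordered allele pair as a two-bit genotype code
#'
#' Biallelic genotypes are stored internally as a single integer code:
#' 0 = missing, 1 = homozygous for allele 1, 2 = heterozygous,
#' 3 = homozygous for allele 2.  The code is insensitive to allele order
#' (phase is never stored), and any half-typed genotype (exactly one
#' allele known) is demoted to fully missing because a single two-bit
#' code cannot represent it.
#'
#' @param a1,a2 integer vectors of allele indices (1 or 2), `NA` = missing.
#' @return integer vector of codes in `0:3`.
#' @examples
#' encode_genotype(c(NA, 1, 2, 2, 1), c(NA, 2, 1, 2, 1))
#' @export
encode_genotype <- function(a1, a2) {
  a1 <- as.integer(a1)
  a2 <- as.integer(a2)
  if (length(a1) != length(a2)) {
    stop("allele vectors must have equal length")
  }
  ok <- is.na(a1) | is.na(a2) | (a1 %in% 1:2 & a2 %in% 1:2)
  if (!all(ok)) {
    stop("allele index > 2: two-bit mode holds at most two alleles; ",
         "use general storage mode for multi-allelic loci")
  }
  code <- integer(length(a1))
  typed <- !is.na(a1) & !is.na(a2)   # half-typed -> 0 (missing)
  lo <- pmin(a1[typed], a2[typed])
  hi <- pmax(a1[typed], a2[typed])
  code[typed] <- ifelse(lo == 1L, ifelse(hi == 1L, 1L, 2L), 3L)
  code
}

#' Decode two-bit genotype codes back to sorted allele pairs
#'
#' @param code integer vector of codes in `0:3`.
#' @return list with integer vectors `a1`, `a2` (`a1 <= a2`, `NA` = missing).
#' @export
decode_genotype <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 3L)) {
    stop("genotype codes must be in 0..3")
  }
  lut1 <- c(NA_integer_, 1L, 1L, 2L)
  lut2 <- c(NA_integer_, 1L, 2L, 2L)
  list(a1 = lut1[code + 1L], a2 = lut2[code + 1L])
}

#' Pack two-bit genotype codes into a byte buffer
#'
#' Four codes per byte, first code in the two least-significant bits
#' (the convention used by the dominant binary genotype file format,
#' which keeps the binary writer a straight memory copy).  A final
#' partial byte is zero-padded.
#'
#' @param codes integer vector with values in `0:3`.
#' @return raw vector of length `ceiling(length(codes)/4)`.
#' @seealso [unpack_codes()] for the exact inverse.
#' @examples
#' pack_codes(c(1L, 2L, 0L, 3L))  # 0xc9
#' @export
pack_codes <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0L) return(raw(0))
  if (any(is.na(codes)) || any(codes < 0L | codes > 3L)) {
    stop("genotype codes must be in 0..3")
  }
  pad <- (-length(codes)) %% 4L
  m <- matrix(c(codes, integer(pad)), nrow = 4L)
  as.raw(as.integer(crossprod(c(1L, 4L, 16L, 64L), m)))
}

#' Unpack a byte buffer into two-bit genotype codes
#'
#' @param bytes raw vector produced by [pack_codes()].
#' @param n number of codes to recover (strips the zero padding).
#' @return integer vector of length `n` with values in `0:3`.
#' @export
unpack_codes <- function(bytes, n) {
  n <- as.integer(n)
  if (n > 4L * length(bytes)) {
    stop("buffer too short for ", n, " genotype codes")
  }
  b <- as.integer(bytes)
  out <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  as.integer(out)[seq_len(n)]
}

# marker-major packing of a codes matrix (individuals x markers):
# one packed column of ceiling(n/4) bytes per marker.
pack_codes_matrix <- function(codes) {
  n <- nrow(codes)
  m <- ncol(codes)
  if (n == 0L || m == 0L) {
    return(matrix(raw(0), nrow = ceiling(n / 4), ncol = m))
  }
  pad <- (-n) %% 4L
  cm <- rbind(codes, matrix(0L, nrow = pad, ncol = m))
  dim(cm) <- c(4L, (n + pad) / 4L * m)
  bytes <- as.raw(as.integer(crossprod(c(1L, 4L, 16L, 64L), cm)))
  matrix(bytes, nrow = (n + pad) / 4L, ncol = m)
}

unpack_codes_matrix <- function(packed, n) {
  m <- ncol(packed)
  if (n == 0L || m == 0L) return(matrix(integer(0), nrow = n, ncol = m))
  b <- as.integer(packed)
  out <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  dim(out) <- c(4L * nrow(packed), m)
  out[seq_len(n), , drop = FALSE]
}

#' Construct a genotype matrix store
#'
#' The genotype store is marker-major and covers *typed* individuals
#' only: individuals whose genotypes are all missing contribute no
#' storage (they remain full members of the pedigree).  Two storage
#' modes exist: `two_bit` packs biallelic genotypes four to a byte;
#' `general` keeps an allele-index-pair table and accepts any number of
#' alleles per locus.  Mode `"auto"` picks `two_bit` whenever every
#' locus has at most two alleles.
#'
#' Half-typed genotypes (one known allele) are demoted to missing; the
#' demotion count is kept in the `half_typed_demoted` field.
#'
#' @param a1,a2 integer matrices (individuals x markers) of allele
#'   indices, `NA` = missing.  Rows cover *all* individuals.
#' @param keys character vector of individual keys, one per row.
#' @param mode `"auto"`, `"two_bit"`, or `"general"`.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(a1, a2, keys, mode = c("auto", "two_bit", "general")) {
  mode <- match.arg(mode)
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
  stopifnot(identical(dim(a1), dim(a2)), length(keys) == nrow(a1))
  if (anyDuplicated(keys)) stop("duplicate individual keys in genotype matrix")

  half <- xor(is.na(a1), is.na(a2))
  n_half <- sum(half)
  if (n_half > 0L) {
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)

  typed <- rowSums(!is.na(lo)) > 0L
  lo <- lo[typed, , drop = FALSE]
  hi <- hi[typed, , drop = FALSE]

  max_allele <- if (length(hi) && any(!is.na(hi))) max(hi, na.rm = TRUE) else 0L
  if (mode == "auto") mode <- if (max_allele <= 2L) "two_bit" else "general"
  if (mode == "two_bit" && max_allele > 2L) {
    stop("allele index > 2 found: two-bit mode holds at most two alleles; ",
         "use general storage mode for multi-allelic loci")
  }

  gm <- structure(list(
    mode = mode,
    typed_keys = as.character(keys)[typed],
    n_markers = ncol(a1),
    half_typed_demoted = n_half
  ), class = "geno_matrix")
  if (mode == "two_bit") {
    code <- matrix(0L, nrow = nrow(lo), ncol = ncol(lo))
    ok <- !is.na(lo)
    code[ok] <- ifelse(lo[ok] == 1L, ifelse(hi[ok] == 1L, 1L, 2L), 3L)
    gm$packed <- pack_codes_matrix(code)
  } else {
    gm$a1 <- lo
    gm$a2 <- hi
  }
  gm
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d typed individuals x %d markers, %s mode\n",
              length(x$typed_keys), x$n_markers, x$mode))
  if (x$mode == "two_bit") {
    cat(sprintf("  packed storage: %d bytes\n", length(x$packed)))
  }
  if (x$half_typed_demoted > 0L) {
    cat(sprintf("  %d half-typed genotypes demoted to missing\n",
                x$half_typed_demoted))
  }
  invisible(x)
}

n_typed <- function(gm) length(gm$typed_keys)

#' Extract genotype codes from a two-bit genotype matrix
#'
#' @param gm a `geno_matrix` in either mode (general mode must be biallelic).
#' @return integer matrix (typed individuals x markers) of codes `0:3`.
#' @export
geno_codes <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$mode == "two_bit") {
    codes <- unpack_codes_matrix(gm$packed, n_typed(gm))
  } else {
    if (length(gm$a2) && any(gm$a2 > 2L, na.rm = TRUE)) {
      stop("genotype codes are only defined for biallelic storage")
    }
    codes <- matrix(0L, nrow = nrow(gm$a1), ncol = ncol(gm$a1))
    ok <- !is.na(gm$a1)
    codes[ok] <- ifelse(gm$a1[ok] == 1L, ifelse(gm$a2[ok] == 1L, 1L, 2L), 3L)
  }
  dimnames(codes) <- list(gm$typed_keys, NULL)
  codes
}

#' Extract allele-index pairs from a genotype matrix
#'
#' @param gm a `geno_matrix`.
#' @return list of two integer matrices `a1`, `a2` (typed individuals x
#'   markers), `a1 <= a2`, `NA` = missing.
#' @export
geno_pairs <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$mode == "general") {
    a1 <- gm$a1; a2 <- gm$a2
  } else {
    p <- decode_genotype(geno_codes(gm))
    a1 <- matrix(p$a1, nrow = n_typed(gm))
    a2 <- matrix(p$a2, nrow = n_typed(gm))
  }
  dimnames(a1) <- dimnames(a2) <- list(gm$typed_keys, NULL)
  list(a1 = a1, a2 = a2)
}

# Allele pairs expanded to all individuals (untyped rows all-NA), aligned
# to `keys`.
geno_pairs_full <- function(gm, keys) {
  p <- geno_pairs(gm)
  a1 <- matrix(NA_integer_, nrow = length(keys), ncol = gm$n_markers)
  a2 <- a1
  idx <- match(gm$typed_keys, keys)
  if (anyNA(idx)) stop("genotype matrix contains keys absent from pedigree")
  a1[idx, ] <- p$a1
  a2[idx, ] <- p$a2
  rownames(a1) <- rownames(a2) <- keys
  list(a1 = a1, a2 = a2)
}

#' Convert a genotype matrix between storage modes
#'
#' @param gm a `geno_matrix`.
#' @param mode target mode, `"two_bit"` or `"general"`.
#' @return a `geno_matrix` storing the same genotypes in the target mode.
#' @export
geno_set_mode <- function(gm, mode = c("two_bit", "general")) {
  mode <- match.arg(mode)
  if (gm$mode == mode) return(gm)
  p <- geno_pairs(gm)
  out <- geno_matrix(p$a1, p$a2, gm$typed_keys, mode = mode)
  out$half_typed_demoted <- gm$half_typed_demoted
  out
}

# subset markers, keeping mode; may shrink typed rows (an individual typed
# only at dropped markers leaves the store).
gm_subset_markers <- function(gm, j) {
  p <- geno_pairs(gm)
  out <- geno_matrix(p$a1[, j, drop = FALSE], p$a2[, j, drop = FALSE],
                     gm$typed_keys, mode = gm$mode)
  out$half_typed_demoted <- gm$half_typed_demoted
  out
}

# count of missing genotype cells over typed rows
gm_missing_count <- function(gm) {
  if (gm$mode == "two_bit") sum(geno_codes(gm) == 0L) else sum(is.na(gm$a1))
}
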