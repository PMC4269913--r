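#' Build a pedigree table
#'
#' The pedigree graph is held as a data frame with one row per
#' individual.  Parent ids refer to individuals within the same
#' pedigree; founders have both parent ids `NA`.  The file sex codes
#' 1/2/0 map to `"male"`/`"female"`/`"unknown"`.
#'
#' @param ped,id character vectors: pedigree id and individual id.
#' @param father,mother character vectors of parent ids, `NA` for
#'   founders.  Empty strings and `"0"` are normalised to `NA`.
#' @param sex `"male"`, `"female"`, or `"unknown"` (or file codes 1/2/0).
#' @return data frame of class `ped_table` with columns
#'   `ped`, `id`, `father`, `mother`, `sex`.
#' @export
ped_table <- function(ped, id, father, mother, sex) {
  norm_parent <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  sex <- as.character(sex)
  sex[sex == "1"] <- "male"
  sex[sex == "2"] <- "female"
  sex[sex == "0" | is.na(sex)] <- "unknown"
  bad_sex <- !sex %in% c("male", "female", "unknown")
  sex[bad_sex] <- "unknown"
  out <- data.frame(ped = as.character(ped), id = as.character(id),
                    father = norm_parent(father), mother = norm_parent(mother),
                    sex = sex, stringsAsFactors = FALSE)
  attr(out, "n_bad_sex") <- sum(bad_sex)
  class(out) <- c("ped_table", "data.frame")
  out
}

#' @export
print.ped_table <- function(x, ...) {
  cat(sprintf("<ped_table> %d individuals in %d pedigree(s)\n",
              nrow(x), length(unique(x$ped))))
  NextMethod()
}

# study-wide unique individual key
ped_key <- function(ped, id = NULL) {
  if (is.null(id)) { id <- ped$id; ped <- ped$ped }
  paste(ped, id, sep = ":")
}

parent_key <- function(tab, which) {
  ifelse(is.na(tab[[which]]), NA_character_, ped_key(tab$ped, tab[[which]]))
}

#' Find the founders of a pedigree graph
#'
#' Founders are exactly the individuals with both parents absent; they
#' carry the population allele frequencies in downstream estimation and
#' simulation.
#'
#' @param tab a [ped_table()].
#' @return character vector of individual keys (`"ped:id"`).
#' @export
find_founders <- function(tab) {
  ped_key(tab)[is.na(tab$father) & is.na(tab$mother)]
}

#' Enumerate the nuclear families of a pedigree graph
#'
#' One entry per distinct parent pair with at least one child.  An
#' individual may appear in several entries (child in one, parent in
#' another).  Enumeration order is deterministic: pedigrees in table
#' order, parent pairs sorted by (father id, mother id) within a
#' pedigree; children are sorted by individual id.
#'
#' @param tab a [ped_table()].
#' @return list of entries with fields `ped`, `father`, `mother`
#'   (individual ids) and `children` (sorted character vector of ids).
#' @export
enumerate_nuclear_families <- function(tab) {
  has_parents <- !is.na(tab$father) & !is.na(tab$mother)
  kids <- tab[has_parents, , drop = FALSE]
  if (nrow(kids) == 0L) return(list())
  out <- list()
  for (p in unique(tab$ped)) {
    sel <- kids$ped == p
    if (!any(sel)) next
    pairs <- unique(data.frame(father = kids$father[sel],
                               mother = kids$mother[sel],
                               stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$father, pairs$mother), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      ch <- kids$id[sel & kids$father == pairs$father[i] &
                      kids$mother == pairs$mother[i]]
      out[[length(out) + 1L]] <- list(ped = p,
                                      father = pairs$father[i],
                                      mother = pairs$mother[i],
                                      children = sort(ch))
    }
  }
  out
}

# per-individual generation depth (founders = 1); NA marks individuals on
# a cycle.  Iterative relaxation bounded by n passes.
ped_generations <- function(tab) {
  n <- nrow(tab)
  keys <- ped_key(tab)
  fk <- parent_key(tab, "father")
  mk <- parent_key(tab, "mother")
  fi <- match(fk, keys)
  mi <- match(mk, keys)
  depth <- ifelse(is.na(fi) & is.na(mi), 1L, NA_integer_)
  for (pass in seq_len(n + 1L)) {
    changed <- FALSE
    for (i in which(is.na(depth))) {
      dp <- c(if (!is.na(fi[i])) depth[fi[i]] else 1L,
              if (!is.na(mi[i])) depth[mi[i]] else 1L)
      if (!anyNA(dp)) { depth[i] <- max(dp) + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  names(depth) <- keys
  depth
}

# TRUE if the parent links contain a directed cycle
ped_has_cycle <- function(tab) anyNA(ped_generations(tab))
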