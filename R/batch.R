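# The batch file is the non-interactive front end: one "key = value"
# pair per line drives the whole read -> validate -> transform -> write
# pipeline.  The key vocabulary is this package's own documented
# dialect.

batch_keys <- c(
  "input.format", "input.pedigree", "input.datafile", "input.names",
  "input.map", "input.omit", "input.freq", "input.penetrance",
  "input.ped", "input.pheno", "input.bed", "input.bim", "input.fam",
  "input.vcf",
  "output.target", "output.dir", "output.stem", "output.per_chromosome",
  "filter.chromosomes", "filter.markers", "filter.bp_range",
  "traits.select", "mendel.policy", "freq.scope", "mode.two_bit",
  "seed", "allow_empty_selection", "validate.override")

list_keys <- c("filter.chromosomes", "filter.markers", "traits.select")
flag_keys <- c("output.per_chromosome", "mode.two_bit",
               "allow_empty_selection", "validate.override")

required_input_keys <- list(
  linkage = c("input.pedigree", "input.datafile"),
  annotated = c("input.pedigree", "input.names", "input.map"),
  plink_text = c("input.ped", "input.map"),
  plink_binary = c("input.bed", "input.bim", "input.fam"),
  vcf = "input.vcf")

parse_bool <- function(x, key) {
  v <- tolower(x)
  if (v %in% c("true", "yes", "on", "1")) return(TRUE)
  if (v %in% c("false", "no", "off", "0")) return(FALSE)
  stop("batch key ", key, ": cannot read '", x, "' as true/false")
}

#' Parse a batch file into a validated configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines are
#' allowed; values are trimmed and list-valued keys split on commas.
#' Unknown keys are rejected with a nearest-key suggestion, duplicate
#' and missing required keys are errors.
#'
#' @param path batch file path.
#' @param overrides named list of key/value pairs (e.g. from CLI
#'   flags) that override the file.
#' @return named list of class `batch_config`.
#' @export
parse_batch_file <- function(path, overrides = list()) {
  lines <- read_clean_lines(path)
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("batch file: no '=' on line: ", trimws(ln))
    key <- trimws(substring(ln, 1, eq - 1))
    val <- trimws(substring(ln, eq + 1))
    if (!key %in% batch_keys) {
      dist <- utils::adist(key, batch_keys)
      stop("unknown batch key '", key, "'; did you mean '",
           batch_keys[which.min(dist)], "'?")
    }
    if (key %in% names(kv)) stop("duplicate batch key '", key, "'")
    kv[[key]] <- val
  }
  for (key in names(overrides)) {
    if (!key %in% batch_keys) {
      dist <- utils::adist(key, batch_keys)
      stop("unknown batch key '", key, "'; did you mean '",
           batch_keys[which.min(dist)], "'?")
    }
    kv[[key]] <- as.character(overrides[[key]])
  }
  batch_config(kv)
}

# validate a raw key->string map and coerce typed values
batch_config <- function(kv) {
  for (key in c("input.format", "output.target", "output.dir")) {
    if (is.null(kv[[key]])) stop("missing required batch key '", key, "'")
  }
  fmt <- match.arg(kv[["input.format"]], names(required_input_keys))
  kv[["input.format"]] <- fmt
  for (key in required_input_keys[[fmt]]) {
    if (is.null(kv[[key]])) {
      stop("input.format ", fmt, " requires batch key '", key, "'")
    }
  }
  kv[["output.target"]] <- match.arg(kv[["output.target"]], write_targets)
  for (key in intersect(names(kv), list_keys)) {
    kv[[key]] <- trimws(strsplit(kv[[key]], ",", fixed = TRUE)[[1]])
  }
  for (key in intersect(names(kv), flag_keys)) {
    kv[[key]] <- parse_bool(kv[[key]], key)
  }
  if (!is.null(kv[["seed"]])) kv[["seed"]] <- as.integer(kv[["seed"]])
  if (!is.null(kv[["mendel.policy"]])) {
    kv[["mendel.policy"]] <- match.arg(kv[["mendel.policy"]],
                                       c("zero_family_marker", "zero_child",
                                         "report_only"))
  }
  if (!is.null(kv[["freq.scope"]])) {
    kv[["freq.scope"]] <- match.arg(kv[["freq.scope"]], c("founders", "all"))
  }
  if (!is.null(kv[["filter.bp_range"]])) {
    part <- strsplit(kv[["filter.bp_range"]], "[:\\-]")[[1]]
    if (length(part) != 3L) {
      stop("filter.bp_range must be 'chromosome:start-end'")
    }
    kv[["filter.bp_range"]] <- list(chromosome = part[1],
                                    start = as.numeric(part[2]),
                                    end = as.numeric(part[3]))
  }
  structure(kv, class = "batch_config")
}

#' Run the conversion pipeline described by a batch configuration
#'
#' Stage order is fixed: read, structural validation, X-genotype check,
#' Mendelian check and resolution, allele-frequency estimation (so that
#' zeroed genotypes cannot bias the counts), omission, locus subset,
#' trait selection, allele recoding, optional per-chromosome split, and
#' the target writer.  Any blocking error aborts with a nonzero status
#' and removes partial output files; every stage logs its finding
#' counts and the file manifest, each line timestamp-prefixed.
#'
#' @param config a `batch_config` from [parse_batch_file()].
#' @param log_file optional path for a copy of the log.
#' @param quiet suppress log output to stderr?
#' @return list with `status` (0 = success), `files` (written paths),
#'   `findings` (combined findings table), `log` (character vector),
#'   and, on success, the final `dataset`; returned invisibly.
#' @export
run_batch <- function(config, log_file = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "batch_config"))
  log <- character()
  say <- function(fmt, ...) {
    line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                   sprintf(fmt, ...))
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  manifest <- character()
  all_findings <- no_findings()
  seed <- if (is.null(config[["seed"]])) 1L else config[["seed"]]
  out_dir <- NULL
  out_dir_before <- character()
  fail <- function(msg) {
    say("ERROR: %s", msg)
    existing <- manifest[file.exists(manifest)]
    if (!is.null(out_dir) && dir.exists(out_dir)) {
      now <- list.files(out_dir, full.names = TRUE)
      existing <- unique(c(existing, setdiff(now, out_dir_before)))
    }
    if (length(existing)) {
      file.remove(existing)
      say("removed %d partial output file(s)", length(existing))
    }
    if (!is.null(log_file)) writeLines(log, log_file)
    list(status = 1L, files = character(), findings = all_findings, log = log)
  }

  out <- tryCatch({
    fmt <- config[["input.format"]]
    say("stage read: format %s", fmt)
    ds <- switch(fmt,
      linkage = read_linkage(config[["input.pedigree"]],
                             config[["input.datafile"]]),
      annotated = read_annotated(list(
        pedigree = config[["input.pedigree"]], names = config[["input.names"]],
        map = config[["input.map"]], omit = config[["input.omit"]],
        freq = config[["input.freq"]],
        penetrance = config[["input.penetrance"]])),
      plink_text = read_plink_text(config[["input.ped"]], config[["input.map"]],
                                   config[["input.pheno"]]),
      plink_binary = read_plink_binary(config[["input.bed"]],
                                       config[["input.bim"]],
                                       config[["input.fam"]],
                                       config[["input.pheno"]]),
      vcf = read_vcf(config[["input.vcf"]], fam_path = config[["input.fam"]]))
    if (isTRUE(config[["mode.two_bit"]])) {
      ds$genotypes <- geno_set_mode(ds$genotypes, "two_bit")
    }
    read_findings <- attr(ds, "findings")
    if (!is.null(read_findings)) {
      all_findings <- bind_findings(all_findings, read_findings)
    }
    say("read %d individuals (%d typed), %d markers", nrow(ds$ped),
        length(ds$genotypes$typed_keys), nrow(ds$loci))

    say("stage validate: structure")
    sf <- validate_structure(ds)
    all_findings <- bind_findings(all_findings, sf)
    n_err <- sum(sf$severity == "error")
    say("structure findings: %d error(s), %d warning(s)", n_err,
        sum(sf$severity == "warning"))
    if (n_err > 0L && !isTRUE(config[["validate.override"]])) {
      stop(n_err, " blocking structure error(s); first: ",
           format_findings(sf[sf$severity == "error", ])[1],
           " (set validate.override to proceed)")
    }

    ds <- validate_x_genotypes(ds)
    xf <- attr(ds, "findings")
    all_findings <- bind_findings(all_findings, xf)
    if (nrow(xf)) say("x-check: %d male X heterozygote(s) blanked", nrow(xf))

    say("stage validate: mendelian")
    mf <- check_mendelian(ds)
    policy <- if (is.null(config[["mendel.policy"]])) "zero_family_marker" else
      config[["mendel.policy"]]
    ds <- resolve_mendelian(ds, mf, policy = policy)
    say("mendel: %d inconsistent family-marker(s), policy %s", nrow(mf), policy)

    scope <- if (is.null(config[["freq.scope"]])) "founders" else
      config[["freq.scope"]]
    ds <- set_allele_frequencies(ds, scope = scope)
    say("allele frequencies: scope %s", scope)

    if (!is.null(ds$omit) && nrow(ds$omit)) {
      ds <- apply_omit(ds, ds$omit)
      say("omit: %d entrie(s) applied", nrow(ds$omit))
    }
    allow_empty <- isTRUE(config[["allow_empty_selection"]])
    if (!is.null(config[["filter.chromosomes"]])) {
      ds <- subset_loci(ds, locus_selector(
        chromosomes = config[["filter.chromosomes"]]), allow_empty)
      say("filter: %d loci on chromosomes %s", nrow(ds$loci),
          paste(config[["filter.chromosomes"]], collapse = ","))
    }
    if (!is.null(config[["filter.markers"]])) {
      ds <- subset_loci(ds, locus_selector(names = config[["filter.markers"]]),
                        allow_empty)
      say("filter: %d loci by name", nrow(ds$loci))
    }
    if (!is.null(config[["filter.bp_range"]])) {
      ds <- subset_loci(ds, locus_selector(bp_range = config[["filter.bp_range"]]),
                        allow_empty)
      say("filter: %d loci in bp range", nrow(ds$loci))
    }
    if (!is.null(config[["traits.select"]])) {
      ds <- select_traits(ds, config[["traits.select"]])
      say("traits: %s", paste(config[["traits.select"]], collapse = ","))
    }
    rec <- recode_alleles(ds, scope = scope)
    ds <- rec$dataset
    say("recode: alleles numbered by descending frequency")

    target <- config[["output.target"]]
    dir <- config[["output.dir"]]
    stem <- if (is.null(config[["output.stem"]])) "out" else
      config[["output.stem"]]
    per_chr <- isTRUE(config[["output.per_chromosome"]])
    say("stage write: target %s -> %s", target, dir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out_dir <- dir
    out_dir_before <- list.files(dir, full.names = TRUE)
    manifest <- write_dataset(ds, target, dir, stem, per_chromosome = per_chr)
    for (f in manifest) say("wrote %s", f)
    say("done: status 0, %d file(s), seed %d", length(manifest), seed)
    if (!is.null(log_file)) writeLines(log, log_file)
    list(status = 0L, files = manifest, findings = all_findings, log = log,
         dataset = ds)
  }, error = function(e) fail(conditionMessage(e)))
  invisible(out)
}
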