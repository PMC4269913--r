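# machine-readable diagnostics shared by all error-checking stages

finding <- function(severity, category, message,
                    pedigree = NA_character_, individual = NA_character_,
                    marker = NA_character_) {
  data.frame(severity = severity, category = category, pedigree = pedigree,
             individual = individual, marker = marker, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() finding(character(), character(), character(),
                                  character(), character(), character())

bind_findings <- function(...) {
  do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0, list(...)))
}

#' Write findings to a tab-separated file
#'
#' @param findings data frame as returned by [validate_structure()] and
#'   friends (columns severity, category, pedigree, individual, marker,
#'   message).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_findings_tsv <- function(findings, path) {
  if (is.null(findings)) findings <- no_findings()
  utils::write.table(findings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# plain-text log rendering of a findings table
format_findings <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0L) return("no findings")
  where <- apply(findings[, c("pedigree", "individual", "marker")], 1L,
                 function(x) paste(stats::na.omit(x), collapse = "/"))
  sprintf("%s [%s]%s %s", toupper(findings$severity), findings$category,
          ifelse(where == "", "", paste0(" (", where, ")")), findings$message)
}
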