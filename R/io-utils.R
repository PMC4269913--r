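# shared text-format helpers: all textual formats accept arbitrary runs
# of spaces/tabs as delimiters, and lines starting with "#" as comments
# (VCF excepted; it follows its own rules via the vcfR parser).

read_clean_lines <- function(path, strip_comments = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (strip_comments) lines <- lines[!grepl("^\\s*#", lines)]
  lines[nzchar(trimws(lines))]
}

split_ws <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

tokenize_lines <- function(lines) {
  lapply(lines, split_ws)
}

# whole-file token stream (for the LINKAGE datafile, which is
# line-layout-flexible); keeps "#" comments per line separately
token_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- character()
  comments <- character()
  for (ln in lines) {
    hash <- regexpr("#", ln, fixed = TRUE)
    if (hash > 0) {
      comments <- c(comments, trimws(substring(ln, hash + 1)))
      ln <- substring(ln, 1, hash - 1)
    }
    t <- split_ws(ln)
    if (length(t)) toks <- c(toks, t)
  }
  list(tokens = toks, comments = comments)
}

write_lines_unix <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

fmt_num <- function(x, digits = 10) {
  vapply(as.numeric(x), function(v)
    format(v, digits = digits, scientific = FALSE, trim = TRUE), character(1))
}
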