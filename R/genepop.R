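#' Read a Genepop genotype file
#'
#' Parses the classic Genepop interchange format: a title line, one locus
#' name per line (or a single comma-separated line), then population blocks
#' introduced by a line reading `pop` (any casing). Individual records are
#' `id , a1a2 a1a2 ...` with fixed-width allele codes; both the 2-digit
#' (4 characters per locus) and 3-digit (6 characters) dialects are
#' auto-detected. Code `00`/`000` means a missing allele.
#'
#' @param x Path to a Genepop file, or the file's contents as a single
#'   string / character vector of lines.
#' @return A tidy genotype tibble (see [as_msat_data()]). Population labels
#'   are `pop1`, `pop2`, ... in order of appearance; locus names and the
#'   title line are kept as attributes `loci` and `title`.
#' @export
read_genepop <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) abort_msat("Genepop document too short to parse")
  title <- lines[1]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort_msat("no 'pop' separator line found")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  locus_lines <- locus_lines[locus_lines != ""]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  if (length(loci) == 0) abort_msat("no locus names before the first 'pop' line")

  pop_id <- cumsum(is_pop)
  recs <- which(!is_pop & seq_along(lines) > first_pop & trimws(lines) != "")
  if (length(recs) == 0) abort_msat("no individual records found")

  # detect allele-code width from the first record
  parse_rec <- function(i, width = NULL) {
    ln <- lines[i]
    cpos <- regexpr(",", ln, fixed = TRUE)
    if (cpos < 0)
      abort_msat(sprintf("line %d: individual record has no comma separator", i))
    id <- trimws(substr(ln, 1, cpos - 1))
    codes <- strsplit(trimws(substr(ln, cpos + 1, nchar(ln))), "[ \t]+")[[1]]
    codes <- codes[codes != ""]
    list(id = id, codes = codes, line = i)
  }
  probe <- parse_rec(recs[1])
  widths <- unique(nchar(probe$codes))
  if (length(widths) != 1 || !widths %in% c(4, 6))
    abort_msat(sprintf(
      "line %d: allele codes must be uniformly 4 (2-digit) or 6 (3-digit) characters",
      probe$line))
  w <- widths / 2

  rows <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    r <- parse_rec(recs[k])
    if (length(r$codes) != length(loci))
      abort_msat(sprintf("line %d: %d genotype codes but %d loci declared",
                         r$line, length(r$codes), length(loci)))
    if (any(nchar(r$codes) != 2 * w))
      abort_msat(sprintf("line %d: inconsistent allele-code width", r$line))
    a1 <- as.integer(substr(r$codes, 1, w))
    a2 <- as.integer(substr(r$codes, w + 1, 2 * w))
    a1[a1 == 0] <- NA_integer_
    a2[a2 == 0] <- NA_integer_
    rows[[k]] <- tibble::tibble(
      pop = paste0("pop", pop_id[recs[k]]),
      ind = r$id, locus = loci, a1 = a1, a2 = a2
    )
  }
  out <- as_msat_data(dplyr::bind_rows(rows))
  attr(out, "loci") <- loci
  attr(out, "title") <- title
  out
}

#' Write a genotype table to Genepop format
#'
#' @param x A tidy genotype tibble (see [as_msat_data()]).
#' @param path Output file path; `NULL` returns the document as a character
#'   vector of lines instead of writing.
#' @param title Title line; Genepop has no comment syntax, so any provenance
#'   string belongs here.
#' @param digits Allele-code width per allele: 3 (default) or 2.
#' @return `path` invisibly, or the lines when `path` is `NULL`.
#' @export
write_genepop <- function(x, path = NULL, title = "msatabc genotype export",
                          digits = 3) {
  x <- as_msat_data(x)
  if (!digits %in% c(2, 3)) abort_msat("digits must be 2 or 3")
  arr <- genotype_arrays(x)
  fmt <- paste0("%0", digits, "d")
  maxcode <- 10^digits - 1
  lines <- c(title, arr$loci)
  for (p in seq_along(arr$pop_levels)) {
    lines <- c(lines, "pop")
    for (i in which(arr$pop == p)) {
      codes <- vapply(arr$gmats, function(m) {
        a1 <- m[1, i]; a2 <- m[2, i]
        if (!is.na(a1) && (a1 > maxcode || a2 > maxcode))
          abort_msat(sprintf("allele size %d does not fit %d-digit codes",
                             max(a1, a2), digits))
        paste0(
          if (is.na(a1)) strrep("0", digits) else sprintf(fmt, a1),
          if (is.na(a2)) strrep("0", digits) else sprintf(fmt, a2)
        )
      }, character(1))
      lines <- c(lines, paste0(arr$ind[i], " ,  ", paste(codes, collapse = " ")))
    }
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
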