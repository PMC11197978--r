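# Corpus container and readers/writers.
#
# A lit_corpus holds one row per article: an opaque document id (PMID-like),
# a 4-digit publication year, the free text analysed for topics (title and
# abstract concatenated), and a set of MeSH-like subject tags.

#' Construct a literature corpus
#'
#' @param doc_id character vector of unique document identifiers.
#' @param year integer vector of 4-digit calendar years.
#' @param text character vector of document text (title + abstract).
#' @param tags list of character vectors of subject headings; `NULL` means
#'   every document has an empty tag set.
#' @param provenance free-text note on where the records came from.
#' @return an object of class `lit_corpus` with elements `docs` (data.frame
#'   with columns doc_id, year, text), `tags` (list), and `provenance`.
#' @export
lit_corpus <- function(doc_id, year, text, tags = NULL, provenance = "") {
  doc_id <- as.character(doc_id)
  year <- as.integer(year)
  text <- as.character(text)
  if (length(doc_id) != length(year) || length(doc_id) != length(text)) {
    stop("doc_id, year and text must have equal length")
  }
  if (anyDuplicated(doc_id)) stop("doc_id values must be unique within a corpus")
  if (any(is.na(year)) || any(year < 1000L | year > 9999L)) {
    stop("year must be a 4-digit integer for every document")
  }
  txt_norm <- trimws(gsub("\\s+", " ", text))
  if (any(!nzchar(txt_norm))) stop("text must be non-empty after whitespace normalization")
  if (is.null(tags)) tags <- rep(list(character(0)), length(doc_id))
  if (length(tags) != length(doc_id)) stop("tags must have one entry per document")
  tags <- lapply(tags, function(x) unique(as.character(x[nzchar(x)])))
  structure(
    list(
      docs = data.frame(doc_id = doc_id, year = year, text = txt_norm,
                        stringsAsFactors = FALSE),
      tags = tags,
      provenance = provenance
    ),
    class = "lit_corpus"
  )
}

#' @export
print.lit_corpus <- function(x, ...) {
  yrs <- range(x$docs$year)
  cat("Literature corpus: ", nrow(x$docs), " documents, years ",
      yrs[1], "-", yrs[2], "\n", sep = "")
  ntag <- sum(lengths(x$tags))
  cat("  tags: ", ntag, " assignments over ",
      length(unique(unlist(x$tags))), " distinct headings\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus a `lit_corpus`.
#' @return integer document count.
#' @export
corpus_size <- function(corpus) nrow(corpus$docs)

# strip qualifier ("/...") and major-topic marker ("*") from a MeSH heading
.clean_mesh <- function(x) {
  x <- sub("/.*$", "", x)
  x <- gsub("*", "", x, fixed = TRUE)
  trimws(x)
}

.first_year_token <- function(dp) {
  m <- regmatches(dp, regexpr("\\b[0-9]{4}\\b", dp))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(m[1])
}

#' Read a MEDLINE flat file
#'
#' Parses MEDLINE tagged records (PMID-, DP-, TI-, AB-, MH- fields;
#' continuation lines indented with spaces are joined with a single space;
#' unknown tags are ignored). One document per record: text is the title and
#' abstract concatenated with a space; tags are the MH headings with
#' major-topic asterisks removed and subheading qualifiers (text after "/")
#' dropped; the year is the first 4-digit token of the DP field.
#'
#' Records missing a PMID or a parseable year are rejected with a message;
#' a file yielding zero valid records is an error.
#'
#' @param path path to a MEDLINE flat file.
#' @param quiet suppress per-record rejection messages.
#' @return a [lit_corpus()].
#' @export
read_medline <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # join continuation lines (leading whitespace) onto the previous field
  fields <- list()  # per record: list of c(tag, value)
  records <- list()
  cur <- list()
  last <- 0L
  flush_rec <- function() {
    if (length(cur) > 0L) records[[length(records) + 1L]] <<- cur
    cur <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush_rec(); next }
    if (grepl("^\\s", ln)) {
      if (length(cur) > 0L) {
        cur[[length(cur)]][2] <- paste(cur[[length(cur)]][2], trimws(ln))
      }
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]{2,4})\\s*-\\s?(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      cur[[length(cur) + 1L]] <- c(m[2], m[3])
    }
    # lines matching no tag outside a continuation are ignored
  }
  flush_rec()
  if (length(records) == 0L) stop("no records in ", path)

  ids <- character(0); yrs <- integer(0); txts <- character(0); tgs <- list()
  n_rej <- 0L
  for (rec in records) {
    tag <- vapply(rec, `[`, character(1), 1L)
    val <- vapply(rec, `[`, character(1), 2L)
    pmid <- val[tag == "PMID"][1]
    if (is.na(pmid) || !nzchar(trimws(pmid))) {
      n_rej <- n_rej + 1L
      if (!quiet) message("rejecting record with no PMID")
      next
    }
    dp <- val[tag == "DP"][1]
    yr <- if (is.na(dp)) NA_integer_ else .first_year_token(dp)
    if (is.na(yr)) {
      n_rej <- n_rej + 1L
      if (!quiet) message("rejecting PMID ", trimws(pmid), ": no parseable year")
      next
    }
    ti <- paste(val[tag == "TI"], collapse = " ")
    ab <- paste(val[tag == "AB"], collapse = " ")
    txt <- trimws(paste(ti, ab))
    if (!nzchar(txt)) {
      n_rej <- n_rej + 1L
      if (!quiet) message("rejecting PMID ", trimws(pmid), ": empty text")
      next
    }
    mh <- unlist(strsplit(val[tag == "MH"], ";", fixed = TRUE), use.names = FALSE)
    mh <- .clean_mesh(mh)
    mh <- mh[nzchar(mh)]
    ids <- c(ids, trimws(pmid)); yrs <- c(yrs, yr); txts <- c(txts, txt)
    tgs[[length(tgs) + 1L]] <- mh
  }
  if (length(ids) == 0L) stop("no valid records in ", path)
  lit_corpus(ids, yrs, txts, tgs, provenance = paste0("medline:", basename(path)))
}

#' Read a corpus from a delimited table
#'
#' Expects a comma- or tab-delimited file with a header. `column_map` names
#' the columns holding the id, year, title, abstract and tags; tags within a
#' cell are separated by ";". Rows whose year cell does not contain a 4-digit
#' integer are rejected with a message.
#'
#' @param path path to a CSV/TSV file.
#' @param column_map named character vector with entries `id`, `year`,
#'   `title`, `abstract`, `tags`.
#' @param quiet suppress per-row rejection messages.
#' @return a [lit_corpus()].
#' @export
read_corpus_table <- function(path,
                              column_map = c(id = "doc_id", year = "year",
                                             title = "title",
                                             abstract = "abstract",
                                             tags = "tags"),
                              quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else {
    l1 <- readLines(path, n = 1L)
    if (grepl("\t", l1)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          quote = if (sep == "\t") "" else "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character", check.names = FALSE)
  for (role in c("id", "year", "title", "abstract", "tags")) {
    col <- column_map[[role]]
    if (is.null(col) || !(col %in% names(df))) {
      stop("missing mapped column for '", role, "': ", col)
    }
  }
  yr_raw <- df[[column_map[["year"]]]]
  yr <- suppressWarnings(vapply(yr_raw, .first_year_token, integer(1),
                                USE.NAMES = FALSE))
  keep <- !is.na(yr)
  if (any(!keep) && !quiet) {
    message("rejecting ", sum(!keep), " row(s) with unparseable year")
  }
  if (!any(keep)) stop("no valid records in ", path)
  tags <- strsplit(df[[column_map[["tags"]]]][keep], ";", fixed = TRUE)
  tags <- lapply(tags, function(x) trimws(x)[nzchar(trimws(x))])
  lit_corpus(
    doc_id = df[[column_map[["id"]]]][keep],
    year = yr[keep],
    text = trimws(paste(df[[column_map[["title"]]]][keep],
                        df[[column_map[["abstract"]]]][keep])),
    tags = tags,
    provenance = paste0("table:", basename(path))
  )
}

#' Write a result table as TSV
#'
#' UTF-8, header line, newline-terminated final line; floating-point values
#' rendered with 6 significant digits.
#'
#' @param rows a data.frame (may have zero rows).
#' @param path output path.
#' @export
write_tsv_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(NULL)
}

#' Write a corpus in the tabular dialect
#'
#' Inverse of [read_corpus_table()]: columns doc_id, year, title (empty),
#' abstract (full text), tags (";"-separated). Round-tripping a corpus
#' through this writer and reader preserves every field.
#'
#' @param corpus a `lit_corpus`.
#' @param path output TSV path.
#' @export
write_corpus_table <- function(corpus, path) {
  df <- data.frame(
    doc_id = corpus$docs$doc_id,
    year = corpus$docs$year,
    title = "",
    abstract = corpus$docs$text,
    tags = vapply(corpus$tags, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write_tsv_table(df, path)
}
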