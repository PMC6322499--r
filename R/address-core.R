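#' Address text normalization
#'
#' All matchers operate on a shared canonical form of the free-text address:
#' uppercase, punctuation replaced by spaces, runs of whitespace collapsed,
#' leading/trailing whitespace stripped. The function is total (any string,
#' including the empty string, is accepted) and idempotent.
#'
#' @param x character vector of free text.
#' @return character vector of normalized uppercase strings.
#' @examples
#' normalize_text("The Elms Care Home,")   # "THE ELMS CARE HOME"
#' normalize_text("12,  high-street")      # "12 HIGH STREET"
#' @export
normalize_text <- function(x) {
  x <- toupper(as.character(x))
  x[is.na(x)] <- ""
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

#' Canonical postcode token
#'
#' Uppercases and removes all whitespace. Empty or whitespace-only input
#' yields `NA` (the MISSING sentinel), never the empty string, so downstream
#' rules can test missingness explicitly. Postcodes are treated as opaque
#' keys: no UK-grammar validation is applied.
#'
#' @param x character vector of free-text postcodes.
#' @return character vector; canonical token or `NA` when missing.
#' @examples
#' canonicalize_postcode("dd1 4hn")  # "DD14HN"
#' canonicalize_postcode("   ")      # NA
#' @export
canonicalize_postcode <- function(x) {
  x <- toupper(as.character(x))
  x[is.na(x)] <- ""
  x <- gsub("[[:space:]]+", "", x)
  x[!nzchar(x)] <- NA_character_
  x
}

#' Concatenate the address fields of a record into one normalized string
#'
#' Joins the non-empty address lines with spaces, appends the postcode when
#' present, and normalizes. This is the string operand of exact matching and
#' the token source for the Phonics and Markov scores.
#'
#' @param lines character vector of address lines for one record (1-5 lines),
#'   or a list of such vectors for several records.
#' @param postcode free-text postcode (possibly empty), recycled per record.
#' @return character vector of normalized concatenated addresses.
#' @examples
#' concat_address(c("The Elms", "Main St"), "DD1 4HN")
#' # "THE ELMS MAIN ST DD1 4HN"
#' @export
concat_address <- function(lines, postcode = "") {
  if (!is.list(lines)) lines <- list(lines)
  pc <- rep_len(as.character(postcode), length(lines))
  pc[is.na(pc)] <- ""
  body <- vapply(lines, function(ln) {
    ln <- as.character(ln)
    ln[is.na(ln)] <- ""
    paste(ln[nzchar(trimws(ln))], collapse = " ")
  }, character(1))
  full <- ifelse(nzchar(trimws(pc)), paste(body, pc), body)
  normalize_text(full)
}

#' Tokenize a normalized address string
#'
#' @param x character vector of normalized strings (see [normalize_text()]).
#' @return list of character vectors of word tokens; empty vector for empty
#'   strings.
#' @export
tokenize <- function(x) {
  out <- strsplit(normalize_text(x), " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Build the canonical form of one raw address
#'
#' Bundles normalized text, tokens, canonical postcode and per-token phonetic
#' codes, as consumed by the matchers.
#'
#' @param lines character vector of 1-5 free-text address lines.
#' @param postcode free-text postcode; may be empty.
#' @return object of class `canonical_address`: a list with `text`, `tokens`,
#'   `postcode` (`NA` when missing) and `phonetic` (data.frame from
#'   [phonetic_encode()], one row per token).
#' @export
canonical_address <- function(lines, postcode = "") {
  if (length(lines) < 1L) {
    cm_validation_error("an address must have at least one line")
  }
  pc <- canonicalize_postcode(postcode)
  body <- lines
  body[is.na(body)] <- ""
  text_body <- normalize_text(paste(body[nzchar(trimws(body))], collapse = " "))
  text <- concat_address(lines, postcode)
  tokens <- tokenize(text_body)[[1]]
  structure(
    list(text = text, tokens = tokens, postcode = pc,
         phonetic = phonetic_encode(tokens)),
    class = "canonical_address"
  )
}

#' @export
print.canonical_address <- function(x, ...) {
  cat("<canonical_address> ", x$text, "\n", sep = "")
  cat("  postcode: ", if (is.na(x$postcode)) "<missing>" else x$postcode,
      ", ", length(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

# -- population address table I/O --------------------------------------------

.population_cols <- c("record_id", "line1", "line2", "line3", "line4", "line5",
                      "postcode", "flag_code", "board", "sample")
.line_cols <- paste0("line", 1:5)

#' Read a population address table
#'
#' Columns: `record_id`, `line1`..`line5`, `postcode`, `flag_code`, `board`,
#' `sample`; header row required; UTF-8.
#'
#' @param path CSV file path.
#' @return data.frame with the canonical columns (`flag_code` integer,
#'   everything else character).
#' @export
read_population_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.population_cols, names(df))
  if (length(missing)) {
    cm_schema_error(paste0("population table is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  df <- df[.population_cols]
  if (anyDuplicated(df$record_id)) {
    cm_validation_error("duplicate record_id in population table")
  }
  df$flag_code <- suppressWarnings(as.integer(df$flag_code))
  df
}

#' Write a population address table
#' @param records data.frame in the schema of [read_population_csv()].
#' @param path output CSV path.
#' @export
write_population_csv <- function(records, path) {
  write.csv(records[.population_cols], path, row.names = FALSE, na = "")
}

# record lines as a list-of-character, shared by the matchers
record_lines <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    unlist(records[i, .line_cols], use.names = FALSE)
  })
}
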