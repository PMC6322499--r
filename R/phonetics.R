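#' Phonetic encodings: Soundex and Metaphone
#'
#' Classic American Soundex (letter + three digits) and Lawrence Philips'
#' original Metaphone, the two encodings combined by the Phonics matcher so
#' that misspelled address words still compare equal when they sound alike.
#' Both are total functions over character vectors: non-letter characters are
#' ignored, and tokens containing no letters at all (house numbers) receive a
#' sentinel code distinct from every real code (see [phonetic_encode()]).
#'
#' @param x character vector of tokens.
#' @return character vector of codes; `NA` where the input has no letters.
#' @examples
#' soundex(c("ELMS", "LODGE"))     # "E452" "L320"
#' metaphone(c("CARE", "KNIGHT"))  # "KR" "NT"
#' @name phonetics
NULL

.letters_only <- function(x) gsub("[^A-Za-z]", "", x)

#' @rdname phonetics
#' @export
soundex <- function(x) {
  vapply(toupper(.letters_only(x)), soundex1, character(1), USE.NAMES = FALSE)
}

.sdx_code <- c(
  B = "1", F = "1", P = "1", V = "1",
  C = "2", G = "2", J = "2", K = "2", Q = "2", S = "2", X = "2", Z = "2",
  D = "3", T = "3", L = "4", M = "5", N = "5", R = "6"
)

soundex1 <- function(word) {
  if (!nzchar(word)) return(NA_character_)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  out <- ch[1]
  last <- .sdx_code[ch[1]]  # code of the head letter, NA for vowels
  if (is.na(last)) last <- ""
  for (c in ch[-1]) {
    code <- .sdx_code[c]
    if (!is.na(code)) {
      if (code != last) out <- c(out, code)
      last <- code
    } else if (c != "H" && c != "W") {
      # vowels separate repeated codes; H and W do not
      last <- ""
    }
    if (length(out) == 4L) break
  }
  paste0(paste(out, collapse = ""), strrep("0", 4L - length(out)))
}

#' @rdname phonetics
#' @export
metaphone <- function(x) {
  vapply(tolower(.letters_only(x)), metaphone1, character(1), USE.NAMES = FALSE)
}

.vowels <- c("a", "e", "i", "o", "u")

metaphone1 <- function(word) {
  if (!nzchar(word)) return(NA_character_)
  s <- strsplit(word, "", fixed = TRUE)[[1]]
  # initial-pair adjustments
  first2 <- paste(s[seq_len(min(2L, length(s)))], collapse = "")
  if (first2 %in% c("kn", "gn", "pn", "wr", "ae")) s <- s[-1]
  n <- length(s)
  at <- function(i) if (i >= 1L && i <= n) s[i] else ""
  out <- character(0)
  i <- 1L
  while (i <= n) {
    c <- s[i]; nx <- at(i + 1L); nx2 <- at(i + 2L); pv <- at(i - 1L)
    if (c == nx && c != "c") { i <- i + 1L; next }  # collapse doubles, cc excepted
    add <- NULL
    if (c %in% .vowels) {
      if (i == 1L) add <- c
    } else if (c == "b") {
      if (!(i == n && pv == "m")) add <- "b"
    } else if (c == "c") {
      if ((nx == "i" && nx2 == "a") || nx == "h") { add <- "x"; i <- i + 1L }
      else if (nx %in% c("i", "e", "y")) { add <- "s"; i <- i + 1L }
      else add <- "k"
    } else if (c == "d") {
      if (nx == "g" && nx2 %in% c("i", "e", "y")) { add <- "j"; i <- i + 2L }
      else add <- "t"
    } else if (c %in% c("f", "j", "l", "m", "n", "r")) {
      add <- c
    } else if (c == "g") {
      if (nx %in% c("i", "e", "y")) add <- "j"
      else if (nx == "h" && nzchar(nx2) && !(nx2 %in% .vowels)) i <- i + 1L
      else if (nx == "n" && !nzchar(nx2)) i <- i + 1L
      else add <- "k"
    } else if (c == "h") {
      if (i == 1L || nx %in% .vowels || !(pv %in% .vowels)) add <- "h"
    } else if (c == "k") {
      if (i == 1L || pv != "c") add <- "k"
    } else if (c == "p") {
      if (nx == "h") { add <- "f"; i <- i + 1L } else add <- "p"
    } else if (c == "q") {
      add <- "k"
    } else if (c == "s") {
      if (nx == "h") { add <- "x"; i <- i + 1L }
      else if (nx == "i" && nx2 %in% c("o", "a")) { add <- "x"; i <- i + 2L }
      else add <- "s"
    } else if (c == "t") {
      if (nx == "i" && nx2 %in% c("o", "a")) add <- "x"
      else if (nx == "h") { add <- "0"; i <- i + 1L }
      else if (!(nx == "c" && nx2 == "h")) add <- "t"
    } else if (c == "v") {
      add <- "f"
    } else if (c == "w") {
      if (i == 1L && nx == "h") { add <- "w"; i <- i + 1L }
      else if (nx %in% .vowels) add <- "w"
    } else if (c == "x") {
      if (i == 1L) {
        add <- if (nx == "h" || (nx == "i" && nx2 %in% c("o", "a"))) "x" else "s"
      } else add <- c("k", "s")
    } else if (c == "y") {
      if (nx %in% .vowels) add <- "y"
    } else if (c == "z") {
      add <- "s"
    }
    if (!is.null(add)) out <- c(out, add)
    i <- i + 1L
  }
  toupper(paste(out, collapse = ""))
}

#' Encode a token as a (metaphone, soundex) pair
#'
#' Tokens with no alphabetic content (pure house numbers such as "12") carry
#' no phonetic information; they receive a sentinel code pair `#<token>` that
#' is distinct from every genuine code, so two different numbers never
#' compare phonetically equal while identical tokens still produce identical
#' pairs. Never raises.
#'
#' @param tokens character vector of (typically uppercase) word tokens.
#' @return data.frame with columns `token`, `metaphone`, `soundex`.
#' @export
phonetic_encode <- function(tokens) {
  tokens <- as.character(tokens)
  m <- metaphone(tokens)
  s <- soundex(tokens)
  sentinel <- is.na(m) | is.na(s)
  m[sentinel] <- paste0("#", tokens[sentinel])
  s[sentinel] <- paste0("#", tokens[sentinel])
  data.frame(token = tokens, metaphone = m, soundex = s,
             stringsAsFactors = FALSE)
}
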