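#' Binary index tests: institution flag, exact address, postcode
#'
#' Each matcher takes the population address table (one row per record, see
#' [read_population_csv()]) and returns one call per record. Binary calls
#' report `positive` plus the matched service id (only when positive); all
#' matchers are deterministic and total.
#'
#' @name binary_matchers
NULL

.flag_positive_codes <- c(93L, 98L)

#' @describeIn binary_matchers positive iff the record's institution flag
#'   code is 93 (residential home) or 98 (nursing home); an absent code is
#'   negative, mirroring the treatment of missing postcodes. No service is
#'   attached: the flag is carried by the register itself.
#' @param records population address data.frame.
#' @return data.frame with columns `record_id`, `method`, `positive`,
#'   `matched_service`.
#' @export
match_flag <- function(records) {
  code <- suppressWarnings(as.integer(records$flag_code))
  pos <- !is.na(code) & code %in% .flag_positive_codes
  data.frame(record_id = records$record_id, method = "flag",
             positive = pos, matched_service = NA_character_,
             stringsAsFactors = FALSE)
}

#' @describeIn binary_matchers positive iff the record's normalized
#'   concatenated address (all available fields plus postcode) equals that of
#'   an eligible service character-for-character. The first matching service
#'   (lowest service id) is reported.
#' @param registry a `care_registry`.
#' @param eligible optional precomputed vector of eligible service ids;
#'   defaults to [eligible_services()] with package defaults.
#' @export
match_exact <- function(records, registry, eligible = eligible_services(registry)) {
  svc <- registry_rows(registry, eligible)
  svc <- svc[order(svc$service_id), , drop = FALSE]
  rec_concat <- concat_address(record_lines(records), records$postcode)
  # empty addresses never match
  i <- match(rec_concat, svc$concat)
  i[!nzchar(rec_concat)] <- NA_integer_
  pos <- !is.na(i)
  data.frame(record_id = records$record_id, method = "exact",
             positive = pos,
             matched_service = ifelse(pos, svc$service_id[i], NA_character_),
             stringsAsFactors = FALSE)
}

#' @describeIn binary_matchers positive iff the record's canonical postcode
#'   (spaces removed) is non-missing and carried by at least one eligible
#'   service. Missing postcodes are negative rather than excluded, since
#'   routine data always contains records with missing postcode. Reports the
#'   lowest-id eligible service on that postcode.
#' @export
match_postcode <- function(records, registry, eligible = eligible_services(registry)) {
  svc <- registry_rows(registry, eligible)
  svc <- svc[!is.na(svc$postcode_canon), , drop = FALSE]
  svc <- svc[order(svc$service_id), , drop = FALSE]
  first_id <- tapply(svc$service_id, svc$postcode_canon,
                     function(x) sort(x)[1])
  rec_pc <- canonicalize_postcode(records$postcode)
  hit <- unname(first_id[match(rec_pc, names(first_id))])
  pos <- !is.na(rec_pc) & !is.na(hit)
  ms <- rep(NA_character_, nrow(records))
  ms[pos] <- hit[pos]
  data.frame(record_id = records$record_id, method = "postcode",
             positive = pos, matched_service = ms,
             stringsAsFactors = FALSE)
}

# -- Phonics -----------------------------------------------------------------

#' Phonics score configuration
#'
#' The Phonics score rewards phonetic overlap between the record's address
#' words and a care-home's name, plus postcode equality. Its free parameters:
#'
#' * `w_postcode`, `w_name` - nonnegative weights summing to 1 (defaults
#'   0.25 / 0.75): the contribution of an exact (space-removed) postcode
#'   match and of the quantized name-overlap fraction.
#' * `quantization_levels` - `q >= 1`; the name-overlap fraction is rounded
#'   to the nearest of `{0, 1/q, ..., 1}` (default 4), giving the score its
#'   characteristic small lattice of values.
#' * `stop_tokens` - generic name words excluded from the overlap (default
#'   CARE, HOME, NURSING, THE): they appear in almost every service name and
#'   carry no discriminating sound.
#' * `all_boards` - widen the candidate set from the record's health board to
#'   the whole registry (default `FALSE`: care homes in different regions
#'   often share similar names).
#'
#' @param w_postcode,w_name,quantization_levels,stop_tokens,all_boards see
#'   above.
#' @return object of class `phonics_config`.
#' @export
phonics_config <- function(w_postcode = 0.25, w_name = 0.75,
                           quantization_levels = 4L,
                           stop_tokens = c("CARE", "HOME", "NURSING", "THE"),
                           all_boards = FALSE) {
  if (w_postcode < 0 || w_name < 0 ||
      abs(w_postcode + w_name - 1) > 1e-8) {
    cm_config_error("phonics weights must be nonnegative and sum to 1")
  }
  if (quantization_levels < 1) {
    cm_config_error("quantization_levels must be >= 1")
  }
  structure(list(w_postcode = w_postcode, w_name = w_name,
                 quantization_levels = as.integer(quantization_levels),
                 stop_tokens = toupper(stop_tokens),
                 all_boards = isTRUE(all_boards)),
            class = "phonics_config")
}

#' Phonics score: phonetic name matching against the registry
#'
#' For each record and each eligible candidate service (by default those in
#' the record's health board), compute
#' \deqn{w_{pc}\,I(\mathrm{postcodes\ equal}) + w_{name}\,Q(f)}
#' where `f` is the fraction of the service's non-stop name tokens whose
#' Metaphone *or* Soundex code occurs among the record's phonetic token
#' codes, and `Q` rounds `f` to `q` equal levels. The score is 100 times the
#' maximum over candidates, rounded to the nearest integer; the best service
#' (ties broken by lowest service id) is reported. An empty candidate set
#' scores 0.
#'
#' @param records population address data.frame.
#' @param registry a `care_registry`.
#' @param config a [phonics_config()].
#' @param eligible optional vector of eligible service ids.
#' @return data.frame with columns `record_id`, `method`, `score`,
#'   `best_service`.
#' @export
score_phonics <- function(records, registry, config = phonics_config(),
                          eligible = eligible_services(registry)) {
  n <- nrow(records)
  out <- data.frame(record_id = records$record_id, method = "phonics",
                    score = numeric(n), best_service = NA_character_,
                    stringsAsFactors = FALSE)
  svc <- registry_rows(registry, eligible)
  if (nrow(svc) == 0L || n == 0L) return(out)
  svc <- svc[order(svc$service_id), , drop = FALSE]

  # phonetic code set per record (metaphone and soundex of every token)
  rec_tokens <- tokenize(concat_address(record_lines(records), ""))
  all_tok <- unique(unlist(rec_tokens))
  enc <- phonetic_encode(all_tok)
  rec_codes <- lapply(rec_tokens, function(t) {
    i <- match(t, enc$token)
    unique(c(enc$metaphone[i], enc$soundex[i]))
  })
  rec_pc <- canonicalize_postcode(records$postcode)
  # map code -> record indexes, for vectorized token membership
  code_long <- data.frame(
    idx = rep.int(seq_len(n), lengths(rec_codes)),
    code = unlist(rec_codes), stringsAsFactors = FALSE)
  code_index <- split(code_long$idx, code_long$code)

  q <- config$quantization_levels
  best <- numeric(n)
  best_svc <- rep(NA_character_, n)
  boards <- if (config$all_boards) "*" else records$board

  for (k in seq_len(nrow(svc))) {
    in_scope <- if (config$all_boards) rep(TRUE, n) else boards == svc$board[k]
    if (!any(in_scope)) next
    name_tok <- tokenize(svc$name[k])[[1]]
    name_tok <- setdiff(name_tok, config$stop_tokens)
    if (length(name_tok)) {
      nenc <- phonetic_encode(name_tok)
      hits <- matrix(FALSE, nrow = n, ncol = length(name_tok))
      for (j in seq_along(name_tok)) {
        ids <- unique(c(code_index[[nenc$metaphone[j]]],
                        code_index[[nenc$soundex[j]]]))
        if (length(ids)) hits[ids, j] <- TRUE
      }
      f <- rowMeans(hits)
    } else {
      f <- numeric(n)
    }
    fq <- round(f * q) / q
    pc_eq <- !is.na(rec_pc) & !is.na(svc$postcode_canon[k]) &
      rec_pc == svc$postcode_canon[k]
    val <- config$w_postcode * as.numeric(pc_eq) + config$w_name * fq
    val[!in_scope] <- -1
    better <- val > best + 1e-12 & in_scope
    # ties keep the earlier (lowest) service id because svc is id-sorted
    best_svc[better] <- svc$service_id[k]
    best[better] <- val[better]
  }
  score <- round(100 * pmax(best, 0))
  best_svc[score == 0 & best <= 0] <- NA_character_
  out$score <- score
  out$best_service <- best_svc
  out
}

#' Write method calls to CSV
#'
#' One row per (record, method); binary methods emit 0/1 in `value`, score
#' methods their 0-100 score.
#'
#' @param calls data.frame from a matcher ([match_flag()] etc. or
#'   [score_phonics()], [score_markov()]), or several rbind-ed together with
#'   a common column layout.
#' @param path output CSV path.
#' @export
write_calls_csv <- function(calls, path) {
  df <- calls
  if ("positive" %in% names(df)) {
    df$value <- as.integer(df$positive)
    df$positive <- NULL
  } else {
    df$value <- df$score
    df$score <- NULL
  }
  svc <- if ("matched_service" %in% names(df)) df$matched_service else df$best_service
  out <- data.frame(record_id = df$record_id, method = df$method,
                    value = df$value, matched_service = svc,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
}
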