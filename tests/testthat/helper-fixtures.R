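# Fixtures are built in code; no data files.

# A registry with two eligible active homes, one cancelled predecessor
# sharing the ELMS site, one sheltered-housing service and one non-older-
# people service.
tiny_registry <- function() {
  new_registry(data.frame(
    service_id = c("CS0001", "CS0002", "CS0003", "CS0004", "CS0005"),
    name = c("THE ELMS CARE HOME", "ROWAN LODGE NURSING HOME",
             "OLD ELMS NURSING HOME", "SEAFIELD COURT SHELTERED HOUSING",
             "BIRCH VIEW CARE HOME"),
    line1 = c("THE ELMS", "ROWAN LODGE", "OLD ELMS", "SEAFIELD COURT",
              "BIRCH VIEW"),
    line2 = c("12 HIGH STREET", "3 MAPLE ROAD", "12 HIGH STREET",
              "9 SHORE ROAD", "4 GLEN DRIVE"),
    line3 = c("DUNDEE", "DUNDEE", "DUNDEE", "DUNDEE", "DUNDEE"),
    postcode = c("DD1 4HN", "DD2 3XY", "DD1 4HN", "DD5 1AB", "DD3 9ZZ"),
    board = "TAYSIDE",
    status = c("active", "active", "cancelled", "active", "active"),
    service_type = c("Care Home Service", "Care Home Service",
                     "Care Home Service", "Housing Support Service",
                     "Care Home Service"),
    client_group = c("Older People", "Older People", "Older People",
                     "Older People", "Adults with Disabilities"),
    stringsAsFactors = FALSE))
}

# Population records: r1 copies the ELMS address exactly; r2 shares only its
# postcode; r3 is a private address with a flag code; r4 has no postcode.
tiny_records <- function() {
  make_records(
    lines = list(c("THE ELMS", "12 HIGH STREET", "DUNDEE"),
                 c("7 HIGH STREET", "DUNDEE"),
                 c("22 MORVEN PLACE", "DUNDEE"),
                 c("FLAT 2", "1 CARSE TERRACE", "DUNDEE")),
    postcode = c("DD1 4HN", "DD1 4HN", "DD4 6PQ", ""),
    flag_code = c(NA, NA, 93L, 7L))
}

make_records <- function(lines, postcode = "", flag_code = NA_integer_,
                         board = "TAYSIDE", sample = "test",
                         record_id = NULL) {
  n <- length(lines)
  pad <- t(vapply(lines, function(l) c(l, rep("", 5 - length(l)))[1:5],
                  character(5)))
  df <- data.frame(
    record_id = record_id %||% sprintf("r%03d", seq_len(n)),
    line1 = pad[, 1], line2 = pad[, 2], line3 = pad[, 3],
    line4 = pad[, 4], line5 = pad[, 5],
    postcode = rep_len(postcode, n),
    flag_code = rep_len(as.integer(flag_code), n),
    board = rep_len(board, n), sample = rep_len(sample, n),
    stringsAsFactors = FALSE)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force Phonics oracle: enumerate every (record, service)
# pair with the formula written out directly.
phonics_bruteforce <- function(records, registry, config = phonics_config(),
                               eligible = eligible_services(registry)) {
  svc <- registry$services[registry$services$service_id %in% eligible, ,
                           drop = FALSE]
  q <- config$quantization_levels
  out <- numeric(nrow(records))
  best <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    rec_lines <- unlist(records[i, paste0("line", 1:5)], use.names = FALSE)
    rec_tok <- tokenize(concat_address(list(rec_lines), ""))[[1]]
    renc <- phonetic_encode(rec_tok)
    rec_codes <- unique(c(renc$metaphone, renc$soundex))
    rec_pc <- canonicalize_postcode(records$postcode[i])
    best_val <- 0
    best_id <- NA_character_
    for (k in seq_len(nrow(svc))) {
      if (!config$all_boards && svc$board[k] != records$board[i]) next
      ntok <- setdiff(tokenize(svc$name[k])[[1]], config$stop_tokens)
      f <- if (length(ntok)) {
        nenc <- phonetic_encode(ntok)
        mean(nenc$metaphone %in% rec_codes | nenc$soundex %in% rec_codes)
      } else 0
      pc_eq <- !is.na(rec_pc) && !is.na(svc$postcode_canon[k]) &&
        rec_pc == svc$postcode_canon[k]
      val <- config$w_postcode * pc_eq + config$w_name * round(f * q) / q
      take <- val > best_val + 1e-12 ||
        (abs(val - best_val) <= 1e-12 && !is.na(best_id) &&
           svc$service_id[k] < best_id)
      if (take && val > 0) { best_val <- val; best_id <- svc$service_id[k] }
    }
    out[i] <- round(100 * best_val)
    best[i] <- best_id
  }
  data.frame(record_id = records$record_id, score = out,
             best_service = best, stringsAsFactors = FALSE)
}

# Exhaustive pairwise AUROC oracle.
auc_pairwise <- function(scores, truth) {
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# random small registry + records for phonics equivalence sweeps
random_phonics_instance <- function(seed) {
  set.seed(seed)
  n_svc <- sample(3:8, 1)
  reg <- generate_registry(n_svc, board = "TAYSIDE",
                           cancelled_fraction = 0.3,
                           ineligible_fraction = 0.3, seed = seed)
  cfg <- generator_config(n_records = sample(10:30, 1), n_homes = n_svc,
                          prevalence = 0.4, seed = seed + 1000L)
  smp <- generate_sample(cfg, reg)
  list(records = smp$records, registry = reg)
}
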