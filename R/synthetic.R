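#' Synthetic registry and population generator
#'
#' Emulates the statistical structure of a care-home identification study:
#' a regulator-style registry (active homes, cancelled predecessors sharing
#' a site, ineligible sheltered-housing services) and population address
#' samples in which a small fraction of records are true care-home
#' addresses. True positives copy a registry address and are then corrupted
#' with realistic noise (character typos, abbreviations, dropped lines,
#' blanked postcodes, historic predecessor names); negatives are private
#' addresses drawn from the same street-name grammar, a small share of which
#' are placed on a care-home postcode - the sole designed source of
#' postcode-match false positives. An institution flag is assigned with a
#' configurable sensitivity and false-positive rate. Everything is driven by
#' one seed.
#'
#' @name synthetic
NULL

# versioned address grammar: deliberately small so examples stay stable
.grammar <- list(
  stems = c("OAK", "ELM", "BIRCH", "ROWAN", "MAPLE", "WILLOW", "CEDAR",
            "HOLLY", "HEATHER", "THISTLE", "BRAMBLE", "ORCHARD",
            "RIVERSIDE", "HILLSIDE", "MEADOW", "PARKVIEW", "ABBEY",
            "CASTLE", "BALMORAL", "KINGSWOOD", "STRATHVIEW", "LOMOND",
            "MORVEN", "CRAIGIE", "SEAFIELD", "ASHGROVE", "FERNBANK",
            "ROSEBANK", "SPRINGFIELD", "WOODLANDS", "FAIRVIEW",
            "SUNNYBRAE", "BENVIEW", "HARBOUR", "VICTORIA", "ALBERT",
            "BALGAY", "CARSE", "DUNMORE", "INVERESK", "LETHAM",
            "MONTROSE", "NEWBURGH", "PITLOCHRY", "SCONE", "TULLOCH",
            "KINNAIRD", "CLAVERHOUSE"),
  suffixes = c("HOUSE", "LODGE", "COURT", "GRANGE", "MANOR", "VIEW"),
  kinds = c("CARE HOME", "NURSING HOME"),
  # ordinary street names, mostly disjoint from home-name stems so that a
  # private address only occasionally collides phonetically with a home
  street_stems = c("KING", "QUEEN", "MILL", "CHAPEL", "STATION", "SCHOOL",
                   "CHURCH", "BRIDGE", "MARKET", "UNION", "COMMERCIAL",
                   "ALBION", "NELSON", "WALLACE", "BRUCE", "SHORE", "DOCK",
                   "FERRY", "CANAL", "TANNERY", "WEAVERS", "BAKERS",
                   "SMITHY", "PROVOST", "BAILIE", "COLLEGE", "CATHEDRAL",
                   "PRIORY", "FRIARY", "BARRACK", "FOUNDRY", "COTTON",
                   "FLAX", "JUTE", "MARINER", "PILOT", "BEACON", "CLIFF",
                   "DEAN", "MAGDALEN"),
  street_types = c("STREET", "ROAD", "AVENUE", "PLACE", "DRIVE",
                   "TERRACE", "GARDENS", "CRESCENT"),
  towns = list(
    TAYSIDE = c("DUNDEE", "PERTH", "ARBROATH", "FORFAR", "MONIFIETH"),
    FIFE = c("KIRKCALDY", "DUNFERMLINE", "ST ANDREWS", "GLENROTHES",
             "LEVEN")),
  pc_prefix = c(TAYSIDE = "DD", FIFE = "KY"),
  # abbreviation dictionary applied by perturb_address
  abbreviations = c(HOUSE = "HSE", STREET = "ST", ROAD = "RD",
                    AVENUE = "AVE", DRIVE = "DRV", PLACE = "PL",
                    GARDENS = "GDNS", TERRACE = "TERR", COURT = "CRT",
                    NURSING = "NURS", LODGE = "LDG")
)

.board_towns <- function(board) {
  .grammar$towns[[board]] %||% c("NEWTOWN", "EASTPORT", "WESTHAVEN")
}

.board_pc_prefix <- function(board) {
  p <- .grammar$pc_prefix[board]
  if (is.na(p)) substr(paste0(board, "XX"), 1, 2) else unname(p)
}

.draw_postcode <- function(n, board) {
  prefix <- .board_pc_prefix(board)
  district <- sample(1:9, n, replace = TRUE)
  inward <- paste0(sample(0:9, n, replace = TRUE),
                   replicate(n, paste(sample(LETTERS[1:20], 2, replace = TRUE),
                                      collapse = "")))
  paste0(prefix, district, " ", inward)
}

#' Generator configuration
#'
#' All rates are per-record probabilities in `[0, 1]`; the seed fixes the
#' full output stream. Defaults are the `tayside_over65` preset (see
#' [carematch_presets()]).
#'
#' @param n_records sample size (default 5000).
#' @param prevalence care-home proportion of records.
#' @param n_homes number of active eligible homes in the generated registry.
#' @param cancelled_fraction fraction of homes given a cancelled predecessor
#'   registered at the same site under a different name.
#' @param ineligible_fraction fraction (of `n_homes`) of additional
#'   sheltered-housing services, ineligible for matching.
#' @param typo_rate,abbreviation_rate,dropped_line_rate per-positive-address
#'   perturbation probabilities.
#' @param missing_postcode_rate probability a record's postcode is blanked.
#' @param shared_postcode_rate probability a negative household sits on a
#'   care-home postcode.
#' @param historic_name_rate probability a positive is recorded under the
#'   cancelled predecessor's (historic) name, where one exists.
#' @param flag_sensitivity probability a true care-home record carries
#'   institution code 93/98.
#' @param flag_false_rate probability a non-care-home record carries code
#'   93/98.
#' @param board health-board label.
#' @param sample_label label stamped on each record.
#' @param seed integer RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_records = 5000L,
                             prevalence = 0.086,
                             n_homes = 60L,
                             cancelled_fraction = 0.2,
                             ineligible_fraction = 0.15,
                             typo_rate = 0.35,
                             abbreviation_rate = 0.30,
                             dropped_line_rate = 0.15,
                             missing_postcode_rate = 0.02,
                             shared_postcode_rate = 0.016,
                             historic_name_rate = 0.10,
                             flag_sensitivity = 0.893,
                             flag_false_rate = 0.00198,
                             board = "TAYSIDE",
                             sample_label = "tayside_over65",
                             seed = 1L) {
  cfg <- list(n_records = as.integer(n_records), prevalence = prevalence,
              n_homes = as.integer(n_homes),
              cancelled_fraction = cancelled_fraction,
              ineligible_fraction = ineligible_fraction,
              typo_rate = typo_rate, abbreviation_rate = abbreviation_rate,
              dropped_line_rate = dropped_line_rate,
              missing_postcode_rate = missing_postcode_rate,
              shared_postcode_rate = shared_postcode_rate,
              historic_name_rate = historic_name_rate,
              flag_sensitivity = flag_sensitivity,
              flag_false_rate = flag_false_rate,
              board = toupper(board), sample_label = sample_label,
              seed = as.integer(seed))
  rates <- c("prevalence", "cancelled_fraction", "ineligible_fraction",
             "typo_rate", "abbreviation_rate", "dropped_line_rate",
             "missing_postcode_rate", "shared_postcode_rate",
             "historic_name_rate", "flag_sensitivity", "flag_false_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      cm_config_error(paste0(r, " must be in [0, 1]"))
    }
  }
  if (cfg$n_records < 1L) cm_config_error("n_records must be > 0")
  if (cfg$n_homes < 1L) cm_config_error("n_homes must be >= 1")
  structure(cfg, class = "generator_config")
}

#' Study-sample presets
#'
#' Four presets mirroring the margins of a two-board, two-age-group design:
#' per-sample care-home prevalence between 4.3\% and 11.1\% of 5,000
#' records, institution-flag sensitivity between 0.558 and 0.893, and a
#' flag false-positive rate chosen so the implied flag PPV stays around
#' 0.98 (0.977-0.996 across presets) - the flag's characteristic profile of
#' high precision with variable, sometimes poor, sensitivity.
#'
#' @return named list of [generator_config()] objects with seeds unset (1).
#' @export
carematch_presets <- function() {
  list(
    fife_population = generator_config(
      prevalence = 0.043, flag_sensitivity = 0.558,
      flag_false_rate = 0.000202, board = "FIFE",
      sample_label = "fife_population"),
    tayside_population = generator_config(
      prevalence = 0.051, flag_sensitivity = 0.597,
      flag_false_rate = 0.000621, board = "TAYSIDE",
      sample_label = "tayside_population"),
    fife_over65 = generator_config(
      prevalence = 0.111, flag_sensitivity = 0.586,
      flag_false_rate = 0.000294, board = "FIFE",
      sample_label = "fife_over65"),
    tayside_over65 = generator_config(
      prevalence = 0.086, flag_sensitivity = 0.893,
      flag_false_rate = 0.00198, board = "TAYSIDE",
      sample_label = "tayside_over65")
  )
}

#' Generate a synthetic care-home registry
#'
#' Home names come from a stem-by-suffix grammar (e.g. `ROWAN LODGE CARE
#' HOME`); each home gets a distinct UK-shaped postcode and a three-line
#' site address. A fraction of homes receive a cancelled predecessor: a
#' differently named service, status `cancelled`, registered at the same
#' site address - the source of "historic name" noise. A further share of
#' ineligible sheltered-housing services is added for eligibility tests.
#'
#' @param n_homes number of active eligible care homes (`>= 1`).
#' @param board health-board label.
#' @param cancelled_fraction fraction of homes with a cancelled predecessor.
#' @param ineligible_fraction fraction of additional ineligible services.
#' @param seed integer RNG seed; identical seeds give identical registries.
#' @return a `care_registry`.
#' @export
generate_registry <- function(n_homes, board = "TAYSIDE",
                              cancelled_fraction = 0.2,
                              ineligible_fraction = 0.15, seed = 1L) {
  if (n_homes < 1) cm_validation_error("n_homes must be >= 1")
  set.seed(as.integer(seed))
  board <- toupper(board)
  n_cancelled <- round(cancelled_fraction * n_homes)
  n_inelig <- round(ineligible_fraction * n_homes)
  n_names <- n_homes + n_cancelled + n_inelig
  combos <- expand.grid(stem = .grammar$stems, suffix = .grammar$suffixes,
                        stringsAsFactors = FALSE)
  if (n_names > nrow(combos)) {
    cm_validation_error("name grammar too small for requested registry size")
  }
  pick <- combos[sample.int(nrow(combos), n_names), , drop = FALSE]
  name_core <- paste(pick$stem, pick$suffix)
  towns <- .board_towns(board)

  active_core <- name_core[seq_len(n_homes)]
  active <- data.frame(
    service_id = sprintf("CS%04d", seq_len(n_homes)),
    name = paste(active_core,
                 sample(.grammar$kinds, n_homes, replace = TRUE)),
    line1 = active_core,
    line2 = paste(sample(1:180, n_homes, replace = TRUE),
                  sample(.grammar$street_stems, n_homes, replace = TRUE),
                  sample(.grammar$street_types, n_homes, replace = TRUE)),
    line3 = sample(towns, n_homes, replace = TRUE),
    postcode = .draw_postcode(n_homes, board),
    board = board, status = "active",
    service_type = "Care Home Service", client_group = "Older People",
    stringsAsFactors = FALSE)

  services <- active
  if (n_cancelled > 0) {
    host <- sample.int(n_homes, n_cancelled)
    core <- name_core[n_homes + seq_len(n_cancelled)]
    cancelled <- data.frame(
      service_id = sprintf("CS%04d", n_homes + seq_len(n_cancelled)),
      name = paste(core, sample(.grammar$kinds, n_cancelled, replace = TRUE)),
      line1 = core,
      line2 = active$line2[host],
      line3 = active$line3[host],
      postcode = active$postcode[host],
      board = board, status = "cancelled",
      service_type = "Care Home Service", client_group = "Older People",
      stringsAsFactors = FALSE)
    services <- rbind(services, cancelled)
  }
  if (n_inelig > 0) {
    core <- name_core[n_homes + n_cancelled + seq_len(n_inelig)]
    inelig <- data.frame(
      service_id = sprintf("CS%04d", n_homes + n_cancelled + seq_len(n_inelig)),
      name = paste(core, "SHELTERED HOUSING"),
      line1 = core,
      line2 = paste(sample(1:180, n_inelig, replace = TRUE),
                    sample(.grammar$street_stems, n_inelig, replace = TRUE),
                    sample(.grammar$street_types, n_inelig, replace = TRUE)),
      line3 = sample(towns, n_inelig, replace = TRUE),
      postcode = .draw_postcode(n_inelig, board),
      board = board, status = "active",
      service_type = "Housing Support Service", client_group = "Older People",
      stringsAsFactors = FALSE)
    services <- rbind(services, inelig)
  }
  new_registry(services)
}

#' Perturb one raw address with configured noise
#'
#' Independently applies, each with its configured probability: a character
#' typo (adjacent swap, deletion or insertion at a random position of a
#' random non-empty line), an abbreviation substitution from a fixed
#' dictionary (HOUSE to HSE, STREET to ST, ...), dropping one line (when at
#' least two are present), and blanking the postcode. Uses the current RNG
#' stream; seed upstream for reproducibility.
#'
#' @param lines character vector of address lines.
#' @param postcode free-text postcode.
#' @param config a [generator_config()] (only the rate fields are used).
#' @return list with `lines`, `postcode` and `applied` (character vector
#'   naming the perturbations that fired).
#' @export
perturb_address <- function(lines, postcode, config) {
  applied <- character(0)
  lines <- as.character(lines)

  if (runif(1) < config$typo_rate) {
    cand <- which(nchar(lines) >= 2)
    if (length(cand)) {
      li <- if (length(cand) == 1L) cand else sample(cand, 1)
      before <- normalize_text(lines[li])
      # a swap of identical neighbours is a no-op; retry until the
      # normalized text genuinely changes
      for (try in 1:10) {
        ch <- strsplit(lines[li], "", fixed = TRUE)[[1]]
        pos <- sample(seq_along(ch), 1)
        op <- sample(c("swap", "delete", "insert"), 1)
        if (op == "swap" && pos < length(ch)) {
          ch[c(pos, pos + 1)] <- ch[c(pos + 1, pos)]
        } else if (op == "delete") {
          ch <- ch[-pos]
        } else {
          ch <- append(ch, sample(LETTERS, 1), after = pos)
        }
        mutated <- paste(ch, collapse = "")
        if (normalize_text(mutated) != before) {
          lines[li] <- mutated
          applied <- c(applied, "typo")
          break
        }
      }
    }
  }

  if (runif(1) < config$abbreviation_rate) {
    dict <- .grammar$abbreviations
    done <- FALSE
    for (li in sample(seq_along(lines))) {
      if (done || !nzchar(lines[li])) next
      words <- strsplit(lines[li], " ", fixed = TRUE)[[1]]
      hit <- which(toupper(words) %in% names(dict))
      if (length(hit)) {
        w <- if (length(hit) == 1L) hit else sample(hit, 1)
        words[w] <- unname(dict[toupper(words[w])])
        lines[li] <- paste(words, collapse = " ")
        applied <- c(applied, "abbreviation")
        done <- TRUE
      }
    }
  }

  if (runif(1) < config$dropped_line_rate) {
    present <- which(nzchar(trimws(lines)))
    if (length(present) >= 2L) {
      drop <- if (length(present) == 1L) present else sample(present, 1)
      lines[drop] <- ""
      applied <- c(applied, "dropped_line")
    }
  }

  if (runif(1) < config$missing_postcode_rate) {
    postcode <- ""
    applied <- c(applied, "missing_postcode")
  }

  list(lines = lines, postcode = postcode, applied = applied)
}

#' Generate one synthetic population sample
#'
#' Each record is a true care-home address with probability
#' `config$prevalence`. Positives copy the three address lines and postcode
#' of a uniformly chosen active eligible home, optionally swap in a
#' cancelled predecessor's historic name, and are then perturbed
#' ([perturb_address()]). Negatives receive grammar-generated private
#' addresses; with probability `shared_postcode_rate` a negative is placed
#' on a care-home postcode, and its postcode may independently be blanked
#' at `missing_postcode_rate`. Institution-flag codes (93/98) are assigned
#' at `flag_sensitivity` for positives and `flag_false_rate` for negatives.
#'
#' @param config a [generator_config()]; `config$seed` fixes the stream.
#' @param registry a `care_registry` with at least one active eligible
#'   service.
#' @return object of class `synthetic_sample`: list with `records`
#'   (population data.frame, see [read_population_csv()]), `truth`
#'   (`record_id`, logical `truth`), `registry`, `provenance` (per-record
#'   source service and applied perturbations) and `config`.
#' @export
generate_sample <- function(config, registry) {
  stopifnot(inherits(config, "generator_config"))
  elig <- eligible_services(registry, include_cancelled = FALSE)
  if (length(elig) == 0L) {
    cm_validation_error("registry has no active eligible services")
  }
  set.seed(config$seed)
  n <- config$n_records
  svc <- registry$services
  elig_rows <- which(svc$service_id %in% elig)
  ch_postcodes <- unique(svc$postcode[elig_rows])
  towns <- .board_towns(config$board)

  y <- runif(n) < config$prevalence
  line1 <- line2 <- line3 <- postcode <- character(n)
  source_svc <- rep(NA_character_, n)
  perturb_note <- rep("", n)

  # negatives: private households from the same street grammar
  neg <- which(!y)
  if (length(neg)) {
    # street names draw mostly from the ordinary pool; a 15% share reuses
    # home-name stems, the realistic source of phonetic false positives
    stem <- ifelse(runif(length(neg)) < 0.15,
                   sample(.grammar$stems, length(neg), replace = TRUE),
                   sample(.grammar$street_stems, length(neg), replace = TRUE))
    line1[neg] <- paste(sample(1:199, length(neg), replace = TRUE), stem,
                        sample(.grammar$street_types, length(neg), replace = TRUE))
    line2[neg] <- sample(towns, length(neg), replace = TRUE)
    line3[neg] <- ""
    shared <- runif(length(neg)) < config$shared_postcode_rate
    pc <- .draw_postcode(length(neg), config$board)
    # redraw any accidental collision with a care-home postcode so that
    # shared_postcode_rate is the sole source of postcode false positives
    while (any(clash <- !shared & pc %in% ch_postcodes)) {
      pc[clash] <- .draw_postcode(sum(clash), config$board)
    }
    if (any(shared)) {
      pc[shared] <- sample(ch_postcodes, sum(shared), replace = TRUE)
    }
    blank <- runif(length(neg)) < config$missing_postcode_rate
    pc[blank] <- ""
    postcode[neg] <- pc
    perturb_note[neg][shared] <- "shared_postcode"
  }

  # positives: copy a home's site address, then corrupt it
  pos <- which(y)
  for (i in pos) {
    k <- if (length(elig_rows) == 1L) elig_rows else sample(elig_rows, 1)
    src_lines <- c(svc$line1[k], svc$line2[k], svc$line3[k])
    src_pc <- svc$postcode[k]
    applied <- character(0)
    if (runif(1) < config$historic_name_rate) {
      pred <- which(svc$status == "cancelled" &
                      svc$line2 == svc$line2[k] &
                      svc$postcode == svc$postcode[k])
      if (length(pred)) {
        p <- if (length(pred) == 1L) pred else sample(pred, 1)
        src_lines[1] <- svc$line1[p]
        applied <- c(applied, "historic_name")
      }
    }
    pert <- perturb_address(src_lines, src_pc, config)
    line1[i] <- pert$lines[1]; line2[i] <- pert$lines[2]
    line3[i] <- pert$lines[3]; postcode[i] <- pert$postcode
    source_svc[i] <- svc$service_id[k]
    perturb_note[i] <- paste(c(applied, pert$applied), collapse = "+")
  }

  flag <- rep(NA_integer_, n)
  fire <- runif(n) < ifelse(y, config$flag_sensitivity, config$flag_false_rate)
  flag[fire] <- sample(c(93L, 98L), sum(fire), replace = TRUE)

  records <- data.frame(
    record_id = sprintf("R%06d", seq_len(n)),
    line1 = line1, line2 = line2, line3 = line3,
    line4 = "", line5 = "",
    postcode = postcode, flag_code = flag,
    board = config$board, sample = config$sample_label,
    stringsAsFactors = FALSE)
  structure(
    list(records = records,
         truth = data.frame(record_id = records$record_id, truth = y,
                            stringsAsFactors = FALSE),
         registry = registry,
         provenance = data.frame(record_id = records$record_id,
                                 source_service = source_svc,
                                 perturbations = perturb_note,
                                 stringsAsFactors = FALSE),
         config = config),
    class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("<synthetic_sample> ", nrow(x$records), " records, ",
      sum(x$truth$truth), " true care-home addresses (",
      pct1(mean(x$truth$truth)), "), board ", x$config$board,
      ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a truth label table
#' @param truth data.frame with `record_id`, `truth`.
#' @param path output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  out <- data.frame(record_id = truth$record_id,
                    truth = as.integer(truth$truth))
  write.csv(out, path, row.names = FALSE)
}

#' Read a truth label table
#' @param path CSV with columns `record_id`, `truth` (0/1).
#' @return data.frame with `record_id` (character), `truth` (logical).
#' @export
read_truth_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(record_id = "character"))
  if (!all(c("record_id", "truth") %in% names(df))) {
    cm_schema_error("truth table needs columns record_id, truth")
  }
  data.frame(record_id = as.character(df$record_id),
             truth = as.logical(as.integer(df$truth)),
             stringsAsFactors = FALSE)
}
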