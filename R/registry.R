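#' Care-home registry
#'
#' The registry emulates a regulator's list of current and previous
#' ("cancelled") registered care services. Each service carries a name, up to
#' three address lines, a postcode, a health-board label, a registration
#' status, a service type and a client group. Eligibility for matching
#' ([eligible_services()]) restricts to mandatory-registered care homes for
#' older people, excluding sheltered housing, supported accommodation and
#' extra-care housing.
#'
#' @name registry
NULL

.registry_cols <- c("service_id", "name", "line1", "line2", "line3",
                    "postcode", "board", "status", "service_type",
                    "client_group")

# Controlled vocabularies; the regulator's real ones are configurable in
# eligible_services() since they are not fixed by this package.
.default_care_home_types <- c("CARE HOME SERVICE")
.default_older_people_groups <- c("OLDER PEOPLE")

#' Build a registry object from a service table
#'
#' @param services data.frame with columns `service_id`, `name`,
#'   `line1`..`line3`, `postcode`, `board`, `status` (`active`/`cancelled`),
#'   `service_type`, `client_group`.
#' @return object of class `care_registry`: the service table plus postcode
#'   and board indexes. Services with a missing postcode are never postcode-
#'   indexed.
#' @export
new_registry <- function(services) {
  missing <- setdiff(.registry_cols, names(services))
  if (length(missing)) {
    cm_schema_error(paste0("registry is missing column(s): ",
                           paste(missing, collapse = ", ")))
  }
  services <- as.data.frame(services, stringsAsFactors = FALSE)[.registry_cols]
  for (cl in .registry_cols) services[[cl]] <- as.character(services[[cl]])
  if (anyDuplicated(services$service_id)) {
    dups <- unique(services$service_id[duplicated(services$service_id)])
    cm_validation_error(paste0("duplicate service_id: ",
                               paste(dups, collapse = ", ")))
  }
  bad <- !services$status %in% c("active", "cancelled")
  if (any(bad)) {
    cm_validation_error(paste0("status must be 'active' or 'cancelled'; got: ",
                               paste(unique(services$status[bad]), collapse = ", ")))
  }
  services$postcode_canon <- canonicalize_postcode(services$postcode)
  services$concat <- concat_address(
    record_lines3(services), services$postcode)
  idx <- !is.na(services$postcode_canon)
  structure(
    list(
      services = services,
      by_postcode = split(services$service_id[idx], services$postcode_canon[idx]),
      by_board = split(services$service_id, services$board)
    ),
    class = "care_registry"
  )
}

record_lines3 <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    unlist(df[i, c("line1", "line2", "line3")], use.names = FALSE)
  })
}

#' Load a care-home registry from CSV
#'
#' @param path CSV file with the columns listed in [new_registry()]; header
#'   row required.
#' @return a `care_registry` object.
#' @export
load_registry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  new_registry(df)
}

#' Write a registry service table to CSV
#' @param registry a `care_registry`.
#' @param path output path.
#' @export
write_registry_csv <- function(registry, path) {
  write.csv(registry$services[.registry_cols], path, row.names = FALSE, na = "")
}

#' @export
print.care_registry <- function(x, ...) {
  s <- x$services
  cat("<care_registry> ", nrow(s), " services (",
      sum(s$status == "active"), " active, ",
      sum(s$status == "cancelled"), " cancelled), ",
      length(x$by_postcode), " indexed postcodes\n", sep = "")
  invisible(x)
}

#' Service ids eligible as care-home matching targets
#'
#' A service is eligible when its `service_type` is in the care-home
#' vocabulary and its `client_group` is in the older-people vocabulary.
#' Cancelled services are included by default: historic care-home names are
#' widespread in routine address data, and a cancelled predecessor sharing a
#' site with a current home is still a care-home address. Set
#' `include_cancelled = FALSE` to restrict to active registrations.
#'
#' @param registry a `care_registry`.
#' @param include_cancelled keep cancelled services? Default `TRUE`.
#' @param care_home_types uppercase `service_type` values counted as
#'   mandatory-registered care homes.
#' @param older_people_groups uppercase `client_group` values counted as
#'   older people.
#' @return character vector of service ids (possibly empty).
#' @export
eligible_services <- function(registry,
                              include_cancelled = TRUE,
                              care_home_types = .default_care_home_types,
                              older_people_groups = .default_older_people_groups) {
  s <- registry$services
  ok <- toupper(s$service_type) %in% care_home_types &
    toupper(s$client_group) %in% older_people_groups
  if (!include_cancelled) ok <- ok & s$status == "active"
  s$service_id[ok]
}

# rows of the service table for a set of ids, in table order
registry_rows <- function(registry, ids) {
  registry$services[registry$services$service_id %in% ids, , drop = FALSE]
}
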