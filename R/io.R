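#' Column dialect for gas-exchange CSV logs
#'
#' Instrument exports and simulated logs differ only in column naming and Ci
#' units; a dialect maps both onto the package schema so one reader serves
#' all sources. A dialect can also be loaded from a YAML file with the same
#' fields ([read_dialect()]).
#'
#' @param columns Named character vector mapping schema fields
#'   (`plant_id`, `species`, `life_stage`, `treatment`, `timestamp`, `ppfd`,
#'   `a_net`, `ci`, `leaf_temp`, `co2_ref`, `pressure`) to CSV column names.
#'   Optional fields (`life_stage`, `ci`, `leaf_temp`, `co2_ref`, `pressure`)
#'   may be omitted.
#' @param ci_unit `"umol_mol"` (instrument convention; converted to Pa on
#'   read) or `"Pa"` (stored as-is).
#' @param pressure_default Atmospheric pressure in kPa used for the
#'   mole-fraction-to-Pa conversion when no pressure column is present
#'   (standard atmosphere by default; the assumption is recorded on the
#'   returned log).
#' @return A list of class `ge_dialect`.
#' @export
ge_dialect <- function(columns = NULL, ci_unit = c("umol_mol", "Pa"),
                       pressure_default = 101.325) {
  ci_unit <- match.arg(ci_unit)
  schema <- c("plant_id", "species", "life_stage", "treatment", "timestamp",
              "ppfd", "a_net", "ci", "leaf_temp", "co2_ref", "pressure")
  if (is.null(columns)) columns <- stats::setNames(schema, schema)
  stopifnot(!is.null(names(columns)), all(names(columns) %in% schema))
  structure(list(columns = columns, ci_unit = ci_unit,
                 pressure_default = pressure_default),
            class = "ge_dialect")
}

#' Read a dialect definition from a YAML file
#'
#' @param path YAML file with fields `columns` (map), `ci_unit`,
#'   `pressure_default`.
#' @return A [ge_dialect()] object.
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  ge_dialect(columns = unlist(y$columns),
             ci_unit = if (is.null(y$ci_unit)) "umol_mol" else y$ci_unit,
             pressure_default = if (is.null(y$pressure_default)) 101.325
             else y$pressure_default)
}

.ge_species <- c("Alliaria", "Maianthemum", "Trillium", "other")
.ge_treatments <- c("fenced", "unfenced")

#' Read a gas-exchange log CSV
#'
#' Reads one row per logged instrument observation, applies the dialect's
#' column map, validates row invariants (`ppfd >= 0`, `ci > 0` when present,
#' treatment/species non-missing and recognised, timestamp parseable) and
#' converts Ci from mole fraction to partial pressure when the dialect says
#' so: `ci_Pa = ci_umol_mol * pressure_kPa / 1000`, using the row's pressure
#' column when available and the dialect's default otherwise. Rows failing
#' an invariant are rejected and counted, never silently kept.
#'
#' @param path CSV file with a header row.
#' @param dialect A [ge_dialect()]; defaults to the package schema names.
#' @return A list of class `ge_log`: `records` (data frame with columns
#'   `plant_id`, `species`, `life_stage`, `treatment`, `timestamp` (POSIXct),
#'   `day_of_year`, `ppfd`, `a_net`, `ci` (Pa), `leaf_temp`, `co2_ref`,
#'   `pressure`), `n_input`, `n_rejected`, `rejections` (reason counts) and
#'   `assumed_pressure` (`TRUE` when the default pressure filled in for any
#'   converted row).
#' @export
read_gas_exchange_log <- function(path, dialect = ge_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("plant_id", "species", "treatment", "timestamp", "ppfd",
                "a_net")
  cols <- dialect$columns
  for (f in required) {
    if (!f %in% names(cols) || !cols[[f]] %in% names(raw)) {
      stop("required column missing from ", basename(path), ": ", f,
           " (mapped to '", if (f %in% names(cols)) cols[[f]] else f, "')")
    }
  }
  get <- function(f, default = NA) {
    if (f %in% names(cols) && cols[[f]] %in% names(raw)) raw[[cols[[f]]]]
    else rep(default, nrow(raw))
  }

  ts <- suppressWarnings(as.POSIXct(get("timestamp"), tz = "UTC",
                                    tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                   "%Y-%m-%d %H:%M",
                                                   "%Y-%m-%dT%H:%M:%OS",
                                                   "%Y-%m-%d")))
  rec <- data.frame(
    plant_id = as.character(get("plant_id")),
    species = as.character(get("species")),
    life_stage = as.character(get("life_stage", NA_character_)),
    treatment = as.character(get("treatment")),
    timestamp = ts,
    ppfd = suppressWarnings(as.numeric(get("ppfd"))),
    a_net = suppressWarnings(as.numeric(get("a_net"))),
    ci = suppressWarnings(as.numeric(get("ci"))),
    leaf_temp = suppressWarnings(as.numeric(get("leaf_temp"))),
    co2_ref = suppressWarnings(as.numeric(get("co2_ref"))),
    pressure = suppressWarnings(as.numeric(get("pressure"))),
    stringsAsFactors = FALSE)

  bad <- list(
    bad_timestamp = is.na(rec$timestamp),
    bad_ppfd = is.na(rec$ppfd) | rec$ppfd < 0,
    bad_a_net = is.na(rec$a_net),
    bad_ci = !is.na(rec$ci) & rec$ci <= 0,
    bad_treatment = is.na(rec$treatment) |
      !(rec$treatment %in% .ge_treatments),
    bad_species = is.na(rec$species) | rec$species == "")
  reject <- Reduce(`|`, bad)
  rejections <- vapply(bad, function(b) sum(b & !is.na(b)), integer(1))
  rec <- rec[!reject, , drop = FALSE]

  assumed <- FALSE
  if (dialect$ci_unit == "umol_mol" && any(!is.na(rec$ci))) {
    p <- rec$pressure
    assumed <- any(is.na(p) & !is.na(rec$ci))
    p[is.na(p)] <- dialect$pressure_default
    rec$ci <- rec$ci * p / 1000
  }
  rec$species[!rec$species %in% .ge_species] <- "other"
  rec$day_of_year <- as.integer(strftime(rec$timestamp, "%j", tz = "UTC"))
  rec <- rec[, c("plant_id", "species", "life_stage", "treatment",
                 "timestamp", "day_of_year", "ppfd", "a_net", "ci",
                 "leaf_temp", "co2_ref", "pressure")]
  rownames(rec) <- NULL
  structure(list(records = rec, n_input = length(reject),
                 n_rejected = sum(reject),
                 rejections = rejections[rejections > 0],
                 assumed_pressure = assumed),
            class = "ge_log")
}

#' Write gas-exchange records to CSV
#'
#' Inverse of [read_gas_exchange_log()] under the identity dialect (with
#' `ci_unit = "Pa"`); numeric fields are written with enough digits to
#' round-trip `ppfd` and `a_net` beyond 4 decimals.
#'
#' @param records Data frame of gas-exchange records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_log <- function(records, path) {
  out <- records
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  for (col in c("ppfd", "a_net", "ci", "leaf_temp", "co2_ref", "pressure")) {
    if (col %in% names(out)) out[[col]] <- format(out[[col]], digits = 10,
                                                  trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Group gas-exchange records into measurement curves
#'
#' Partitions records by plant and contiguous measurement session: within a
#' plant, a time gap longer than `session_gap_min` minutes starts a new
#' curve. Curves that fail the minimum-size invariant for their kind
#' (light-response: at least 6 distinct PPFD levels; A/Ci: at least 8
#' distinct Ci values) are flagged `below_minimum`, not dropped.
#'
#' @param records Gas-exchange record data frame (e.g. from
#'   [read_gas_exchange_log()]).
#' @param curve_kind `"light_response"`, `"aci"` or `"spot"`.
#' @param session_gap_min Gap (minutes) that splits sessions.
#' @return A list of class `ge_curves`: `records` (input plus `curve_id`)
#'   and `curves` (one row per curve: `curve_id`, `plant_id`, `curve_kind`,
#'   `n_records`, `n_levels`, `below_minimum`).
#' @export
group_into_curves <- function(records,
                              curve_kind = c("light_response", "aci", "spot"),
                              session_gap_min = 30) {
  curve_kind <- match.arg(curve_kind)
  if (nrow(records) == 0) {
    return(structure(list(records = cbind(records,
                                          curve_id = character(0)),
                          curves = data.frame()), class = "ge_curves"))
  }
  stopifnot(all(c("plant_id", "timestamp") %in% names(records)))
  records <- records[order(records$plant_id, records$timestamp), ]
  gap <- c(TRUE, diff(as.numeric(records$timestamp)) > session_gap_min * 60 |
             records$plant_id[-1] != records$plant_id[-nrow(records)])
  session <- cumsum(gap)
  records$curve_id <- sprintf("%s_%s_%03d", records$plant_id, curve_kind,
                              stats::ave(session, records$plant_id,
                                         FUN = function(s) match(s, unique(s))))
  min_levels <- c(light_response = 6L, aci = 8L, spot = 1L)[[curve_kind]]
  level_col <- if (curve_kind == "aci") "ci" else "ppfd"
  curves <- do.call(rbind, lapply(split(records, records$curve_id),
                                  function(d) {
    lv <- if (level_col %in% names(d)) {
      length(unique(d[[level_col]][!is.na(d[[level_col]])]))
    } else nrow(d)
    data.frame(curve_id = d$curve_id[1], plant_id = d$plant_id[1],
               curve_kind = curve_kind, n_records = nrow(d), n_levels = lv,
               below_minimum = lv < min_levels)
  }))
  rownames(curves) <- NULL
  rownames(records) <- NULL
  structure(list(records = records, curves = curves), class = "ge_curves")
}
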