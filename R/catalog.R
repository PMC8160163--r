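#' The fixed 52-parameter performance catalog
#'
#' Returns the vocabulary of the 52 performance parameters measured around a
#' simulated judo match: athlete profile, anthropometry and body composition,
#' inspiratory capacity, blood lactate, heart rate, rating of perceived
#' exertion (RPE), and the technical-tactical (time-motion and offensive)
#' match parameters. Correlation networks are defined on exactly these 52
#' nodes; datasets are validated against this catalog.
#'
#' Categories are \code{profile} (2), \code{physical} (13), \code{physiological}
#' (17: 7 inspiratory, 6 lactate, 4 heart-rate), \code{psychophysiological}
#' (4), and \code{technical_tactical} (16: 10 time-motion, 6 offensive).
#' The seven inspiratory measures (MIP through VP) are classed as
#' physiological capacity measures. Parameters measured once per athlete
#' (profile, anthropometric, inspiratory) are flagged
#' \code{shared_across_scenarios}: their columns must be identical in the
#' CON, IMPA15 and IMPA40 tables.
#'
#' @return A data frame with one row per parameter and columns \code{code},
#'   \code{name}, \code{category}, \code{units}, \code{shared}. Row order is
#'   the canonical column order for scenario tables.
#' @examples
#' cat52 <- default_catalog()
#' nrow(cat52)            # 52
#' table(cat52$category)
#' @export
default_catalog <- function() {
  p <- function(code, name, category, units, shared) {
    data.frame(code = code, name = name, category = category,
               units = units, shared = shared, stringsAsFactors = FALSE)
  }
  rows <- list(
    ## athletes' profile
    p("AG",      "Age",                               "profile", "years", TRUE),
    p("JPT",     "Judo practice time",                "profile", "years", TRUE),
    ## anthropometric characteristics and body composition
    p("HT",      "Height",                            "physical", "cm", TRUE),
    p("WS",      "Wingspan",                          "physical", "cm", TRUE),
    p("BM",      "Body mass",                         "physical", "kg", TRUE),
    p("TTD",     "Transverse thoracic diameter",      "physical", "mm", TRUE),
    p("ATD",     "Anteroposterior thoracic diameter", "physical", "mm", TRUE),
    p("NC",      "Neck circumference",                "physical", "cm", TRUE),
    p("AC",      "Arm circumference flexed",          "physical", "cm", TRUE),
    p("TC",      "Thorax circumference",              "physical", "cm", TRUE),
    p("WC",      "Waist circumference",               "physical", "cm", TRUE),
    p("ABC",     "Abdominal circumference",           "physical", "cm", TRUE),
    p("HC",      "Hip circumference",                 "physical", "cm", TRUE),
    p("THC",     "Thigh circumference",               "physical", "cm", TRUE),
    p("FM",      "Fat mass",                          "physical", "%", TRUE),
    ## inspiratory measures
    p("MIP",     "Maximal inspiratory pressure",      "physiological", "cmH2O", TRUE),
    p("SM",      "S-index mean",                      "physiological", "cmH2O", TRUE),
    p("SP",      "S-index peak",                      "physiological", "cmH2O", TRUE),
    p("PIFM",    "Peak inspiratory flow (mean)",      "physiological", "L/s", TRUE),
    p("PIF",     "Peak inspiratory flow (peak)",      "physiological", "L/s", TRUE),
    p("VM",      "Inspired volume (mean)",            "physiological", "L", TRUE),
    p("VP",      "Inspired volume (peak)",            "physiological", "L", TRUE),
    ## blood lactate
    p("PRELac",  "Pre-combat blood lactate",          "physiological", "mM", FALSE),
    p("POSTLac", "Post-combat blood lactate",         "physiological", "mM", FALSE),
    p("DLac",    "Delta of blood lactate",            "physiological", "mM", FALSE),
    p("LacPEAK", "Peak of blood lactate",             "physiological", "mM", FALSE),
    p("TRPLac",  "Time to reach the peak of blood lactate", "physiological", "min", FALSE),
    p("RDLac",   "Rate of decay of blood lactate",    "physiological", "%", FALSE),
    ## heart rate
    p("PREHR",   "Pre-combat heart rate",             "physiological", "bpm", FALSE),
    p("POSTHR",  "Post-combat heart rate",            "physiological", "bpm", FALSE),
    p("DHR",     "Delta of heart rate",               "physiological", "bpm", FALSE),
    p("RDHR",    "Rate of decay of heart rate",       "physiological", "%", FALSE),
    ## rating of perceived exertion
    p("PRERPE",  "Pre-combat RPE",                    "psychophysiological", "a.u.", FALSE),
    p("POSTRPE", "Post-combat RPE",                   "psychophysiological", "a.u.", FALSE),
    p("DRPE",    "Delta of RPE",                      "psychophysiological", "a.u.", FALSE),
    p("RDRPE",   "Rate of decay of RPE",              "psychophysiological", "%", FALSE),
    ## time-motion
    p("CF",      "Combat frequency",                  "technical_tactical", "a.u.", FALSE),
    p("ACT",     "Average combat time",               "technical_tactical", "s", FALSE),
    p("TPT",     "Total pause time",                  "technical_tactical", "s", FALSE),
    p("APT",     "Average pause time",                "technical_tactical", "s", FALSE),
    p("TSCT",    "Total standing combat time",        "technical_tactical", "s", FALSE),
    p("TGCT",    "Total groundwork combat time",      "technical_tactical", "s", FALSE),
    p("ASCT",    "Average standing combat time",      "technical_tactical", "s", FALSE),
    p("AGCT",    "Average groundwork combat time",    "technical_tactical", "s", FALSE),
    p("TAtt",    "Time between attacks",              "technical_tactical", "s", FALSE),
    p("E:P",     "Effort-pause ratio",                "technical_tactical", "a.u.", FALSE),
    ## offensive actions
    p("Att",     "Attacks",                           "technical_tactical", "a.u.", FALSE),
    p("EFFEC",   "Effectiveness",                     "technical_tactical", "%", FALSE),
    p("EFFIC",   "Efficiency",                        "technical_tactical", "a.u.", FALSE),
    p("IP",      "Ippon score",                       "technical_tactical", "a.u.", FALSE),
    p("WA",      "Wazari score",                      "technical_tactical", "a.u.", FALSE),
    p("SH",      "Shido penalty",                     "technical_tactical", "a.u.", FALSE)
  )
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$code))
  out
}

#' Look up one catalog parameter
#'
#' @param code Parameter code (case-sensitive), e.g. \code{"BM"}.
#' @param catalog A catalog data frame, by default \code{default_catalog()}.
#' @return A one-row data frame with the parameter definition.
#' @export
catalog_lookup <- function(code, catalog = default_catalog()) {
  i <- match(code, catalog$code)
  if (anyNA(i)) {
    stop("unknown parameter code(s): ", paste(code[is.na(i)], collapse = ", "))
  }
  catalog[i, , drop = FALSE]
}

#' Validate scenario datasets against the catalog
#'
#' Checks that each of the three scenario tables carries exactly the 52
#' catalog columns, that athlete identifiers agree in content and order, and
#' that parameters measured once per athlete (profile, anthropometric,
#' inspiratory) are numerically identical across scenarios.
#'
#' @param datasets Named list of scenario data frames; names must be
#'   \code{CON}, \code{IMPA15}, \code{IMPA40}. Each table must have an
#'   \code{athlete} column plus the parameter columns.
#' @param catalog Parameter catalog; default \code{default_catalog()}.
#' @param tol Numeric tolerance for the shared-column identity check.
#' @return A data frame of violations (zero rows when valid) with columns
#'   \code{scenario}, \code{code}, \code{type}, \code{message}.
#' @export
validate_datasets <- function(datasets, catalog = default_catalog(),
                              tol = 1e-9) {
  scen <- c("CON", "IMPA15", "IMPA40")
  viol <- list()
  add <- function(scenario, code, type, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      scenario = scenario, code = code, type = type, message = message,
      stringsAsFactors = FALSE)
  }
  if (!all(scen %in% names(datasets))) {
    for (s in setdiff(scen, names(datasets)))
      add(s, NA_character_, "missing_scenario", paste("no table for scenario", s))
    return(do.call(rbind, viol))
  }
  for (s in scen) {
    d <- datasets[[s]]
    cols <- setdiff(names(d), "athlete")
    if (!"athlete" %in% names(d))
      add(s, "athlete", "missing_column", "no athlete identifier column")
    for (code in setdiff(catalog$code, cols))
      add(s, code, "missing_column", paste0("column ", code, " absent in ", s))
    for (code in setdiff(cols, catalog$code))
      add(s, code, "extra_column", paste0("column ", code, " not in catalog (", s, ")"))
  }
  ids <- lapply(datasets[scen], function(d) d$athlete)
  for (s in scen[-1]) {
    if (!identical(as.character(ids[[s]]), as.character(ids[["CON"]])))
      add(s, NA_character_, "athlete_mismatch",
          paste0("athlete identifiers in ", s, " differ from CON"))
  }
  shared <- catalog$code[catalog$shared]
  for (code in shared) {
    if (!all(vapply(datasets[scen], function(d) code %in% names(d), logical(1))))
      next  # already reported as missing
    ref <- datasets[["CON"]][[code]]
    for (s in c("IMPA15", "IMPA40")) {
      v <- datasets[[s]][[code]]
      if (length(v) != length(ref) || any(abs(v - ref) > tol, na.rm = TRUE) ||
          any(is.na(v) != is.na(ref))) {
        bad <- which(abs(v - ref) > tol | is.na(v) != is.na(ref))
        add(s, code, "shared_divergence",
            paste0("shared column ", code, " differs from CON in ", s,
                   " (athlete row ", paste(bad, collapse = ","), ")"))
      }
    }
  }
  if (length(viol) == 0L) {
    return(data.frame(scenario = character(), code = character(),
                      type = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Write the catalog as CSV
#'
#' @param path Output file path.
#' @param catalog Catalog data frame.
#' @return The path, invisibly.
#' @export
write_catalog_csv <- function(path, catalog = default_catalog()) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}
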