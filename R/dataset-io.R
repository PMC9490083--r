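#' Construct a PKDataset from an event table
#'
#' Normalizes column types, orders events chronologically within subject
#' (doses before observations at tied times) and keeps subjects in order of
#' first appearance.
#'
#' @param events data.frame with columns ID, TIME, AMT, RATE, DV, MDV, CW,
#'   BW, GA, PNA, PMA (missing AMT/RATE/DV entries may be NA; dose rows are
#'   MDV = 1, observation rows MDV = 0)
#' @return a [PKDataset-class]
#' @examples
#' ev <- data.frame(ID = "n1", TIME = c(0, 2), AMT = c(100, NA),
#'                  RATE = c(200, NA), DV = c(NA, 55), MDV = c(1, 0),
#'                  CW = 2310, BW = 2310, GA = 35.7, PNA = 1, PMA = 35.84)
#' pkDataset(ev)
#' @export
pkDataset <- function(events) {
  miss <- setdiff(.PK_COLS, names(events))
  if (length(miss) > 0)
    stop("missing event columns: ", paste(miss, collapse = ", "))
  ev <- events[, .PK_COLS, drop = FALSE]
  ev$ID <- as.character(ev$ID)
  for (cc in setdiff(.PK_COLS, "ID")) ev[[cc]] <- as.numeric(ev[[cc]])
  ord <- order(match(ev$ID, unique(ev$ID)), ev$TIME, -ev$MDV)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  new("PKDataset", events = ev)
}

#' @rdname PKDataset-class
#' @export
setMethod("nSubjects", "PKDataset", function(object)
  length(unique(object@events$ID)))

#' @rdname PKDataset-class
#' @export
setMethod("nObservations", "PKDataset", function(object)
  sum(object@events$MDV == 0))

#' @rdname PKDataset-class
#' @export
setMethod("subjectIds", "PKDataset", function(object)
  unique(object@events$ID))

#' @export
#' @rdname covariateTable
setMethod("covariateTable", "PKDataset", function(object) {
  ev <- object@events
  first <- ev[!duplicated(ev$ID), c("ID", "CW", "BW", "GA", "PNA", "PMA")]
  rownames(first) <- NULL
  first
})

#' @rdname PKDataset-class
#' @export
setMethod("show", "PKDataset", function(object) {
  cat("PKDataset:", nSubjects(object), "subjects,",
      nObservations(object), "observations,",
      sum(object@events$MDV == 1), "dose events\n")
  if (nrow(object@events) > 0) {
    cw <- covariateTable(object)$CW
    cat(sprintf("  current weight %g-%g g (median %g)\n",
                min(cw), max(cw), stats::median(cw)))
  }
})

#' @describeIn pkDataset underlying event table
#' @param x a `PKDataset`
#' @param ... ignored
#' @export
as.data.frame.PKDataset <- function(x, ...) x@events

#' Subset a dataset by subject
#' @param x a [PKDataset-class]
#' @param i subject ids (character) or positional indices
#' @param j,drop,... ignored
#' @export
setMethod("[", "PKDataset", function(x, i, j, ..., drop = FALSE) {
  ids <- subjectIds(x)
  keep <- if (is.character(i)) i else ids[i]
  pkDataset(x@events[x@events$ID %in% keep, , drop = FALSE])
})

#' Default event-file dialect
#'
#' Column-mapping and unit configuration for the event CSV. The default is
#' the NONMEM-flavoured layout (ID, TIME, AMT, RATE, DV, MDV plus covariate
#' columns). Other layouts can be mapped by renaming entries of `columns`, or
#' by loading a YAML dialect file with [readDialect()]. Accepted unit tags:
#' concentration "mg/L" or "ug/mL" (synonyms), amount "mg", time "h", weight
#' "g", age columns "weeks"/"days".
#'
#' @param columns named list mapping internal fields to file column names
#' @param units named list of unit tags for dv, amt, time and cw
#' @param loq lower limit of quantification in mg/L; observations below it
#'   are excluded from the dataset with a warning
#' @return a dialect list
#' @export
pkDialect <- function(columns = list(), units = list(), loq = 0.5) {
  cols <- list(id = "ID", time = "TIME", amt = "AMT", rate = "RATE",
               dv = "DV", mdv = "MDV", cw = "CW", bw = "BW", ga = "GA",
               pna = "PNA", pma = "PMA")
  cols[names(columns)] <- columns
  un <- list(dv = "mg/L", amt = "mg", time = "h", cw = "g")
  un[names(units)] <- units
  .checkUnits(un)
  list(columns = cols, units = un, loq = loq)
}

.UNIT_SYNONYMS <- list(
  dv = c("mg/l", "ug/ml", "µg/ml", "mcg/ml"),
  amt = "mg", time = c("h", "hours"), cw = c("g", "grams"))

.checkUnits <- function(units) {
  for (nm in names(.UNIT_SYNONYMS)) {
    tag <- tolower(units[[nm]])
    if (!tag %in% .UNIT_SYNONYMS[[nm]])
      stop("unknown unit tag for ", nm, ": '", units[[nm]],
           "' (accepted: ", paste(.UNIT_SYNONYMS[[nm]], collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Read a dialect configuration from YAML
#' @param path YAML file with optional keys columns, units, loq
#' @return a dialect list as from [pkDialect()]
#' @export
readDialect <- function(path) {
  y <- yaml::read_yaml(path)
  pkDialect(columns = y$columns %||% list(), units = y$units %||% list(),
            loq = y$loq %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a NONMEM-style event CSV
#'
#' Rows with MDV = 1 and AMT > 0 become infusion dose events; rows with
#' MDV = 0 become concentration observations. Concentrations reported in
#' ug/ml are identical to mg/L, so no numeric conversion is applied beyond
#' the unit-tag check. Observations below the limit of quantification
#' (dialect `loq`, default 0.5 mg/L) are excluded with a warning.
#'
#' @param path CSV file path
#' @param dialect column-mapping configuration from [pkDialect()] or
#'   [readDialect()]
#' @return a validated [PKDataset-class]
#' @export
readDataset <- function(path, dialect = pkDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  cols <- dialect$columns
  need <- unlist(cols[c("id", "time", "amt", "dv", "mdv", "cw", "bw",
                        "ga", "pna", "pma")])
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ev <- data.frame(ID = as.character(raw[[cols$id]]),
                   TIME = as.numeric(raw[[cols$time]]),
                   AMT = as.numeric(raw[[cols$amt]]),
                   RATE = if (cols$rate %in% names(raw))
                     as.numeric(raw[[cols$rate]]) else NA_real_,
                   DV = as.numeric(raw[[cols$dv]]),
                   MDV = as.numeric(raw[[cols$mdv]]),
                   CW = as.numeric(raw[[cols$cw]]),
                   BW = as.numeric(raw[[cols$bw]]),
                   GA = as.numeric(raw[[cols$ga]]),
                   PNA = as.numeric(raw[[cols$pna]]),
                   PMA = as.numeric(raw[[cols$pma]]),
                   stringsAsFactors = FALSE)
  badT <- which(ev$TIME < 0)
  if (length(badT) > 0)
    stop("negative time at row(s): ", paste(head(badT, 5), collapse = ", "))
  badA <- which(ev$MDV == 1 & !(ev$AMT > 0))
  if (length(badA) > 0)
    stop("dose row without positive amount at row(s): ",
         paste(head(badA, 5), collapse = ", "))
  isObs <- ev$MDV == 0
  blq <- isObs & !is.na(ev$DV) & ev$DV < dialect$loq
  if (any(blq)) {
    warning(sum(blq), " observation(s) below the limit of quantification (",
            dialect$loq, " mg/L) excluded")
    ev <- ev[!blq, , drop = FALSE]
  }
  ds <- pkDataset(ev)
  f <- validateDataset(ds)
  if (nrow(f) > 0)
    warning("dataset has ", nrow(f), " validation finding(s); ",
            "see validateDataset()")
  ds
}

#' Write a dataset as an event CSV
#'
#' One row per event, chronological within subject, readable by
#' [readDataset()] with the default dialect. Subject ids are written
#' verbatim (UTF-8).
#'
#' @param data a [PKDataset-class]
#' @param path output CSV path
#' @export
writeDataset <- function(data, path) {
  stopifnot(is(data, "PKDataset"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(data@events, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a dataset against the domain rules
#'
#' Pure check: returns a data.frame of findings (empty when every rule
#' holds), never modifies its input and never throws for rule violations.
#' Rules: times non-negative; dose amounts, rates and implied durations
#' positive with rate x duration = amount; observed concentrations
#' non-negative; each subject has at least one dose; observations fall
#' within the treatment window (first dose to one dosing interval past the
#' last dose, taken as 12 h); CW and BW positive; PNA >= 0; PMA consistent
#' with GA + PNA/7 within one week.
#'
#' @param data a [PKDataset-class]
#' @return data.frame with columns subject, field, rule, detail
#' @export
validateDataset <- function(data) {
  stopifnot(is(data, "PKDataset"))
  ev <- data@events
  f <- list()
  add <- function(subject, field, rule, detail)
    f[[length(f) + 1]] <<- data.frame(subject = subject, field = field,
                                      rule = rule, detail = detail,
                                      stringsAsFactors = FALSE)
  for (id in unique(ev$ID)) {
    sub <- ev[ev$ID == id, , drop = FALSE]
    dose <- sub[sub$MDV == 1, , drop = FALSE]
    obs <- sub[sub$MDV == 0, , drop = FALSE]
    if (any(sub$TIME < 0))
      add(id, "TIME", "time >= 0",
          sprintf("min time %g", min(sub$TIME)))
    if (nrow(dose) == 0) {
      add(id, "AMT", ">= 1 dose event", "subject has no dose records")
    } else {
      if (any(!(dose$AMT > 0)))
        add(id, "AMT", "amount > 0", "non-positive dose amount")
      if (any(!is.na(dose$RATE) & !(dose$RATE > 0)))
        add(id, "RATE", "rate > 0", "non-positive infusion rate")
      okr <- !is.na(dose$RATE) & dose$RATE > 0 & dose$AMT > 0
      if (any(okr)) {
        dur <- dose$AMT[okr] / dose$RATE[okr]
        rel <- abs(dose$RATE[okr] * dur - dose$AMT[okr]) / dose$AMT[okr]
        if (any(rel > 1e-9))
          add(id, "RATE", "rate * duration = amount",
              sprintf("max relative error %g", max(rel)))
      }
      if (nrow(obs) > 0) {
        win <- c(min(dose$TIME), max(dose$TIME) + 12)
        out <- obs$TIME < win[1] | obs$TIME > win[2]
        if (any(out))
          add(id, "TIME", "observation within treatment window",
              sprintf("%d observation(s) outside [%g, %g] h",
                      sum(out), win[1], win[2]))
      }
    }
    if (any(!is.na(obs$DV) & obs$DV < 0))
      add(id, "DV", "concentration >= 0", "negative concentration")
    cv <- sub[1, ]
    if (!(cv$CW > 0) || !(cv$BW > 0))
      add(id, "CW", "CW, BW > 0", "non-positive weight")
    if (cv$PNA < 0) add(id, "PNA", "PNA >= 0", "negative postnatal age")
    dpma <- abs(cv$PMA - (cv$GA + cv$PNA / 7))
    if (is.finite(dpma) && dpma > 1)
      add(id, "PMA", "PMA = GA + PNA/7 within 1 week",
          sprintf("discrepancy %.2f weeks", dpma))
  }
  if (length(f) == 0)
    return(data.frame(subject = character(), field = character(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, f)
}

# Flatten a PKDataset into the per-subject list structure the C++ engine
# consumes: list(y, t, doseT, rate, dur) per subject, plus the covariate
# table. Subjects without observations are kept (empty y) so EBE conventions
# apply.
.subjectList <- function(data) {
  ev <- data@events
  ids <- unique(ev$ID)
  subj <- vector("list", length(ids))
  names(subj) <- ids
  for (k in seq_along(ids)) {
    sub <- ev[ev$ID == ids[k], , drop = FALSE]
    dose <- sub[sub$MDV == 1, , drop = FALSE]
    obs <- sub[sub$MDV == 0, , drop = FALSE]
    rate <- ifelse(is.na(dose$RATE), dose$AMT / 0.5, dose$RATE)
    subj[[k]] <- list(y = as.numeric(obs$DV), t = as.numeric(obs$TIME),
                      doseT = as.numeric(dose$TIME), rate = as.numeric(rate),
                      dur = as.numeric(dose$AMT / rate))
  }
  list(subjects = subj, cov = covariateTable(data))
}
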