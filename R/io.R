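.surveyCols <- c("species_id", "site_id", "year_index", "survey_index",
                 "capture_count", "survey_date", "herbaceous_floral_count",
                 "woody_floral_count")

#' Read long-format survey records
#'
#' Reads one row per species x site x year x survey with the capture count
#' and the per-survey covariates (day of year, herbaceous and woody floral
#' counts). Honey bees are managed rather than wild and are excluded from
#' the analysis by default via `dropSpecies`.
#'
#' @param path path to a CSV file with header columns `species_id`,
#'   `site_id`, `year_index`, `survey_index`, `capture_count`,
#'   `survey_date`, `herbaceous_floral_count`, `woody_floral_count`.
#' @param dropSpecies character vector of species codes to remove.
#' @return data.frame of survey records.
#' @export
readSurveyTable <- function(path,
                            dropSpecies = c("Apis_mellifera", "Apis mellifera")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.surveyCols, names(x))
  if (length(missing))
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "))
  x <- x[, .surveyCols]
  validateSurveyRecords(x)
  x[!(x$species_id %in% dropSpecies), , drop = FALSE]
}

#' @rdname readSurveyTable
#' @param records a survey-record data.frame.
#' @export
validateSurveyRecords <- function(records) {
  missing <- setdiff(.surveyCols, names(records))
  if (length(missing))
    stop("survey records are missing column(s): ", paste(missing, collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop(what, " in survey row(s): ",
           paste(utils::head(which(cond), 10), collapse = ", "))
  }
  bad(records$capture_count < 0, "negative capture_count")
  bad(records$herbaceous_floral_count < 0, "negative herbaceous_floral_count")
  bad(records$woody_floral_count < 0, "negative woody_floral_count")
  bad(records$year_index < 1, "year_index below 1")
  bad(records$survey_index < 1, "survey_index below 1")
  bad(records$survey_date < 1 | records$survey_date > 366,
      "survey_date outside 1..366")
  invisible(records)
}

#' @rdname readSurveyTable
#' @export
writeSurveyTable <- function(records, path) {
  utils::write.csv(records[, .surveyCols], path, row.names = FALSE)
  invisible(path)
}

#' Read the site table
#'
#' @param path CSV with columns `site_id` and `restored` (0/1).
#' @return data.frame.
#' @export
readSiteTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("site_id", "restored"), names(x))
  if (length(missing))
    stop("site table is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(x$restored %in% c(0, 1))) stop("restored must be coded 0/1")
  if (anyDuplicated(x$site_id)) stop("duplicated site_id in site table")
  x
}

#' @rdname readSiteTable
#' @param sites a site data.frame.
#' @export
writeSiteTable <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

# survey-level covariate frame: one row per conducted site x year x survey
.surveyLevel <- function(records) {
  key <- interaction(records$site_id, records$year_index,
                     records$survey_index, drop = TRUE)
  first <- !duplicated(key)
  sl <- records[first, c("site_id", "year_index", "survey_index",
                         "survey_date", "herbaceous_floral_count",
                         "woody_floral_count")]
  # covariates must agree across the species rows of one survey
  for (col in c("survey_date", "herbaceous_floral_count", "woody_floral_count")) {
    ref <- sl[[col]][match(key, key[first])]
    if (any(records[[col]] != ref))
      stop("inconsistent ", col, " within a site-year-survey")
  }
  sl
}

#' Yearly woody floral abundance per site
#'
#' For each site and year, the mean over conducted surveys of the
#' log-transformed woody floral count. `log1p` is used so that sites with
#' zero woody flowers (e.g. plain turfgrass lawns) remain defined.
#'
#' @param records survey records (see [readSurveyTable()]).
#' @param nYears number of study years the summary must cover (defaults to
#'   the largest year index present).
#' @return data.frame with columns `site_id`, `year_index`, `woody`
#'   (log scale, unstandardised).
#' @export
summarizeWoody <- function(records, nYears = max(records$year_index)) {
  validateSurveyRecords(records)
  sl <- .surveyLevel(records)
  agg <- stats::aggregate(log1p(sl$woody_floral_count),
                          by = list(site_id = sl$site_id,
                                    year_index = sl$year_index),
                          FUN = mean)
  names(agg)[3] <- "woody"
  full <- expand.grid(site_id = sort(unique(sl$site_id)),
                      year_index = seq_len(nYears),
                      stringsAsFactors = FALSE)
  hit <- interaction(full$site_id, full$year_index) %in%
    interaction(agg$site_id, agg$year_index)
  if (!all(hit)) {
    miss <- full[!hit, ]
    stop("site-year(s) with zero surveys: ",
         paste(paste(miss$site_id, miss$year_index, sep = "/y"), collapse = ", "))
  }
  agg[order(agg$site_id, agg$year_index), ]
}

#' Build the binary detection array
#'
#' Converts long-format capture counts into the detection/non-detection
#' tensor `V[i, j, k, l]` (`V = 1` iff the capture count was positive),
#' together with the survey mask and the standardised per-survey covariates
#' (day of year; `log1p` of the summed woody and herbaceous floral counts).
#' Surveys absent from the records are masked as not conducted, never
#' imputed as non-detections. Species without a single detection anywhere
#' are unidentifiable under the model and are removed; their ids are kept in
#' the `dropped` slot.
#'
#' The day-of-year covariate is standardised across all conducted surveys
#' jointly (one standardiser), keeping phenological peaks comparable across
#' years.
#'
#' @param records survey records (see [readSurveyTable()]).
#' @param speciesFilter optional character vector restricting the species
#'   set before the array is built.
#' @return a [DetectionArray-class].
#' @export
buildDetectionArray <- function(records, speciesFilter = NULL) {
  validateSurveyRecords(records)
  if (!is.null(speciesFilter))
    records <- records[records$species_id %in% speciesFilter, , drop = FALSE]
  if (!nrow(records)) stop("no survey records to build from")

  dupKey <- interaction(records$species_id, records$site_id,
                        records$year_index, records$survey_index, drop = TRUE)
  if (anyDuplicated(dupKey)) {
    d <- unique(as.character(dupKey[duplicated(dupKey)]))
    stop("duplicate (species, site, year, survey) rows: ",
         paste(utils::head(d, 5), collapse = "; "))
  }

  species <- sort(unique(records$species_id))
  sites <- sort(unique(records$site_id))
  S <- length(species); J <- length(sites)
  K <- max(records$year_index); L <- max(records$survey_index)

  sl <- .surveyLevel(records)
  mask <- array(FALSE, c(J, K, L))
  date <- array(0, c(J, K, L))
  flowers <- array(0, c(J, K, L))
  cell <- cbind(match(sl$site_id, sites), sl$year_index, sl$survey_index)
  mask[cell] <- TRUE
  # degenerate (constant) survey covariates centre to zero rather than error:
  # a single-survey fixture has no date spread to standardise over
  tolerantStd <- function(x) {
    if (length(unique(x)) < 2)
      list(values = rep(0, length(x)), standardizer = c(mean = mean(x), sd = 1))
    else standardizeCovariate(x)
  }
  dateStd <- tolerantStd(sl$survey_date)
  flRaw <- log1p(sl$woody_floral_count + sl$herbaceous_floral_count)
  flStd <- tolerantStd(flRaw)
  date[cell] <- dateStd$values
  flowers[cell] <- flStd$values

  V <- array(0L, c(S, J, K, L))
  V[cbind(match(records$species_id, species),
          match(records$site_id, sites),
          records$year_index, records$survey_index)] <-
    as.integer(records$capture_count > 0)

  det <- apply(V, 1, sum)
  dropped <- species[det == 0]
  keep <- det > 0
  V <- V[keep, , , , drop = FALSE]
  species <- species[keep]

  new("DetectionArray", V = V, mask = mask, date = date, flowers = flowers,
      species = species, sites = sites, dropped = dropped,
      standardizers = list(date = dateStd$standardizer,
                           flowers = flStd$standardizer))
}
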