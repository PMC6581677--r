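# Domain tables, CSV readers/writers, attribute derivation.
#
# A "herd_data" object is a list of five data frames:
#   individuals:  id, sex (factor CM/F/M), birth_date (Date)
#   residences:   id, location, start (Date), end (Date, NA = open)
#   compositions: composition_id, group, start_date, end_date,
#                 enclosure_change_only, members (list column),
#                 n_scans, n_agonistic
#   scans:        composition_id, scan_index, day (optional), focal_id,
#                 neighbour_id
#   events:       composition_id, date, winner_id, loser_id, behaviour

SEX_LEVELS <- c("CM", "F", "M")
BEHAVIOURS <- c("supplant", "avoidance", "aggression")

# Dates may be full ISO dates or bare years; bare years are imputed to
# July 1 (mid-year), the documented convention for year-precision records.
.parse_dates <- function(x, field, file, allow_na = FALSE) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | !nzchar(x)
  yearish <- !blank & grepl("^[0-9]{4}$", x)
  if (any(yearish))
    out[yearish] <- as.Date(paste0(x[yearish], "-07-01"))
  rest <- !blank & !yearish
  suppressWarnings(out[rest] <- as.Date(x[rest], format = "%Y-%m-%d"))
  bad <- rest & is.na(out)
  if (any(bad))
    .stop("%s: cannot parse %s as ISO date on row(s) %s", file, field,
          paste(utils::head(which(bad), 5L), collapse = ", "))
  if (!allow_na && any(blank))
    .stop("%s: missing %s on row(s) %s", file, field,
          paste(utils::head(which(blank), 5L), collapse = ", "))
  out
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stop("%s: missing required column(s): %s", file,
          paste(miss, collapse = ", "))
}

.read_chr_csv <- function(path) {
  read.csv(path, colClasses = "character", check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Load the four herd observation tables
#'
#' Reads the roster, scan log, agonistic log and composition manifest CSV
#' files and cross-validates them into a single referentially consistent
#' object: every individual referenced by a scan or agonistic event must
#' exist in the roster and belong to the named composition, residence
#' intervals must be chronological and non-overlapping, and composition
#' ids must be unique.
#'
#' File dialects (comma-separated, UTF-8, header mandatory):
#' \describe{
#'   \item{roster.csv}{`id,sex,birth_date,location,res_start,res_end` —
#'     one row per residence interval; `res_end` empty = still resident;
#'     `birth_date` may be a bare year (imputed to July 1).}
#'   \item{scans.csv}{`composition_id,scan_index,focal_id,neighbour_id`
#'     plus an optional `day` column (1-based day offset from composition
#'     start) used by the post-change exclusion window.}
#'   \item{agonistic.csv}{`composition_id,date,winner_id,loser_id,behaviour`
#'     with behaviour one of supplant/avoidance/aggression.}
#'   \item{manifest.csv}{`composition_id,group,start_date,end_date,`
#'     `enclosure_change_only,member_ids` with member ids
#'     semicolon-joined.}
#' }
#'
#' @param roster_path,scans_path,agonistic_path,manifest_path paths to the
#'   four CSV files.
#' @return A `herd_data` object (list of data frames `individuals`,
#'   `residences`, `compositions`, `scans`, `events`).  Composition scan
#'   and agonistic counts are recomputed from the logs.
#' @seealso [write_tables()] for the canonical writer (round-trip safe).
#' @export
load_tables <- function(roster_path, scans_path, agonistic_path,
                        manifest_path) {
  roster <- .read_chr_csv(roster_path)
  .require_cols(roster, c("id", "sex", "birth_date", "location",
                          "res_start", "res_end"), roster_path)
  if (!all(roster$sex %in% SEX_LEVELS))
    .stop("%s: sex must be one of %s", roster_path,
          paste(SEX_LEVELS, collapse = "/"))
  roster$birth_date <- .parse_dates(roster$birth_date, "birth_date",
                                    roster_path)
  roster$res_start <- .parse_dates(roster$res_start, "res_start", roster_path)
  roster$res_end <- .parse_dates(roster$res_end, "res_end", roster_path,
                                 allow_na = TRUE)

  individuals <- unique(roster[, c("id", "sex", "birth_date")])
  if (anyDuplicated(individuals$id))
    .stop("%s: individual(s) with inconsistent sex or birth date: %s",
          roster_path,
          paste(unique(individuals$id[duplicated(individuals$id)]),
                collapse = ", "))
  individuals$sex <- factor(individuals$sex, levels = SEX_LEVELS)
  individuals <- individuals[order(individuals$id), , drop = FALSE]
  rownames(individuals) <- NULL

  residences <- data.frame(id = roster$id, location = roster$location,
                           start = roster$res_start, end = roster$res_end,
                           stringsAsFactors = FALSE)
  residences <- residences[order(residences$id, residences$start), ,
                           drop = FALSE]
  rownames(residences) <- NULL
  .check_residences(residences, individuals, roster_path)

  manifest <- .read_chr_csv(manifest_path)
  .require_cols(manifest, c("composition_id", "group", "start_date",
                            "end_date", "enclosure_change_only",
                            "member_ids"), manifest_path)
  if (anyDuplicated(manifest$composition_id))
    .stop("%s: duplicate composition id(s): %s", manifest_path,
          paste(unique(manifest$composition_id[
            duplicated(manifest$composition_id)]), collapse = ", "))
  manifest$start_date <- .parse_dates(manifest$start_date, "start_date",
                                      manifest_path)
  manifest$end_date <- .parse_dates(manifest$end_date, "end_date",
                                    manifest_path)
  if (any(manifest$start_date >= manifest$end_date))
    .stop("%s: start_date must precede end_date", manifest_path)
  flag <- tolower(trimws(manifest$enclosure_change_only))
  if (!all(flag %in% c("true", "false", "1", "0")))
    .stop("%s: enclosure_change_only must be TRUE/FALSE", manifest_path)
  members <- lapply(strsplit(manifest$member_ids, ";", fixed = TRUE),
                    function(m) sort(trimws(m)))
  if (any(lengths(members) == 0L))
    .stop("%s: composition with empty member list", manifest_path)
  for (k in seq_along(members)) {
    unknown <- setdiff(members[[k]], individuals$id)
    if (length(unknown))
      .stop("%s: composition %s references id(s) not in roster: %s",
            manifest_path, manifest$composition_id[k],
            paste(unknown, collapse = ", "))
  }
  compositions <- data.frame(
    composition_id = manifest$composition_id, group = manifest$group,
    start_date = manifest$start_date, end_date = manifest$end_date,
    enclosure_change_only = flag %in% c("true", "1"),
    stringsAsFactors = FALSE)
  compositions$members <- members

  scans <- .read_chr_csv(scans_path)
  .require_cols(scans, c("composition_id", "scan_index", "focal_id",
                         "neighbour_id"), scans_path)
  if (nrow(scans)) {
    scans$scan_index <- as.integer(scans$scan_index)
    if ("day" %in% names(scans)) scans$day <- as.integer(scans$day)
    .check_log_ids(scans, c("focal_id", "neighbour_id"), compositions,
                   scans_path)
    bad <- scans$focal_id == scans$neighbour_id
    if (any(bad))
      .stop("%s: focal equals neighbour on row(s) %s", scans_path,
            paste(utils::head(which(bad), 5L), collapse = ", "))
  } else {
    scans <- data.frame(composition_id = character(),
                        scan_index = integer(), focal_id = character(),
                        neighbour_id = character(),
                        stringsAsFactors = FALSE)
  }

  events <- .read_chr_csv(agonistic_path)
  .require_cols(events, c("composition_id", "date", "winner_id",
                          "loser_id", "behaviour"), agonistic_path)
  if (nrow(events)) {
    events$date <- .parse_dates(events$date, "date", agonistic_path)
    if (!all(events$behaviour %in% BEHAVIOURS))
      .stop("%s: behaviour must be one of %s", agonistic_path,
            paste(BEHAVIOURS, collapse = "/"))
    .check_log_ids(events, c("winner_id", "loser_id"), compositions,
                   agonistic_path)
    bad <- events$winner_id == events$loser_id
    if (any(bad))
      .stop("%s: winner equals loser on row(s) %s", agonistic_path,
            paste(utils::head(which(bad), 5L), collapse = ", "))
  } else {
    events <- data.frame(composition_id = character(),
                         date = as.Date(character()),
                         winner_id = character(), loser_id = character(),
                         behaviour = character(), stringsAsFactors = FALSE)
  }

  compositions$n_scans <- vapply(seq_len(nrow(compositions)), function(k) {
    s <- scans[scans$composition_id == compositions$composition_id[k], ]
    length(unique(s$scan_index))
  }, integer(1))
  compositions$n_agonistic <- vapply(compositions$composition_id,
    function(cid) sum(events$composition_id == cid), integer(1),
    USE.NAMES = FALSE)

  structure(list(individuals = individuals, residences = residences,
                 compositions = compositions, scans = scans,
                 events = events),
            class = "herd_data")
}

.check_residences <- function(residences, individuals, file) {
  for (id in unique(residences$id)) {
    r <- residences[residences$id == id, ]
    ends <- r$end
    if (any(is.na(ends[-nrow(r)])))
      .stop("%s: open-ended residence interval before the last one for %s",
            file, id)
    if (any(!is.na(ends) & ends <= r$start))
      .stop("%s: residence interval with end <= start for %s", file, id)
    if (nrow(r) > 1L) {
      prev_end <- ends[-nrow(r)]
      if (any(r$start[-1L] < prev_end))
        .stop("%s: overlapping residence intervals for %s", file, id)
    }
    b <- individuals$birth_date[match(id, individuals$id)]
    if (any(r$start < b))
      .stop("%s: residence starts before birth for %s", file, id)
  }
  invisible(TRUE)
}

.check_log_ids <- function(df, id_cols, compositions, file) {
  m <- match(df$composition_id, compositions$composition_id)
  if (anyNA(m))
    .stop("%s: unknown composition id on row(s) %s", file,
          paste(utils::head(which(is.na(m)), 5L), collapse = ", "))
  for (col in id_cols) {
    ok <- mapply(function(id, k) id %in% compositions$members[[k]],
                 df[[col]], m)
    if (!all(ok))
      .stop("%s: %s not a member of its composition on row(s) %s", file,
            col, paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write herd tables to canonical CSV files
#'
#' Writes the four tables in the exact dialect [load_tables()] reads, with
#' deterministic row ordering and ISO dates, so that write -> load -> write
#' is byte-identical.
#'
#' @param herd a `herd_data` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the four files written.
#' @export
write_tables <- function(herd, dir) {
  stopifnot(inherits(herd, "herd_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

  res <- herd$residences
  ind <- herd$individuals
  roster <- data.frame(
    id = res$id,
    sex = as.character(ind$sex[match(res$id, ind$id)]),
    birth_date = fmt(ind$birth_date[match(res$id, ind$id)]),
    location = res$location,
    res_start = fmt(res$start), res_end = fmt(res$end),
    stringsAsFactors = FALSE)
  roster <- roster[order(roster$id, roster$res_start), , drop = FALSE]

  comp <- herd$compositions
  manifest <- data.frame(
    composition_id = comp$composition_id, group = comp$group,
    start_date = fmt(comp$start_date), end_date = fmt(comp$end_date),
    enclosure_change_only = ifelse(comp$enclosure_change_only,
                                   "TRUE", "FALSE"),
    member_ids = vapply(comp$members, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)

  scans <- herd$scans
  scan_cols <- c("composition_id", "scan_index",
                 if ("day" %in% names(scans)) "day",
                 "focal_id", "neighbour_id")
  scans <- scans[do.call(order, scans[c("composition_id", "scan_index",
                                        "focal_id")]),
                 scan_cols, drop = FALSE]

  ev <- herd$events
  ev_out <- data.frame(composition_id = ev$composition_id,
                       date = fmt(ev$date), winner_id = ev$winner_id,
                       loser_id = ev$loser_id, behaviour = ev$behaviour,
                       stringsAsFactors = FALSE)
  ev_out <- ev_out[do.call(order, ev_out), , drop = FALSE]

  paths <- file.path(dir, c("roster.csv", "scans.csv", "agonistic.csv",
                            "manifest.csv"))
  write.csv(roster, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(scans, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(ev_out, paths[3], row.names = FALSE, quote = FALSE)
  write.csv(manifest, paths[4], row.names = FALSE, quote = FALSE)
  invisible(setNames(paths, c("roster", "scans", "agonistic", "manifest")))
}

.shift_year <- function(d, k) {
  md <- format(d, "%m-%d")
  y <- as.integer(format(d, "%Y")) + k
  out <- as.Date(paste0(y, "-", md), format = "%Y-%m-%d")
  # Feb 29 birthdays roll to Mar 1 in non-leap years
  if (is.na(out)) out <- as.Date(paste0(y, "-03-01"))
  out
}

#' Age in years at a reference date
#'
#' Anniversary-based age: whole years completed plus the fraction of the
#' current birthday-to-birthday year elapsed, so an exact anniversary
#' gives an integer.  Year-precision birth dates are imputed to July 1
#' upstream (see [load_tables()]).
#'
#' @param birth_date,reference_date `Date` vectors (recycled).
#' @return Numeric vector of non-negative ages in years, monotone in the
#'   reference date.
#' @export
compute_age <- function(birth_date, reference_date) {
  b <- as.Date(birth_date); r <- as.Date(reference_date)
  n <- max(length(b), length(r))
  b <- rep_len(b, n); r <- rep_len(r, n)
  if (any(r < b))
    .stop("reference date precedes birth date")
  vapply(seq_len(n), function(i) {
    k <- as.integer(format(r[i], "%Y")) - as.integer(format(b[i], "%Y"))
    if (.shift_year(b[i], k) > r[i]) k <- k - 1L
    a0 <- .shift_year(b[i], k); a1 <- .shift_year(b[i], k + 1L)
    k + as.numeric(r[i] - a0) / as.numeric(a1 - a0)
  }, numeric(1))
}

# Total co-residence days of two individuals before `ref`: summed overlap
# of residence intervals at common locations.  Intervals are closed on
# start, open on end; open ends are clipped at `ref`.
.coresidence_days <- function(r1, r2, ref) {
  e1 <- ifelse(is.na(r1$end), ref, unclass(r1$end))
  e2 <- ifelse(is.na(r2$end), ref, unclass(r2$end))
  total <- 0
  for (i in seq_len(nrow(r1))) {
    for (j in seq_len(nrow(r2))) {
      if (r1$location[i] != r2$location[j]) next
      s <- max(unclass(r1$start[i]), unclass(r2$start[j]))
      e <- min(e1[i], e2[j], unclass(as.Date(ref)))
      if (e > s) total <- total + (e - s)
    }
  }
  total
}

#' Pairwise familiarity indicator matrix
#'
#' Two individuals are familiar at `ref_date` when their accumulated
#' co-residence (same location, overlapping residence intervals, counted
#' strictly before `ref_date`) exceeds `threshold_days` — "more than"
#' is strict, so exactly 90 days does not qualify.
#'
#' @param members character vector of individual ids.
#' @param ref_date the date at which familiarity is assessed (typically a
#'   composition start date).
#' @param residences residence table (`id`, `location`, `start`, `end`).
#' @param threshold_days co-residence needed, default 90 (three months).
#' @return Symmetric logical matrix with `FALSE` diagonal, dimnames =
#'   members.
#' @export
familiarity_matrix <- function(members, ref_date, residences,
                               threshold_days = 90) {
  ref_date <- as.Date(ref_date)
  n <- length(members)
  res_by_id <- lapply(members, function(id) {
    r <- residences[residences$id == id, , drop = FALSE]
    if (!nrow(r)) .stop("no residence history for individual %s", id)
    r
  })
  fam <- matrix(FALSE, n, n, dimnames = list(members, members))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- .coresidence_days(res_by_id[[i]], res_by_id[[j]], ref_date)
        fam[i, j] <- fam[j, i] <- d > threshold_days
      }
    }
  }
  fam
}

#' Familiarity counts for a composition
#'
#' For each member of a composition, counts the other members it has
#' co-resided with for more than `threshold_days` before the composition
#' start (see [familiarity_matrix()]).
#'
#' @param composition a composition id or a one-row slice of
#'   `herd$compositions`.
#' @param herd a `herd_data` object.
#' @param threshold_days default 90.
#' @return Named integer vector, one count per member.
#' @export
compute_familiarity <- function(composition, herd, threshold_days = 90) {
  comp <- .as_composition(composition, herd)
  fam <- familiarity_matrix(comp$members, comp$start_date,
                            herd$residences, threshold_days)
  rowSums(fam)
}

# Normalize a composition argument (id string or one-row data frame /
# list) into list(composition_id, members, start_date, end_date, ...).
.as_composition <- function(composition, herd = NULL) {
  if (is.character(composition) && length(composition) == 1L) {
    if (is.null(herd)) .stop("a herd_data object is needed to look up %s",
                             composition)
    k <- match(composition, herd$compositions$composition_id)
    if (is.na(k)) .stop("unknown composition id: %s", composition)
    composition <- herd$compositions[k, , drop = FALSE]
  }
  if (is.data.frame(composition)) {
    stopifnot(nrow(composition) == 1L)
    out <- as.list(composition[1L, setdiff(names(composition), "members")])
    out$members <- composition$members[[1L]]
    return(out)
  }
  stopifnot(is.list(composition), !is.null(composition$members))
  composition
}

#' @export
print.herd_data <- function(x, ...) {
  cat("herd_data:", nrow(x$individuals), "individuals,",
      nrow(x$compositions), "compositions,", nrow(x$scans), "scan records,",
      nrow(x$events), "agonistic events\n")
  invisible(x)
}
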