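# Synthetic herd generator: rosters, compositions, scan logs and
# agonistic logs with the statistical structure the analysis assumes
# (homophily in neighbour choice, a latent linear dominance hierarchy,
# transfers linking compositions).

#' Define a synthetic herd scenario
#'
#' A scenario fixes the study conditions: who exists, how compositions
#' succeed one another (transfers, enclosure changes), how many scans are
#' collected, and the data-generating parameters.  Nearest-neighbour
#' choice follows a log-linear homophily kernel (see [generate_scans()]);
#' agonistic outcomes follow a latent linear hierarchy where individual
#' i's latent score is `gamma * age + Normal(0, sigma_dom)` and i beats j
#' with probability `logistic(steepness * (score_i - score_j))`.
#'
#' The default scenario mirrors field scales for this kind of study:
#' group sizes 12-13, 300 scans per composition collected on roughly
#' weekly observation days of `scans_per_day` scans, a four-composition
#' timeline over one group (a 5-individual transfer, an enclosure-only
#' change, a single removal), and founders pre-resident together for
#' `pre_days` days so familiarity structure exists from the start.
#'
#' @param ids individual ids (default 15: 12 founders + 3 later arrivals).
#' @param sexes named character vector (`CM`/`F`/`M`) or `NULL` for the
#'   default (one bull, one castrated male, the rest females).
#' @param age_range,arrival_age_range age ranges (years) for founders and
#'   for transferred-in individuals (farmers mostly move young animals).
#' @param gamma,sigma_dom latent dominance score = `gamma * age + noise`.
#' @param beta_age,beta_rank,beta_sex,beta_fam homophily coefficients on
#'   the log scale of neighbour choice.
#' @param lambda agonistic interaction rate per dyad per day.
#' @param steepness logistic scale on latent-score differences.
#' @param n_scans scans per composition (recycled over the timeline).
#' @param scans_per_day scans collected per observation day.
#' @param timeline list of compositions, each a list with
#'   `composition_id`, `group`, `members`, `start_day`, `end_day`,
#'   `location`, `enclosure_change_only`; `NULL` for the default.
#' @param origin calendar date of day 0.
#' @param pre_days co-residence days before day 0 for founders (and for
#'   arrivals at their own rearing location).
#' @param familiarity_threshold days, for the generator's own familiarity
#'   indicator (matches the analysis default of 90).
#' @return A `herd_scenario` object.
#' @export
herd_scenario <- function(ids = sprintf("c%02d", 1:15), sexes = NULL,
                          age_range = c(1, 10), arrival_age_range = c(1, 3),
                          gamma = 1, sigma_dom = 1,
                          beta_age = 0.5, beta_rank = 0.3,
                          beta_sex = 0.5, beta_fam = 0.7,
                          lambda = 0.3, steepness = 1,
                          n_scans = 300, scans_per_day = 60,
                          timeline = NULL,
                          origin = as.Date("2015-04-14"),
                          pre_days = 180, familiarity_threshold = 90) {
  if (is.null(timeline)) {
    stopifnot(length(ids) >= 15L)
    founders <- ids[1:12]; arrivals <- ids[13:15]
    timeline <- list(
      list(composition_id = "H1", group = "herd", members = founders,
           start_day = 0L, end_day = 60L, location = "paddockA",
           enclosure_change_only = FALSE),
      list(composition_id = "H2", group = "herd",
           members = c(founders[1:10], arrivals),
           start_day = 60L, end_day = 130L, location = "paddockA",
           enclosure_change_only = FALSE),
      list(composition_id = "H3", group = "herd",
           members = c(founders[1:10], arrivals),
           start_day = 130L, end_day = 190L, location = "paddockB",
           enclosure_change_only = TRUE),
      list(composition_id = "H4", group = "herd",
           members = c(founders[2:10], arrivals),
           start_day = 190L, end_day = 250L, location = "paddockB",
           enclosure_change_only = FALSE))
  }
  used <- sort(unique(unlist(lapply(timeline, `[[`, "members"))))
  unknown <- setdiff(used, ids)
  if (length(unknown))
    .stop("timeline references unknown id(s): %s",
          paste(unknown, collapse = ", "))
  # no individual in two overlapping compositions of different groups
  for (i in seq_along(timeline)) {
    for (j in seq_along(timeline)) {
      if (i >= j) next
      a <- timeline[[i]]; b <- timeline[[j]]
      overlap <- a$start_day < b$end_day && b$start_day < a$end_day
      if (overlap && length(intersect(a$members, b$members)))
        .stop("individual(s) in two compositions at once: %s / %s",
              a$composition_id, b$composition_id)
    }
  }
  if (is.null(sexes)) {
    sexes <- setNames(rep("F", length(ids)), ids)
    sexes[ids[1L]] <- "M"; sexes[ids[2L]] <- "CM"
  }
  stopifnot(all(sexes[ids] %in% SEX_LEVELS))
  n_scans <- rep_len(as.integer(n_scans), length(timeline))
  if (any(n_scans < 1L)) .stop("n_scans must be positive")
  structure(list(ids = ids, sexes = sexes[ids], age_range = age_range,
                 arrival_age_range = arrival_age_range, gamma = gamma,
                 sigma_dom = sigma_dom, beta_age = beta_age,
                 beta_rank = beta_rank, beta_sex = beta_sex,
                 beta_fam = beta_fam, lambda = lambda,
                 steepness = steepness, n_scans = n_scans,
                 scans_per_day = scans_per_day, timeline = timeline,
                 origin = as.Date(origin), pre_days = pre_days,
                 familiarity_threshold = familiarity_threshold),
            class = "herd_scenario")
}

.day2date <- function(scenario, day) scenario$origin + day

#' Generate roster, residence histories and composition manifest
#'
#' Writes residence intervals so that the familiarity counts the analysis
#' derives from them match the scenario's intent: founders share
#' `pre_days` of co-residence before day 0; later arrivals are co-reared
#' at a separate location (familiar among themselves, strangers to the
#' residents on arrival); removed individuals move to an "away" location.
#' Ages and latent dominance scores are drawn here and attached as the
#' `"truth"` attribute.
#'
#' @param scenario a [herd_scenario()].
#' @param seed integer seed (mandatory: generation is reproducible).
#' @return A `herd_data`-shaped list (no scans/events yet) with attribute
#'   `"truth"`: data frame of id, age at day 0, sex, latent score.
#' @export
generate_timeline <- function(scenario, seed) {
  stopifnot(inherits(scenario, "herd_scenario"))
  set.seed(seed)
  tl <- scenario$timeline
  ids <- scenario$ids
  founders <- tl[[1L]]$members
  is_founder <- ids %in% founders
  ages <- numeric(length(ids))
  ages[is_founder] <- runif(sum(is_founder), scenario$age_range[1L],
                            scenario$age_range[2L])
  ages[!is_founder] <- runif(sum(!is_founder),
                             scenario$arrival_age_range[1L],
                             scenario$arrival_age_range[2L])
  score <- scenario$gamma * ages + rnorm(length(ids), 0,
                                         scenario$sigma_dom)
  truth <- data.frame(id = ids, age = ages,
                      sex = as.character(scenario$sexes),
                      score = score, stringsAsFactors = FALSE)

  birth <- scenario$origin - round(ages * 365.25)
  individuals <- data.frame(id = ids,
                            sex = factor(as.character(scenario$sexes),
                                         levels = SEX_LEVELS),
                            birth_date = birth, stringsAsFactors = FALSE)
  individuals <- individuals[order(individuals$id), , drop = FALSE]
  rownames(individuals) <- NULL

  end_of_time <- max(vapply(tl, `[[`, numeric(1), "end_day"))
  res <- list()
  for (id in ids) {
    in_comp <- which(vapply(tl, function(co) id %in% co$members,
                            logical(1)))
    segs <- list()
    if (length(in_comp)) {
      first <- tl[[in_comp[1L]]]
      pre_loc <- if (first$start_day == tl[[1L]]$start_day) first$location
                 else paste0("rearing_", first$group)
      segs[[1L]] <- list(loc = pre_loc,
                         s = tl[[1L]]$start_day - scenario$pre_days,
                         e = first$start_day)
      last_end <- first$start_day
      for (k in in_comp) {
        co <- tl[[k]]
        if (co$start_day > last_end)
          segs[[length(segs) + 1L]] <- list(loc = "away", s = last_end,
                                            e = co$start_day)
        segs[[length(segs) + 1L]] <- list(loc = co$location,
                                          s = co$start_day, e = co$end_day)
        last_end <- co$end_day
      }
      if (last_end < end_of_time)
        segs[[length(segs) + 1L]] <- list(loc = "away", s = last_end,
                                          e = NA_real_)
      else segs[[length(segs)]]$e <- NA_real_
    } else {
      segs[[1L]] <- list(loc = "away",
                         s = tl[[1L]]$start_day - scenario$pre_days,
                         e = NA_real_)
    }
    # merge consecutive same-location segments
    merged <- list(segs[[1L]])
    for (sg in segs[-1L]) {
      lastm <- merged[[length(merged)]]
      if (identical(sg$loc, lastm$loc)) {
        merged[[length(merged)]]$e <- sg$e
      } else merged[[length(merged) + 1L]] <- sg
    }
    res[[id]] <- data.frame(
      id = id,
      location = vapply(merged, `[[`, "", "loc"),
      start = .day2date(scenario, vapply(merged, `[[`, numeric(1), "s")),
      end = .day2date(scenario,
                      vapply(merged, function(m) m$e %||% NA_real_,
                             numeric(1))),
      stringsAsFactors = FALSE)
  }
  residences <- do.call(rbind, res)
  residences <- residences[order(residences$id, residences$start), ,
                           drop = FALSE]
  rownames(residences) <- NULL

  compositions <- data.frame(
    composition_id = vapply(tl, `[[`, "", "composition_id"),
    group = vapply(tl, `[[`, "", "group"),
    start_date = .day2date(scenario,
                           vapply(tl, `[[`, numeric(1), "start_day")),
    end_date = .day2date(scenario, vapply(tl, `[[`, numeric(1), "end_day")),
    enclosure_change_only = vapply(tl, `[[`, logical(1),
                                   "enclosure_change_only"),
    stringsAsFactors = FALSE)
  compositions$members <- lapply(tl, function(co) sort(co$members))
  compositions$n_scans <- 0L
  compositions$n_agonistic <- 0L

  skeleton <- structure(list(individuals = individuals,
                             residences = residences,
                             compositions = compositions,
                             scans = NULL, events = NULL),
                        class = "herd_data")
  attr(skeleton, "truth") <- truth
  skeleton
}

# homophily kernel weights for one composition; exact choice
# probabilities are these rows renormalized without the focal
.neighbour_weights <- function(scenario, skeleton, comp_idx) {
  co <- scenario$timeline[[comp_idx]]
  members <- sort(co$members)
  n <- length(members)
  if (n < 2L) .stop("singleton composition %s cannot produce scans",
                    co$composition_id)
  truth <- attr(skeleton, "truth")
  start_date <- .day2date(scenario, co$start_day)
  ind <- skeleton$individuals
  age <- compute_age(ind$birth_date[match(members, ind$id)], start_date)
  sc <- truth$score[match(members, truth$id)]
  lrank <- rank(-sc, ties.method = "first")
  sex <- truth$sex[match(members, truth$id)]
  fam <- familiarity_matrix(members, start_date, skeleton$residences,
                            scenario$familiarity_threshold)
  W <- exp(-scenario$beta_age * abs(outer(age, age, `-`)) -
           scenario$beta_rank * abs(outer(lrank, lrank, `-`)) +
           scenario$beta_sex * outer(sex, sex, `==`) +
           scenario$beta_fam * fam)
  diag(W) <- 0
  dimnames(W) <- list(members, members)
  W
}

#' Generate the scan log of a scenario
#'
#' For every scan and every focal individual, the nearest neighbour is
#' drawn from the other composition members with probability proportional
#' to `exp(-beta_age*|age_i - age_j| - beta_rank*|rank_i - rank_j| +
#' beta_sex*[same sex] + beta_fam*[familiar])`, where rank is the rank of
#' the latent dominance score (ground truth, not the estimated one).
#' Neighbour draws are independent across focals within a scan; the
#' association builder symmetrizes anyway.  Scans are dated: observation
#' days of `scans_per_day` scans are spread evenly over each
#' composition's duration, and the `day` column drives the post-change
#' exclusion window downstream.
#'
#' @param scenario a [herd_scenario()].
#' @param skeleton output of [generate_timeline()].
#' @param seed integer seed.
#' @return Scan log data frame (`composition_id`, `scan_index`, `day`,
#'   `focal_id`, `neighbour_id`).
#' @export
generate_scans <- function(scenario, skeleton, seed) {
  set.seed(seed)
  out <- vector("list", length(scenario$timeline))
  for (t in seq_along(scenario$timeline)) {
    co <- scenario$timeline[[t]]
    members <- sort(co$members)
    n <- length(members)
    W <- .neighbour_weights(scenario, skeleton, t)
    ns <- scenario$n_scans[t]
    dur <- co$end_day - co$start_day
    n_days <- max(1L, ceiling(ns / scenario$scans_per_day))
    obs_days <- unique(pmax(1L, round(seq(1, dur, length.out = n_days))))
    day_of <- rep(obs_days, each = ceiling(ns / length(obs_days)))[1:ns]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- sample(members[-i], ns, replace = TRUE, prob = W[i, -i])
      rows[[i]] <- data.frame(composition_id = co$composition_id,
                              scan_index = seq_len(ns), day = day_of,
                              focal_id = members[i], neighbour_id = nb,
                              stringsAsFactors = FALSE)
    }
    out[[t]] <- do.call(rbind, rows)
  }
  scans <- do.call(rbind, out)
  scans <- scans[order(scans$composition_id, scans$scan_index,
                       scans$focal_id), , drop = FALSE]
  rownames(scans) <- NULL
  scans
}

#' Generate the agonistic event log of a scenario
#'
#' Each dyad of a composition interacts `Poisson(lambda * days)` times;
#' individual i wins each interaction against j with probability
#' `logistic(steepness * (score_i - score_j))`.  Behaviour categories
#' (supplant, avoidance, aggression) are drawn uniformly: the analysis
#' weights them equally.
#'
#' @inheritParams generate_scans
#' @return Agonistic event data frame (`composition_id`, `date`,
#'   `winner_id`, `loser_id`, `behaviour`).
#' @export
generate_agonistic <- function(scenario, skeleton, seed) {
  set.seed(seed)
  truth <- attr(skeleton, "truth")
  out <- list()
  for (t in seq_along(scenario$timeline)) {
    co <- scenario$timeline[[t]]
    members <- sort(co$members)
    n <- length(members)
    sc <- truth$score[match(members, truth$id)]
    dur <- co$end_day - co$start_day
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        n_int <- rpois(1L, scenario$lambda * dur)
        if (n_int == 0L) next
        p_i <- stats::plogis(scenario$steepness * (sc[i] - sc[j]))
        i_wins <- stats::rbinom(n_int, 1L, p_i) == 1L
        days <- sample.int(dur, n_int, replace = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          composition_id = co$composition_id,
          date = .day2date(scenario, co$start_day + days - 1L),
          winner_id = ifelse(i_wins, members[i], members[j]),
          loser_id = ifelse(i_wins, members[j], members[i]),
          behaviour = sample(BEHAVIOURS, n_int, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(composition_id = character(),
                      date = as.Date(character()),
                      winner_id = character(), loser_id = character(),
                      behaviour = character(), stringsAsFactors = FALSE))
  events <- do.call(rbind, out)
  events <- events[order(events$composition_id, events$date,
                         events$winner_id, events$loser_id), ,
                   drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Generate a complete synthetic herd data set
#'
#' Chains [generate_timeline()], [generate_scans()] and
#' [generate_agonistic()] (with seeds `seed`, `seed + 1`, `seed + 2`)
#' into a `herd_data` object that passes [load_tables()]'s referential
#' checks, with the generator's ground truth attached as the `"truth"`
#' attribute.
#'
#' @inheritParams generate_timeline
#' @return A `herd_data` object.
#' @export
generate_herd <- function(scenario, seed) {
  skeleton <- generate_timeline(scenario, seed)
  scans <- generate_scans(scenario, skeleton, seed + 1L)
  events <- generate_agonistic(scenario, skeleton, seed + 2L)
  herd <- skeleton
  herd$scans <- scans
  herd$events <- events
  herd$compositions$n_scans <- vapply(
    herd$compositions$composition_id, function(cid)
      length(unique(scans$scan_index[scans$composition_id == cid])),
    integer(1), USE.NAMES = FALSE)
  herd$compositions$n_agonistic <- vapply(
    herd$compositions$composition_id, function(cid)
      sum(events$composition_id == cid), integer(1), USE.NAMES = FALSE)
  herd
}
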