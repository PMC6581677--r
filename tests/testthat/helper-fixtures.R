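# Small in-code fixtures shared across test files.

# minimal five-individual herd with staggered arrivals, one transfer
make_small_herd <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  roster <- data.frame(
    id = c("a", "b", "c", "d", "e", "e"),
    sex = c("F", "F", "M", "CM", "F", "F"),
    birth_date = c("2010-06-01", "2011", "2009-03-15", "2008-01-01",
                   "2013-02-10", "2013-02-10"),
    location = c("north", "north", "north", "north", "barn", "north"),
    res_start = c("2014-01-01", "2014-03-01", "2014-01-01", "2014-06-15",
                  "2014-01-01", "2015-03-01"),
    res_end = c("", "", "", "", "2015-03-01", ""),
    stringsAsFactors = FALSE)
  manifest <- data.frame(
    composition_id = c("N1", "N2"), group = "north",
    start_date = c("2015-01-01", "2015-03-01"),
    end_date = c("2015-03-01", "2015-06-01"),
    enclosure_change_only = c("FALSE", "FALSE"),
    member_ids = c("a;b;c;d", "a;b;c;d;e"), stringsAsFactors = FALSE)
  scans <- data.frame(
    composition_id = c("N1", "N1", "N1", "N2", "N2", "N2"),
    scan_index = c(1L, 1L, 2L, 1L, 1L, 2L),
    day = c(10L, 10L, 20L, 15L, 15L, 30L),
    focal_id = c("a", "b", "c", "a", "e", "d"),
    neighbour_id = c("b", "a", "d", "e", "a", "c"),
    stringsAsFactors = FALSE)
  agonistic <- data.frame(
    composition_id = c("N1", "N1", "N2"),
    date = c("2015-01-20", "2015-02-01", "2015-04-01"),
    winner_id = c("c", "c", "d"), loser_id = c("a", "b", "e"),
    behaviour = c("supplant", "aggression", "avoidance"),
    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("roster.csv", "scans.csv", "agonistic.csv",
                            "manifest.csv"))
  write.csv(roster, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(scans, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(agonistic, paths[3], row.names = FALSE, quote = FALSE)
  write.csv(manifest, paths[4], row.names = FALSE, quote = FALSE)
  list(dir = dir, paths = setNames(as.list(paths),
                                   c("roster", "scans", "agonistic",
                                     "manifest")))
}

# symmetric random association-like matrix with zero diagonal
random_sym_matrix <- function(n, max_count = 20, ids = letters[seq_len(n)]) {
  m <- matrix(sample.int(max_count + 1L, n * n, replace = TRUE) - 1L, n, n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

# a tiny quick scenario for pipeline-level tests (two compositions)
quick_scenario <- function(n_scans = 120) {
  ids <- sprintf("q%02d", 1:10)
  timeline <- list(
    list(composition_id = "Q1", group = "g", members = ids[1:8],
         start_day = 0L, end_day = 40L, location = "padA",
         enclosure_change_only = FALSE),
    list(composition_id = "Q2", group = "g",
         members = c(ids[1:5], ids[9:10]), start_day = 40L, end_day = 80L,
         location = "padA", enclosure_change_only = FALSE))
  herd_scenario(ids = ids, timeline = timeline, n_scans = n_scans,
                scans_per_day = 40)
}
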