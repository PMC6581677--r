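test_that("the default scenario is internally consistent and loader-valid", {
  sc <- herd_scenario()
  herd <- generate_herd(sc, 101)
  expect_s3_class(herd, "herd_data")
  # generator output passes the full referential-integrity loader
  dir <- withr::local_tempdir()
  p <- write_tables(herd, dir)
  reloaded <- load_tables(p["roster"], p["scans"], p["agonistic"],
                          p["manifest"])
  expect_equal(reloaded$compositions$members, herd$compositions$members)
  expect_equal(nrow(reloaded$scans), nrow(herd$scans))
})

test_that("generation is byte-identical under a fixed seed", {
  sc <- quick_scenario()
  h1 <- generate_herd(sc, 7)
  h2 <- generate_herd(sc, 7)
  expect_identical(h1$scans, h2$scans)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$residences, h2$residences)
  h3 <- generate_herd(sc, 8)
  expect_false(identical(h1$scans, h3$scans))
})

test_that("with all homophily coefficients zero, neighbour choice is uniform", {
  ids <- sprintf("u%02d", 1:6)
  tl <- list(list(composition_id = "U1", group = "g", members = ids,
                  start_day = 0L, end_day = 50L, location = "p",
                  enclosure_change_only = FALSE))
  sc <- herd_scenario(ids = ids, timeline = tl, beta_age = 0,
                      beta_rank = 0, beta_sex = 0, beta_fam = 0,
                      n_scans = 900, scans_per_day = 100)
  herd <- generate_herd(sc, 11)
  # each directed designation is uniform over the 5 partners: each dyad's
  # symmetrized expected count is 2 * n_scans / (N - 1)
  a <- build_association_matrix(herd$scans, "U1", exclusion_days = 0,
                                herd = herd)
  n_scans <- 900
  expected <- 2 * n_scans / 5
  sd3 <- 3 * sqrt(2 * n_scans * (1 / 5) * (4 / 5))
  off <- a$counts[upper.tri(a$counts)]
  expect_true(all(abs(off - expected) <= sd3))
})

test_that("age homophily shifts associations toward the same age cluster", {
  # two age clusters; with beta_age = 2 the between-cluster choice
  # probability is tiny and computable exactly from the kernel
  ids <- sprintf("v%02d", 1:6)
  tl <- list(list(composition_id = "V1", group = "g", members = ids,
                  start_day = 0L, end_day = 50L, location = "p",
                  enclosure_change_only = FALSE))
  sc <- herd_scenario(ids = ids, timeline = tl, beta_age = 2,
                      beta_rank = 0, beta_sex = 0, beta_fam = 0,
                      n_scans = 600, scans_per_day = 100)
  skel <- generate_timeline(sc, 12)
  truth <- attr(skel, "truth")
  # overwrite ages into two tight clusters with a 6-year gap
  truth$age <- rep(c(2, 8), each = 3)
  truth$score <- truth$age
  attr(skel, "truth") <- truth
  skel$individuals$birth_date <- sc$origin - round(365.25 *
    truth$age[match(skel$individuals$id, truth$id)])
  scans <- generate_scans(sc, skel, 13)
  herd <- skel; herd$scans <- scans
  herd$events <- data.frame(composition_id = character(),
                            date = as.Date(character()),
                            winner_id = character(),
                            loser_id = character(),
                            behaviour = character())
  a <- build_association_matrix(scans, "V1", exclusion_days = 0,
                                herd = herd)
  same <- outer(truth$age, truth$age, `==`)
  dimnames(same) <- list(truth$id, truth$id)
  within_share <- sum(a$counts[same]) / sum(a$counts)
  # exact multinomial share for one focal: 2 partners at weight e^0 vs
  # 3 partners at e^{-12} (ages differ by ~6 years, beta 2)
  p_within <- 2 * exp(0) / (2 * exp(0) + 3 * exp(-2 * 6))
  expect_gt(within_share, 0.9 * p_within)
  expect_gt(within_share, 0.95)
})

test_that("win probabilities follow the latent hierarchy at the extremes", {
  ids <- sprintf("w%02d", 1:5)
  tl <- list(list(composition_id = "W1", group = "g", members = ids,
                  start_day = 0L, end_day = 100L, location = "p",
                  enclosure_change_only = FALSE))
  # steep limit: perfectly transitive win matrix
  sc_inf <- herd_scenario(ids = ids, timeline = tl, steepness = 500,
                          sigma_dom = 0, lambda = 0.5)
  herd <- generate_herd(sc_inf, 14)
  am <- agonistic_matrix(herd$events, "W1", herd = herd)
  truth <- attr(generate_timeline(sc_inf, 14), "truth")
  ord <- truth$id[order(-truth$score)]
  W <- am$wins[ord, ord]
  expect_true(all(W[lower.tri(W)] == 0))
  # flat limit: per-dyad win proportions near one half
  sc0 <- herd_scenario(ids = ids, timeline = tl, steepness = 0,
                       lambda = 2)
  herd0 <- generate_herd(sc0, 15)
  am0 <- agonistic_matrix(herd0$events, "W1", herd = herd0)
  n <- am0$wins + t(am0$wins)
  ut <- upper.tri(n) & n > 30
  props <- am0$wins[ut] / n[ut]
  expect_true(all(abs(props - 0.5) <= 3 * sqrt(0.25 / n[ut])))
})

test_that("residence histories encode the intended familiarity", {
  sc <- herd_scenario()
  skel <- generate_timeline(sc, 16)
  comps <- skel$compositions
  # founders: fully familiar at the first composition (180 days together)
  m1 <- comps$members[[1]]
  fam1 <- familiarity_matrix(m1, comps$start_date[1], skel$residences)
  expect_true(all(fam1[upper.tri(fam1)]))
  # arrivals on day 0 of composition 2: strangers to residents,
  # familiar among themselves (co-reared)
  m2 <- comps$members[[2]]
  arrivals <- setdiff(m2, m1)
  residents <- intersect(m2, m1)
  fam2 <- familiarity_matrix(m2, comps$start_date[2], skel$residences)
  expect_true(all(!fam2[arrivals, residents]))
  expect_true(all(fam2[arrivals, arrivals][upper.tri(diag(length(arrivals)))]))
  # by composition 3 (70 days later, enclosure change only) still < 90 days
  fam3 <- familiarity_matrix(m2, comps$start_date[3], skel$residences)
  expect_true(all(!fam3[arrivals, residents]))
  # by composition 4 (130 days after arrival) everyone is familiar
  m4 <- comps$members[[4]]
  fam4 <- familiarity_matrix(m4, comps$start_date[4], skel$residences)
  expect_true(all(fam4[upper.tri(fam4)]))
})

test_that("singleton compositions cannot produce scans", {
  ids <- c("s1", "s2")
  tl <- list(list(composition_id = "S1", group = "g", members = "s1",
                  start_day = 0L, end_day = 10L, location = "p",
                  enclosure_change_only = FALSE))
  sc <- herd_scenario(ids = ids, timeline = tl)
  skel <- generate_timeline(sc, 17)
  expect_error(generate_scans(sc, skel, 17), "singleton")
})

test_that("overlapping group membership is rejected at scenario build", {
  ids <- c("x1", "x2", "x3", "x4")
  tl <- list(
    list(composition_id = "A", group = "g1", members = c("x1", "x2"),
         start_day = 0L, end_day = 50L, location = "p1",
         enclosure_change_only = FALSE),
    list(composition_id = "B", group = "g2", members = c("x2", "x3"),
         start_day = 10L, end_day = 60L, location = "p2",
         enclosure_change_only = FALSE))
  expect_error(herd_scenario(ids = ids, timeline = tl), "at once")
})
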