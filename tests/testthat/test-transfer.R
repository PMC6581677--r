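# helpers: minimal compositions + metric rows around a change
make_pair <- function(members_before, members_after, enclosure = FALSE,
                      seed = 61) {
  set.seed(seed)
  cb <- list(composition_id = "T1", group = "g", members = members_before,
             start_date = as.Date("2015-01-01"),
             end_date = as.Date("2015-03-01"),
             enclosure_change_only = FALSE)
  ca <- list(composition_id = "T2", group = "g", members = members_after,
             start_date = as.Date("2015-03-01"),
             end_date = as.Date("2015-05-01"),
             enclosure_change_only = enclosure)
  ab <- association_matrix(random_sym_matrix(length(members_before),
                                             ids = members_before))
  aa <- association_matrix(random_sym_matrix(length(members_after),
                                             ids = members_after))
  met <- function(comp, members) data.frame(
    individual_id = members, composition_id = comp,
    eigenvector_corrected = runif(length(members)),
    strength_corrected = runif(length(members), 0, 50),
    dominance = sample(length(members)),
    familiarity = rpois(length(members), 3), stringsAsFactors = FALSE)
  list(cb = cb, ca = ca, ab = ab, aa = aa,
       mb = met("T1", members_before), ma = met("T2", members_after))
}

test_that("an unchanged composition gives Mantel r = 1, zero deltas, zero transfers", {
  m <- c("a", "b", "c", "d")
  p <- make_pair(m, m)
  p$ma <- p$mb; p$ma$composition_id <- "T2"
  rec <- build_transfer_record(p$cb, p$ca, p$ab, p$ab, p$mb, p$ma,
                               sided = "two")
  expect_equal(rec$mantel$r, 1)
  expect_equal(rec$n_transferred, 0L)
  expect_equal(rec$deltas$d_eigenvector, rep(0, 4))
  expect_equal(rec$deltas$d_strength, rep(0, 4))
  expect_equal(rec$deltas$d_rank, rep(0L, 4))
})

test_that("enclosure-only changes carry n_transferred = 0 and are validated", {
  m <- c("a", "b", "c", "d")
  p <- make_pair(m, m, enclosure = TRUE)
  rec <- build_transfer_record(p$cb, p$ca, p$ab, p$aa, p$mb, p$ma,
                               sided = "two")
  expect_equal(rec$n_transferred, 0L)
  expect_true(rec$enclosure_only)
  # an enclosure-only flag with a member change is inconsistent
  p2 <- make_pair(m, c("a", "b", "c", "e"), enclosure = TRUE)
  expect_error(build_transfer_record(p2$cb, p2$ca, p2$ab, p2$aa, p2$mb,
                                     p2$ma, sided = "two"),
               "same members")
})

test_that("added plus removed individuals are counted by set algebra", {
  p <- make_pair(c("a", "b", "c", "d", "e"), c("a", "b", "c", "f"))
  rec <- build_transfer_record(p$cb, p$ca, p$ab, p$aa, p$mb, p$ma,
                               sided = "two")
  expect_equal(rec$n_transferred, 3L)        # d, e removed; f added
  expect_equal(rec$removed, c("d", "e"))
  expect_equal(rec$added, "f")
  expect_equal(rec$shared_members, c("a", "b", "c"))
})

test_that("swapping before and after negates deltas and keeps Mantel r", {
  p <- make_pair(c("a", "b", "c", "d", "e"), c("a", "b", "c", "d", "f"))
  fwd <- build_transfer_record(p$cb, p$ca, p$ab, p$aa, p$mb, p$ma,
                               sided = "two")
  # reverse the roles (dates swapped so adjacency still holds)
  cb2 <- p$ca; cb2$start_date <- p$cb$start_date
  cb2$end_date <- p$cb$end_date; cb2$enclosure_change_only <- FALSE
  ca2 <- p$cb; ca2$start_date <- p$ca$start_date
  ca2$end_date <- p$ca$end_date
  rev <- build_transfer_record(cb2, ca2, p$aa, p$ab, p$ma, p$mb,
                               sided = "two")
  expect_equal(rev$mantel$r, fwd$mantel$r)
  expect_equal(rev$n_transferred, fwd$n_transferred)
  ord <- match(fwd$deltas$individual_id, rev$deltas$individual_id)
  expect_equal(rev$deltas$d_eigenvector[ord], -fwd$deltas$d_eigenvector)
  expect_equal(rev$deltas$d_strength[ord], -fwd$deltas$d_strength)
  expect_equal(rev$deltas$d_rank[ord], -fwd$deltas$d_rank)
})

test_that("non-adjacent or cross-group compositions are rejected", {
  p <- make_pair(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  p$ca$start_date <- p$cb$end_date - 10   # overlaps the before period
  expect_error(build_transfer_record(p$cb, p$ca, p$ab, p$aa, p$mb, p$ma,
                                     sided = "two"), "not adjacent")
  p2 <- make_pair(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  p2$ca$group <- "other"
  expect_error(build_transfer_record(p2$cb, p2$ca, p2$ab, p2$aa, p2$mb,
                                     p2$ma, sided = "two"),
               "different groups")
})

test_that("stability statistics summarize the record set", {
  mk <- function(r, n_tr) {
    structure(list(mantel = list(r = r), n_transferred = n_tr),
              class = "transfer_record")
  }
  recs <- list(mk(0.9, 1L), mk(0.6, 3L), mk(0.2, 6L), mk(0.1, 8L))
  st <- stability_vs_transfers(recs, sided = "one_neg")
  expect_equal(st$estimate, -1)      # r strictly decreasing in transfers
  ms <- mean_stability(recs)
  expect_equal(ms$mean, mean(c(0.9, 0.6, 0.2, 0.1)))
  expect_equal(ms$min, 0.1)
  expect_equal(ms$max, 0.9)
  expect_equal(mean_stability(recs[1])$mean, 0.9)
  const <- list(mk(0.5, 2L), mk(0.4, 2L), mk(0.3, 2L))
  expect_error(stability_vs_transfers(const, sided = "two"), "constant")
})
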