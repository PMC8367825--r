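test_that("mean-of-means thresholds depend only on the class means", {
  expect_equal(learn_threshold(c(1, 1), c(3, 3)), 2)
  expect_equal(learn_threshold(c(2), c(2)), 2)
  expect_equal(learn_threshold(c(1, 3), c(2, 4)), learn_threshold(c(2, 4), c(1, 3)))

  set.seed(91)
  for (i in 1:25) {
    a <- runif(sample(1:40, 1), 0.5, 3)
    b <- runif(sample(1:40, 1), 1, 5)
    expect_equal(learn_threshold(a, b),
                 (sum(a) / length(a) + sum(b) / length(b)) / 2)
    if (abs(mean(a) - mean(b)) > 1e-12) {
      expect_gt(learn_threshold(a, b), min(mean(a), mean(b)))
      expect_lt(learn_threshold(a, b), max(mean(a), mean(b)))
    }
    # replicating one class leaves the threshold unchanged (size invariance)
    expect_equal(learn_threshold(rep(a, 3), b), learn_threshold(a, b))
  }
  expect_error(learn_threshold(numeric(0), c(1)), "non-empty")
})

make_records <- function(normals, opml, scc, site = "gingiva",
                         source = "patient") {
  tibble::tibble(
    site_id = sprintf("r%03d", seq_len(length(normals) + length(opml) +
                                         length(scc))),
    anatomical_site = site,
    score = c(normals, opml, scc),
    label = rep(c("normal", "OPML", "SCC"),
                c(length(normals), length(opml), length(scc))),
    source = source
  )
}

test_that("fit_model places both cutoffs at class-mean midpoints", {
  recs <- make_records(rep(1, 5), rep(3, 4), rep(5, 6))
  m <- fit_model(recs)
  expect_equal(m$t_opml, 2)
  expect_equal(m$t_scc, 4)
  expect_equal(m$provenance$n$normal, 5)
  # provenance reproduces the cutoffs under the mean-of-means rule
  cm <- m$provenance$class_means
  expect_equal((cm$normal + cm$OPML) / 2, m$t_opml)
  expect_equal((cm$OPML + cm$SCC) / 2, m$t_scc)

  expect_error(fit_model(make_records(rep(1, 3), rep(3, 3), numeric(0))),
               "missing class")
  expect_error(fit_model(make_records(rep(5, 3), rep(3, 3), rep(1, 3))),
               "degenerate training")
})

test_that("fitted cutoffs agree with recomputing means from the generator", {
  coh <- generate_cohort(c(normal = 5000, OPML = 5000, SCC = 5000), seed = 14)
  m <- fit_model(coh)
  means <- tapply(coh$score, coh$label, mean)
  expect_equal(m$t_opml, unname((means["normal"] + means["OPML"]) / 2))
  expect_equal(m$t_scc, unname((means["OPML"] + means["SCC"]) / 2))
  td <- tidy(m)
  expect_equal(td$cutoff, c(m$t_opml, m$t_scc))
  g <- glance(m)
  expect_equal(g$n_opml, 5000)
})

test_that("site-group filters select the right anatomical records", {
  recs <- dplyr::bind_rows(
    make_records(c(1, 1.2), c(3, 3.2), c(5, 5.2), site = "buccal_mucosa_left"),
    make_records(c(2, 2.2), c(4, 4.2), c(6, 6.2), site = "gingiva")
  )
  buccal <- fit_model(recs, group = "site:buccal_mucosa")
  expect_equal(buccal$t_opml, (1.1 + 3.1) / 2)
  ker <- fit_model(recs, group = "keratinized")
  expect_equal(ker$t_opml, (2.1 + 4.1) / 2)
  nonker <- fit_model(recs, group = "non_keratinized")
  expect_equal(nonker$t_opml, buccal$t_opml)
  expect_error(fit_model(recs, group = "site:hard_palate"), "missing class")
  expect_error(fit_model(recs, group = "everything"), "unknown group")
})

test_that("volunteer normals lower the OPML cutoff when they score lower", {
  coh <- generate_cohort(c(normal = 400, OPML = 200, SCC = 200),
                         n_volunteer_normals = 400, seed = 15)
  patient_model <- fit_model(coh, normal_source = "patient")
  volunteer_model <- fit_model(coh, normal_source = "healthy_volunteer")
  expect_lt(volunteer_model$t_opml, patient_model$t_opml)
  expect_equal(volunteer_model$t_scc, patient_model$t_scc)
})

test_that("classification respects the three zones and boundary convention", {
  m <- structure(list(group = "all_sites", t_opml = 2.028, t_scc = 3.6,
                      provenance = list(), version = 1L),
                 class = "threshold_model")
  out <- classify(c(2.51, 2.028, 0.9 * 2.028, 3.6, 5), m)
  expect_equal(as.character(out$class),
               c("suspect", "suspect", "normal", "critical", "critical"))
  expect_equal(unname(out$color),
               c("yellow", "yellow", "green", "red", "red"))
  # monotone non-decreasing risk along increasing scores
  grid <- classify(seq(0.5, 6, by = 0.1), m)
  expect_true(all(diff(as.integer(grid$class)) >= 0))
  expect_error(classify(-1, m), "positive")
})

test_that("models serialize to JSON and back without loss", {
  m <- fit_model(make_records(c(1, 1.4), c(2.9, 3.1), c(5, 5.5)))
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  back <- read_model(p)
  expect_equal(back$t_opml, m$t_opml)
  expect_equal(back$t_scc, m$t_scc)
  expect_equal(back$version, m$version)
  expect_equal(back$provenance$normal_source, "patient")
})
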