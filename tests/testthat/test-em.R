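test_that("nm to bp conversion applies the 3 bp/nm calibration", {
  m <- make_molecules(list(a = list(L = 50, bubbles = cbind(10, 43.4))),
                      unit = "nm")
  b <- to_bp(m)
  expect_equal(b$total_length, 150)           # 50 nm -> 150 bp
  expect_equal(unname(b$bubbles[[1]][1, ]), c(30, 130))
  expect_equal(attr(b, "unit"), "bp")
  m2 <- make_molecules(list(a = list(L = 100, bubbles = cbind(0, 10))),
                       unit = "nm")
  expect_equal(to_bp(m2)$total_length, 300)   # linearity
  expect_warning(to_bp(to_bp(m2)), "already in bp")
})

test_that("linearization shifts coordinates modulo ring length", {
  m <- make_molecules(list(
    a = list(L = 6000, topology = "circular", bubbles = cbind(1500, 1700)),
    b = list(L = 6000, topology = "circular", bubbles = cbind(5900, 100))),
    topology = "circular")
  lin <- linearize(m, 1000)
  expect_equal(unname(lin$bubbles[[1]][1, ]), c(500, 700))
  ## wrapping bubble (5900, 100): length 200, image (4900, 5100)
  expect_equal(unname(lin$bubbles[[2]][1, ]), c(4900, 5100))
  expect_true(all(lin$topology == "linear"))

  bad <- make_molecules(list(
    c = list(L = 6000, topology = "circular", bubbles = cbind(900, 1100))),
    topology = "circular")
  expect_error(linearize(bad, 1000), "unanalyzable")
  expect_warning(ok <- linearize(bad, 1000, drop_unanalyzable = TRUE),
                 "dropped")
  expect_equal(nrow(ok), 0L)
})

test_that("size bins follow the published nucleosome-footprint boundaries", {
  expect_equal(size_category(c(150, 320, 200, 270, 100, 400)),
               c("mono", "di", "intermediate", "gap", "sub", "supra"))
  ## boundary conventions: lower inclusive, di upper inclusive
  expect_equal(size_category(c(130, 180, 260, 280, 360, 361)),
               c("mono", "intermediate", "gap", "di", "di", "supra"))
})

test_that("classification matches a brute-force oracle and conserves counts", {
  feature <- c(1200, 1350)
  set.seed(99)
  pop <- random_molecules(1000)
  classes <- classify_molecules(pop, feature)
  expect_equal(sum(classes$count), nrow(pop))
  expect_equal(sum(classes$percent), 100, tolerance = 1e-9)

  keys <- vapply(seq_len(nrow(pop)), function(i)
    oracle_class_key(pop$bubbles[[i]], feature), "")
  want <- table(keys)
  expect_equal(sort(classes$class_key), sort(names(want)))
  expect_equal(classes$count[match(names(want), classes$class_key)],
               as.integer(want))

  ## invariant to bubble listing order (multiset key)
  m1 <- make_molecules(list(a = list(L = 3000,
                                     bubbles = cbind(c(100, 1210), c(250, 1360)))))
  m2 <- make_molecules(list(a = list(L = 3000,
                                     bubbles = cbind(c(1210, 100), c(1360, 250)))))
  expect_equal(classify_molecules(m1, feature)$class_key,
               classify_molecules(m2, feature)$class_key)
  ## uniform shift that crosses no feature boundary keeps the class
  m3 <- make_molecules(list(a = list(L = 3000,
                                     bubbles = cbind(c(110, 1220), c(260, 1370)))))
  expect_equal(classify_molecules(m1, feature)$class_key,
               classify_molecules(m3, feature)$class_key)

  ## fully crosslinked molecule gets the 0-bubble class
  m0 <- make_molecules(list(a = list(L = 3000,
                                     bubbles = matrix(numeric(), ncol = 2))))
  expect_equal(classify_molecules(m0, feature)$class_key, "0:crosslinked")
})

test_that("bubble size histogram matches brute-force binning and conserves totals", {
  m <- make_molecules(list(
    a = list(L = 3000, bubbles = cbind(c(0, 500), c(150, 650))),
    b = list(L = 3000, bubbles = cbind(c(100, 1000), c(420, 1200)))))
  h <- bubble_size_distribution(m)
  expect_equal(h$count[h$label == "mono"], 2L)
  expect_equal(h$count[h$label == "di"], 1L)
  expect_equal(h$count[h$label == "intermediate"], 1L)
  expect_equal(h$fraction[h$label == "mono"], 0.5)
  expect_equal(sum(h$fraction), 1)

  set.seed(7)
  pop <- random_molecules(300)
  lens <- oracle_bubble_lengths(pop)
  want <- table(factor(vapply(lens, oracle_size_label, ""),
                       levels = default_size_bins()$label))
  got <- bubble_size_distribution(pop)
  expect_equal(got$count, as.integer(want))
  expect_equal(sum(got$count), length(lens))
})

test_that("crosslinked-over-feature counts molecules with no bubble touching the feature", {
  feature <- c(1000, 1120)
  specs <- list()
  for (i in 1:69) specs[[paste0("f", i)]] <-
    list(L = 3000, bubbles = cbind(1050, 1200))        # occupied
  for (i in 1:31) specs[[paste0("c", i)]] <-
    list(L = 3000, bubbles = cbind(1500, 1650))        # free over feature
  m <- make_molecules(specs)
  expect_equal(fraction_crosslinked_over_feature(m, feature), 0.31)
  ## all bubble-free molecules -> 1
  m1 <- make_molecules(list(a = list(L = 100, bubbles = matrix(numeric(), ncol = 2))))
  expect_equal(fraction_crosslinked_over_feature(m1, feature), 1.0)
  ## 1-bp touch disqualifies at min_overlap 1 but not at min_overlap 10
  m2 <- make_molecules(list(a = list(L = 3000, bubbles = cbind(1119, 1200))))
  expect_equal(fraction_crosslinked_over_feature(m2, feature), 0)
  expect_equal(fraction_crosslinked_over_feature(m2, feature,
                                                 min_overlap = 10), 1)
})
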