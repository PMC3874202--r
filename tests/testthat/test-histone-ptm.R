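test_that("derivatized digest cleaves after R only, never before P", {
  d4 <- derivatized_digest(histone_sequence("H4"))
  expect_true(any(d4$start == 4 & d4$end == 17))   # N-terminal tail peptide
  expect_true(any(d4$start == 46 & d4$end == 55))  # anchor
  expect_true(any(d4$start == 79 & d4$end == 92))  # anchor

  d3 <- derivatized_digest(histone_sequence("H3"))
  expect_true(any(d3$start == 27 & d3$end == 40))
  expect_true(any(d3$start == 64 & d3$end == 69))

  toy <- chromdom:::new_histone_sequence
  t1 <- derivatized_digest(toy("toy", "AKRGKA"))
  expect_equal(t1$peptide, c("AKR", "GKA"))  # K blocked, cleave after R
  t2 <- derivatized_digest(toy("toy", "ARPGGR"))
  expect_equal(t2$peptide, c("ARPGGR"))      # no cleavage before P
  t3 <- derivatized_digest(toy("toy", "AGGQS"))
  expect_equal(t3$peptide, "AGGQS")          # no R: whole chain
})

test_that("mass arithmetic is additive and matches elemental deltas", {
  expect_equal(theoretical_mz("G", nterm = "free"), 76.0393,
               tolerance = 1e-4)
  ## acetyl vs trimethyl near-isobar
  expect_equal(mod_delta("me3") - mod_delta("ac"), 0.03639,
               tolerance = 2e-4)
  ## adding one propionyl adds exactly its delta
  base <- theoretical_mz("GKGGK", c("ac", "ac"))
  expect_equal(theoretical_mz("GKGGK", c("ac", "prop")) - base,
               mod_delta("prop") - mod_delta("ac"), tolerance = 1e-12)
  ## oracle: independent residue-sum for a modified peptide
  pep <- "KSAPSTGGVKKPHR"
  res <- strsplit(pep, "")[[1]]
  oracle <- sum(residue_masses()[res]) + 18.010565 + 1.007276 +
    56.026215 + 3 * 56.026215  # N-term + 3 propionylated K
  expect_equal(theoretical_mz(pep, rep("prop", 3)), oracle,
               tolerance = 1e-9)
})

test_that("modform enumeration collapses positional isomers into mass bins", {
  mf <- enumerate_modforms("GKGGKGLGKGGAKR", c("prop", "ac"))
  expect_equal(nrow(mf), 5L)                       # 0..4 acetyl
  expect_equal(diff(mf$mz_mh), rep(14.01565, 4), tolerance = 1e-6)
  expect_equal(oracle_modform_bins("GKGGKGLGKGGAKR", c("prop", "ac")),
               round(mf$mono_mass, 4))

  ## full 5-state alphabet: 70 multisets; bin count from the exhaustive
  ## per-site oracle
  mf5 <- enumerate_modforms("GKGGKGLGKGGAKR")
  expect_equal(sum(mf5$n_forms), 70L)              # C(8,4)
  expect_equal(oracle_modform_bins("GKGGKGLGKGGAKR",
                                   c("prop", "ac", "me1+prop",
                                     "me2", "me3")),
               round(mf5$mono_mass, 4))

  ## peptide without lysines: the single N-derivatized form
  mf0 <- enumerate_modforms("ISGLIYEETR", c("prop", "ac"))
  expect_equal(nrow(mf0), 1L)
})

test_that("recalibration recovers linear drift and falls back to offset-only", {
  mz <- c(800, 1200, 1600, 2000)
  pl <- peaklist("s", 1.0001 * mz + 0.05, c(10, 20, 30, 40))
  anchors <- data.frame(theoretical = mz[c(1, 4)],
                        observed = 1.0001 * mz[c(1, 4)] + 0.05)
  out <- recalibrate(pl, anchors)
  expect_equal(out$mz, mz, tolerance = 1e-9)

  ## uniform +0.2 offset, two anchors
  pl2 <- peaklist("s", mz + 0.2, rep(1, 4))
  out2 <- recalibrate(pl2, data.frame(theoretical = mz[c(2, 3)],
                                      observed = mz[c(2, 3)] + 0.2))
  expect_equal(out2$mz, mz, tolerance = 1e-9)

  ## single anchor: offset-only
  out3 <- recalibrate(pl2, data.frame(theoretical = mz[1],
                                      observed = mz[1] + 0.2))
  expect_equal(out3$mz, mz, tolerance = 1e-9)

  expect_warning(out4 <- recalibrate(pl2, data.frame(theoretical = numeric(),
                                                     observed = numeric())),
                 "skipped")
  expect_equal(out4$mz, pl2$mz)
})

test_that("peak assignment respects tolerance and merges near-isobaric bins", {
  mf <- enumerate_modforms("GKGGKGLGKGGAKR", c("prop", "ac"))
  ## exact peaks for two bins, nothing else
  pl <- peaklist("s", c(mf$mz_mh[1] + 0.01, mf$mz_mh[3] - 0.02), c(5, 7))
  a <- assign_peaks(pl, mf, tolerance = 0.15)
  expect_equal(a$intensity, c(5, 0, 7, 0, 0))

  ## no peak within tolerance -> 0
  pl2 <- peaklist("s", mf$mz_mh[2] + 0.5, 9)
  expect_equal(sum(assign_peaks(pl2, mf, tolerance = 0.15)$intensity), 0)

  ## ac vs me3 (0.0364 Da apart) merge into one ambiguity group
  mf2 <- enumerate_modforms("GKR", c("prop", "ac", "me3"))
  a2 <- assign_peaks(peaklist("s", mf2$mz_mh[1], 4), mf2, tolerance = 0.15)
  merged <- a2[a2$n_bins_merged > 1, ]
  expect_equal(nrow(merged), 1L)
  expect_match(merged$group, "1ac.*/.*1me3")
})

test_that("proportions normalize per peptide and average over detected replicas", {
  a <- data.frame(group = c("x", "y", "z"), intensity = c(2, 3, 5))
  p <- modification_proportions(a)
  expect_equal(p$proportion, c(0.2, 0.3, 0.5))
  expect_true(attr(p, "detected"))

  none <- modification_proportions(data.frame(group = "x", intensity = 0))
  expect_false(attr(none, "detected"))

  t1 <- data.frame(group = c("x", "y"), proportion = c(1, 0))
  t2 <- data.frame(group = c("x", "y"), proportion = c(0, 1))
  attr(t1, "detected") <- TRUE; attr(t2, "detected") <- TRUE
  avg <- average_replicas(list(t1, t2))
  expect_equal(avg$proportion, c(0.5, 0.5))
  ## identical replicas unchanged; mean matches brute force
  t3 <- data.frame(group = c("x", "y"), proportion = c(0.25, 0.75))
  attr(t3, "detected") <- TRUE
  expect_equal(average_replicas(list(t3, t3, t3))$proportion, c(0.25, 0.75))
  avg3 <- average_replicas(list(t1, t2, t3))
  expect_equal(avg3$proportion,
               colMeans(rbind(c(1, 0), c(0, 1), c(0.25, 0.75))))
})

test_that("pipeline proportions sum to 1 at every stage and survive drift", {
  p_true <- c(0.02, 0.08, 0.2, 0.3, 0.4)
  sim <- gen_maldi(p_true, noise_cv = 0.08,
                   drift_slope = 1.0001, drift_offset = 0.05, seed = 21)
  out <- histone_ptm_pipeline(sim$peaklists, histone_sequence("H4"),
                              c(4, 17), anchor_ranges = sim$anchor_ranges)
  for (t in out$per_spot) expect_equal(sum(t$proportion), 1,
                                       tolerance = 1e-9)
  expect_equal(sum(out$averaged$proportion), 1, tolerance = 1e-9)
  expect_lt(score_proportions(out$averaged, sim$truth), 0.05)
})
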