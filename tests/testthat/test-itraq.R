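test_that("protein ratios aggregate peptide ratios and match a brute-force oracle", {
  q <- quant_from_ratios(list(P1 = c(2, 2, 2), P2 = c(1, 2, 9)))
  r <- protein_ratio_from_peptides(q, "115", "114")
  expect_equal(r$raw_ratio[r$protein_id == "P1"], 2)
  expect_equal(r$n_peptides[r$protein_id == "P1"], 3L)
  expect_equal(r$raw_ratio[r$protein_id == "P2"], 2)  # median of {1,2,9}

  set.seed(42)
  rows <- list()
  for (rep_ in c("rep1", "rep2")) for (p in sprintf("P%02d", 1:15)) {
    for (i in seq_len(sample(1:5, 1)))
      rows[[length(rows) + 1L]] <- list(rep_, p, paste0(p, i),
                                        runif(1, 50, 500), runif(1, 50, 500))
  }
  q2 <- make_quant(rows)
  got <- protein_ratio_from_peptides(q2, "115", "114")
  want <- oracle_protein_ratios(as.data.frame(q2))
  expect_equal(got$raw_ratio, want$raw_ratio, tolerance = 1e-12)
  expect_equal(got$n_peptides, want$n_peptides)

  ## mean aggregation matches the oracle with mean
  got_m <- protein_ratio_from_peptides(q2, "115", "114", "mean")
  want_m <- oracle_protein_ratios(as.data.frame(q2), agg = mean)
  expect_equal(got_m$raw_ratio, want_m$raw_ratio, tolerance = 1e-12)
})

test_that("proteins without usable control intensity are excluded with a warning", {
  q <- make_quant(list(list("rep1", "P1", "a", 0, 100),
                       list("rep1", "P2", "b", 50, 100)))
  expect_warning(r <- protein_ratio_from_peptides(q, "115", "114"),
                 "without usable control")
  expect_equal(r$protein_id, "P2")
})

test_that("background factor is the mean ratio of background proteins and recovers a known bias", {
  ann <- simple_annotation(c("B1", "B2", "S1"),
                           c("housekeeping", "ribosomal protein", "x"))
  q <- quant_from_ratios(list(B1 = 0.5, B2 = 1.5, S1 = 3))
  r <- protein_ratio_from_peptides(q, "115", "114")
  expect_equal(background_factor(r, ann, "rep1"), 1.0)
  expect_error(
    background_factor(r, simple_annotation("S1", "x"), "rep1"),
    "background")

  ## simulation with global bias 2.0 and noise: factor close to 2
  sim <- gen_itraq(n_background = 150, n_spiked = 0, replicate_bias = 2.0,
                   n_replicates = 1, noise_cv = 0.25, seed = 7)
  rs <- protein_ratio_from_peptides(sim$quant, "115", "114")
  f <- background_factor(rs, sim$annotation, "rep1")
  expect_lt(abs(f - 2.0), 0.1)
})

test_that("correction and replicate averaging follow identified replicates only", {
  ann <- simple_annotation(c("B1", "P1", "P2"),
                           c("housekeeping", "x", "x"))
  rows <- list(
    list("rep1", "B1", "b1", 100, 100),   # factor rep1 = 1
    list("rep1", "P1", "p1", 100, 150),
    list("rep2", "B1", "b1", 100, 200),   # factor rep2 = 2
    list("rep2", "P1", "p1", 100, 300),
    list("rep2", "P1", "p2", 100, 300),
    list("rep2", "P2", "q1", 100, 600))
  s <- correct_and_summarize(
    protein_ratio_from_peptides(make_quant(rows), "115", "114"), ann)
  p1 <- s[s$protein_id == "P1", ]
  expect_equal(p1$avg_ratio, 1.5)       # corrected {1.5, 1.5}
  expect_equal(p1$total_peptides, 3L)
  ## protein in 1 of 2 replicates: singleton mean
  expect_equal(s$avg_ratio[s$protein_id == "P2"], 3.0)
})

test_that("background correction makes background mean 1, is idempotent and scale invariant", {
  sim <- gen_itraq(n_background = 40, n_spiked = 5, n_replicates = 3,
                   noise_cv = 0.2, seed = 11)
  r <- protein_ratio_from_peptides(sim$quant, "115", "114")
  ## balanced design: every protein in every replicate, so the corrected
  ## per-replicate background mean is exactly 1
  for (rep_ in unique(r$replicate_id)) {
    f <- background_factor(r, sim$annotation, rep_)
    r2 <- r
    r2$raw_ratio <- r$raw_ratio / f
    expect_equal(background_factor(r2, sim$annotation, rep_), 1,
                 tolerance = 1e-9)
  }
  ## scale invariance: multiplying one replicate's domain channel by g
  q2 <- sim$quant
  sel <- q2$replicate_id == "rep2"
  q2$`115`[sel] <- q2$`115`[sel] * 7.3
  s1 <- correct_and_summarize(r, sim$annotation)
  s2 <- correct_and_summarize(
    protein_ratio_from_peptides(q2, "115", "114"), sim$annotation)
  expect_equal(s2$avg_ratio, s1$avg_ratio, tolerance = 1e-9)
})

test_that("tier calling respects the quoted boundary inclusivity and is monotone", {
  cases <- data.frame(
    ratio = c(1.5, 1.5, 1.2, 1.0, 1.49, 0.9, 2.0),
    pep   = c(2L,  1L,  3L,  5L,  2L,   10L, 1L),
    tier  = c("STRICT", "RELAXED_A", "RELAXED_B", "NONE", "RELAXED_B",
              "NONE", "RELAXED_A"))
  got <- call_enrichment_tier(cases$ratio, cases$pep)
  expect_equal(as.character(got), cases$tier)

  ## monotonicity: raising ratio or peptides never lowers the tier
  set.seed(5)
  ratios <- runif(200, 0.5, 2.5); peps <- sample(1:6, 200, replace = TRUE)
  rank0 <- as.integer(call_enrichment_tier(ratios, peps))
  expect_true(all(as.integer(call_enrichment_tier(ratios + 0.3, peps))
                  <= rank0))
  expect_true(all(as.integer(call_enrichment_tier(ratios, peps + 2L))
                  <= rank0))
})

test_that("complex summaries apply the 50% coverage rule over annotated members", {
  s <- structure(data.frame(
    protein_id = c("A", "B", "C", "E", "F", "G"),
    avg_ratio = c(2, 3, 1.6, 1.2, 0.8, 2.0),
    total_peptides = c(4L, 2L, 1L, 2L, 5L, 3L),
    n_replicates = 1L, stringsAsFactors = FALSE),
    class = c("enrichment_summary", "data.frame"))
  s <- call_enrichment_tier(s)
  cx <- summarize_complex("cplx", c("A", "B", "C", "D"), s)
  expect_equal(cx$coverage, 0.75)
  expect_true(cx$depicted)
  expect_equal(cx$avg_ratio, mean(c(2, 3, 1.6)))
  expect_equal(cx$avg_peptides, 7 / 3)

  ## 4 of 10 passing -> below threshold
  cx2 <- summarize_complex("big", c("A", "B", "C", "E", letters[1:6]), s)
  expect_equal(cx2$coverage, 0.4)
  expect_false(cx2$depicted)
  expect_error(summarize_complex("solo", "A", s), ">= 2")
})

test_that("functional composition sums to 1 and maps unknowns to other", {
  ann <- simple_annotation(c("H1", "H2", "R1", "R2"),
                           c("histones", "histones",
                             "ribosomal protein", "ribosomal protein"))
  s <- data.frame(protein_id = c("H1", "H2", "R1", "R2"))
  comp <- functional_composition(s, ann)
  expect_equal(comp[["histones"]], 0.5)
  expect_equal(comp[["ribosomal protein"]], 0.5)
  comp2 <- functional_composition(data.frame(protein_id = c("X", "Y")), ann)
  expect_equal(comp2, c(other = 1.0))
  ## property: sums to 1 on random inputs
  for (k in 1:5) {
    n <- 5 + k
    s3 <- data.frame(protein_id = sprintf("p%d", 1:n))
    ann3 <- simple_annotation(sprintf("p%d", 1:n),
                              sample(c("a", "b", "c"), n, replace = TRUE))
    expect_equal(sum(functional_composition(s3, ann3)), 1, tolerance = 1e-12)
  }
})
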