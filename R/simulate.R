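## Seeded synthetic-data generators with ground truth for every analysis
## stage. A single root seed expands into fixed per-generator substreams
## so adding a generator never perturbs existing fixtures.

substream_seed <- function(seed, generator) {
  offsets <- c(itraq = 101L, maldi = 211L, em = 307L, amounts = 401L)
  if (!(generator %in% names(offsets))) stop("unknown generator")
  (as.integer(seed) %% 100000L) * 10007L + offsets[[generator]]
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

## mean-1 multiplicative log-normal noise
rlnorm1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate an iTRAQ comparative experiment
#'
#' Background proteins (housekeeping + ribosomal) have true
#' background-corrected ratio 1; spiked proteins sit at `spike_ratio`.
#' Each replicate carries a global multiplicative bias (mimicking
#' labeling/loading differences) that the background correction must
#' remove. Intensities are generated at peptide level: per peptide, a
#' log-normal control-channel intensity and a domain-channel intensity
#' equal to control x true ratio x bias x multiplicative noise of the
#' given CV. Peptide counts are 1 + Poisson(`peptide_lambda`).
#'
#' @param n_background number of background proteins (>= 1).
#' @param n_spiked number of enriched proteins.
#' @param spike_ratio true corrected ratio of spiked proteins.
#' @param n_replicates biological replicates.
#' @param noise_cv coefficient of variation of peptide-level ratio noise.
#' @param peptide_lambda Poisson rate for extra peptides per protein and
#'   replicate.
#' @param replicate_bias optional numeric vector of per-replicate global
#'   bias factors; drawn log-normally (CV 0.2) when NULL.
#' @param base_intensity median control-channel intensity.
#' @param domain_channel,control_channel channel labels.
#' @param seed root seed.
#' @return List: `quant` (`quant_table`), `annotation`
#'   (`annotation_table`), `truth` (data frame `protein_id`,
#'   `true_ratio`, `enriched`), `replicate_bias`.
#' @export
gen_itraq <- function(n_background = 200L, n_spiked = 20L,
                      spike_ratio = 3.0, n_replicates = 3L,
                      noise_cv = 0.25, peptide_lambda = 2,
                      replicate_bias = NULL, base_intensity = 1000,
                      domain_channel = "115", control_channel = "114",
                      seed = 1L) {
  if (n_background < 1L)
    stop("background correction undefined without background proteins")
  set.seed(substream_seed(seed, "itraq"))
  prot <- c(sprintf("BG%03d", seq_len(n_background)),
            if (n_spiked > 0L) sprintf("SPK%03d", seq_len(n_spiked)))
  true_ratio <- c(rep(1, n_background), rep(spike_ratio, n_spiked))
  classes <- c(rep(c("housekeeping", "ribosomal protein"),
                   length.out = n_background),
               rep("chromatin factor", n_spiked))
  if (is.null(replicate_bias))
    replicate_bias <- rlnorm1(n_replicates, 0.2)
  stopifnot(length(replicate_bias) == n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (i in seq_along(prot)) {
      npep <- 1L + stats::rpois(1, peptide_lambda)
      ctl <- stats::rlnorm(npep, meanlog = log(base_intensity), sdlog = 0.5)
      dom <- ctl * true_ratio[i] * replicate_bias[r] * rlnorm1(npep, noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = sprintf("rep%d", r),
        protein_id = prot[i],
        peptide_seq = sprintf("%s_pep%02d", prot[i], seq_len(npep)),
        ctl = ctl, dom = dom, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  names(df)[names(df) == "ctl"] <- control_channel
  names(df)[names(df) == "dom"] <- domain_channel
  list(quant = quant_table(df, c(control_channel, domain_channel)),
       annotation = annotation_table(prot, classes),
       truth = data.frame(protein_id = prot, true_ratio = true_ratio,
                          enriched = true_ratio > 1,
                          stringsAsFactors = FALSE),
       replicate_bias = replicate_bias)
}

#' Score enrichment calls against simulation truth
#'
#' @param summaries tier-called `enrichment_summary`.
#' @param truth truth data frame from [gen_itraq()].
#' @param call_tier tiers counted as positive calls (default `"STRICT"`).
#' @return List: `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
score_enrichment <- function(summaries, truth, call_tier = "STRICT") {
  called <- summaries$protein_id[as.character(summaries$tier) %in% call_tier]
  pos <- truth$protein_id[truth$enriched]
  neg <- truth$protein_id[!truth$enriched]
  tp <- sum(pos %in% called); fn <- length(pos) - tp
  fp <- sum(neg %in% called); tn <- length(neg) - fp
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Simulate MALDI spot replicas for one histone peptide
#'
#' Generates centroided peak lists at the theoretical m/z of the
#' peptide's modification-form bins (plus derivatized anchor peptides)
#' under a linear calibration drift `mz' = slope x mz + offset`, with
#' per-peak multiplicative log-normal intensity noise.
#'
#' @param true_proportions numeric vector summing to 1, one entry per
#'   mass bin of the peptide in ascending-mass order (see
#'   [enumerate_modforms()]).
#' @param histone `histone_sequence` (default H4).
#' @param peptide_range quantified peptide (default `c(4, 17)`).
#' @param alphabet lysine site-state alphabet (default
#'   `c("prop", "ac")`).
#' @param anchor_ranges anchor peptides included in each spectrum
#'   (default H4 46–55 and 79–92).
#' @param n_spots spot replicas (default 3).
#' @param total_intensity summed intensity of the peptide's forms.
#' @param noise_cv intensity noise CV.
#' @param drift_slope,drift_offset linear calibration drift.
#' @param seed root seed.
#' @return List: `peaklists`, `truth` (data frame `group`,
#'   `proportion`), `modforms`, `anchor_ranges`.
#' @export
gen_maldi <- function(true_proportions,
                      histone = histone_sequence("H4"),
                      peptide_range = c(4, 17),
                      alphabet = c("prop", "ac"),
                      anchor_ranges = list(c(46, 55), c(79, 92)),
                      n_spots = 3L, total_intensity = 1e5,
                      noise_cv = 0, drift_slope = 1, drift_offset = 0,
                      seed = 1L) {
  if (abs(sum(true_proportions) - 1) > 1e-9)
    stop("true proportions must sum to 1")
  set.seed(substream_seed(seed, "maldi"))
  digest <- derivatized_digest(histone)
  pick <- function(rng) {
    hit <- digest$start == rng[1] & digest$end == rng[2]
    if (!any(hit)) stop("peptide ", rng[1], "-", rng[2],
                        " not in derivatized digest")
    digest$peptide[hit][1]
  }
  modforms <- enumerate_modforms(pick(peptide_range), alphabet)
  if (length(true_proportions) != nrow(modforms))
    stop("need one proportion per mass bin (", nrow(modforms), ")")
  anchor_mz <- vapply(anchor_ranges, function(rng) {
    p <- pick(rng)
    theoretical_mz(p, rep("prop", sum(strsplit(p, "")[[1]] == "K")))
  }, 0)
  truth <- data.frame(group = modforms$bin,
                      proportion = as.numeric(true_proportions),
                      stringsAsFactors = FALSE)
  peaklists <- lapply(seq_len(n_spots), function(s) {
    mz_true <- c(modforms$mz_mh, anchor_mz)
    inten <- c(total_intensity * true_proportions *
                 rlnorm1(nrow(modforms), noise_cv),
               rep(2 * total_intensity, length(anchor_mz)) *
                 rlnorm1(length(anchor_mz), noise_cv))
    keep <- inten > 0
    mz_obs <- drift_slope * mz_true[keep] + drift_offset
    o <- order(mz_obs)
    peaklist(sprintf("spot%d", s), mz_obs[o], inten[keep][o])
  })
  names(peaklists) <- sprintf("spot%d", seq_len(n_spots))
  list(peaklists = peaklists, truth = truth, modforms = modforms,
       anchor_ranges = anchor_ranges)
}

#' Mean absolute error of estimated modification proportions
#'
#' @param estimated proportion table (columns `group`, `proportion`).
#' @param truth truth data frame from [gen_maldi()].
#' @return Mean absolute error over bins.
#' @export
score_proportions <- function(estimated, truth) {
  est <- estimated$proportion[match(truth$group, estimated$group)]
  est[is.na(est)] <- 0
  mean(abs(est - truth$proportion))
}

#' Simulate psoralen-EM molecule populations
#'
#' Each molecule draws a nucleosome configuration from `catalog`; every
#' nucleosome protects `footprint` bp from crosslinking. Protected
#' intervals separated by linkers shorter than `merge_threshold`
#' coalesce into a single bubble (EM cannot resolve short crosslinked
#' linkers). Bubble boundaries are then jittered by a Gaussian of sd
#' `jitter_sd` (sizing noise). Coordinates are emitted circular, in bp
#' or nm.
#'
#' @param n_molecules population size.
#' @param fmap `feature_map` providing the ring length.
#' @param catalog list of configurations, each
#'   `list(positions = <nucleosome start positions, bp>, prob = <p>)`;
#'   probabilities must sum to 1.
#' @param footprint protected bp per nucleosome (default 147).
#' @param merge_threshold minimum resolvable crosslinked linker, bp
#'   (default 30).
#' @param jitter_sd boundary sizing noise sd, bp (default 0).
#' @param unit `"bp"` (default) or `"nm"` output unit.
#' @param scale bp per nm used when emitting nm.
#' @param seed root seed.
#' @return List: `molecules` (`molecule_table`), `truth` (data frame
#'   `molecule_id`, `configuration`, `n_nucleosomes`,
#'   `feature_occupied`).
#' @export
gen_molecules <- function(n_molecules, fmap, catalog, footprint = 147,
                          merge_threshold = 30, jitter_sd = 0,
                          unit = c("bp", "nm"), scale = default_scale(),
                          seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(inherits(fmap, "feature_map"))
  L <- fmap$ring_length
  probs <- vapply(catalog, function(x) x$prob, 0)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("catalog probabilities must sum to 1")
  for (cfg in catalog)
    if (length(cfg$positions) &&
        (any(cfg$positions < 0) || any(cfg$positions >= L)))
      stop("nucleosome placement outside ring")
  set.seed(substream_seed(seed, "em"))
  feat <- c(fmap$features$start[1], fmap$features$end[1])
  draw <- sample.int(length(catalog), n_molecules, replace = TRUE,
                     prob = probs)
  bubbles <- vector("list", n_molecules)
  occupied <- logical(n_molecules)
  for (i in seq_len(n_molecules)) {
    pos <- catalog[[draw[i]]]$positions
    if (!length(pos)) {
      bubbles[[i]] <- matrix(numeric(), ncol = 2)
      next
    }
    prot <- cbind(start = pos, len = rep(footprint, length(pos)))
    merged <- merge_circular(prot, L, merge_threshold)
    if (jitter_sd > 0) {
      merged[, "start"] <- (merged[, "start"] +
        stats::rnorm(nrow(merged), 0, jitter_sd)) %% L
      merged[, "len"] <- pmax(1, merged[, "len"] +
        stats::rnorm(nrow(merged), 0, jitter_sd))
    }
    b <- cbind(start = round_half_up(merged[, "start"]) %% L,
               end = round_half_up(merged[, "start"] + merged[, "len"]) %% L)
    bubbles[[i]] <- b
    occupied[i] <- any(vapply(seq_along(pos), function(k)
      circular_overlap(pos[k], footprint, feat, L) >= 1, logical(1)))
  }
  ids <- sprintf("mol%04d", seq_len(n_molecules))
  mol <- molecule_table(ids,
                        rep(if (unit == "bp") L else L / scale,
                            n_molecules),
                        unit, "circular",
                        if (unit == "bp") bubbles
                        else lapply(bubbles, function(b) b / scale))
  list(molecules = mol,
       truth = data.frame(molecule_id = ids, configuration = draw,
                          n_nucleosomes = vapply(catalog[draw], function(x)
                            length(x$positions), 0L),
                          feature_occupied = occupied,
                          stringsAsFactors = FALSE))
}

## merge circular (start, len) intervals whose gaps are below threshold
merge_circular <- function(iv, L, threshold) {
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  ## iterative pairwise merging around the circle
  repeat {
    n <- nrow(iv)
    if (n <= 1L) break
    ends <- iv[, "start"] + iv[, "len"]
    gaps <- c(iv[-1, "start"], iv[1, "start"] + L) - ends
    j <- which(gaps < threshold)
    if (!length(j)) break
    j <- j[1]
    k <- if (j == n) 1L else j + 1L
    newlen <- gaps[j] + iv[j, "len"] + iv[k, "len"]
    iv[j, "len"] <- newlen
    iv <- iv[-k, , drop = FALSE]
    iv <- iv[order(iv[, "start"]), , drop = FALSE]
    if (nrow(iv) == 1L && iv[1, "len"] >= L) { iv[1, "len"] <- L - 1; break }
  }
  iv[, "start"] <- iv[, "start"] %% L
  iv
}

circular_overlap <- function(start, len, feature, L) {
  end <- start + len
  pieces <- if (end <= L) list(c(start, end))
            else list(c(start, L), c(0, end - L))
  sum(vapply(pieces, function(p)
    max(0, min(p[2], feature[2]) - max(p[1], feature[1])), 0))
}

#' Simulate a purification fraction-amount table
#'
#' Closed-form generator: the cellular extract splits into pellet and
#' supernatant with a configurable loss, the elution is CE x true
#' recovery, reference-locus amounts follow the configured fold-excess,
#' and recombined/non-recombined amounts follow the configured
#' efficiency.
#'
#' @param domain_name label.
#' @param ce cellular-extract amount (fmoles).
#' @param true_recovery fraction of CE recovered in the IgG elution.
#' @param loss fraction of CE lost between CE and P + SUP.
#' @param pellet_fraction share of the retained material in the pellet.
#' @param fold_excess_elution domain:reference ratio in the elution.
#' @param efficiency recombination efficiency (fraction of total).
#' @param seed root seed (the generator is deterministic; the seed is
#'   accepted for interface uniformity).
#' @return List: `amounts` (`fraction_amounts`), `truth`.
#' @export
gen_amounts <- function(domain_name = "synthetic", ce = 1000,
                        true_recovery = 0.13, loss = 0,
                        pellet_fraction = 0.5,
                        fold_excess_elution = 10000,
                        efficiency = 0.6, seed = 1L) {
  set.seed(substream_seed(seed, "amounts"))
  e <- ce * true_recovery
  p <- ce * (1 - loss) * pellet_fraction
  sup <- ce * (1 - loss) * (1 - pellet_fraction)
  b <- 0.02 * e
  ft <- max(ce - e - b, 0)
  amounts <- c(CE = ce, P = p, SUP = sup, FT_igg = ft, E_igg = e, B_igg = b)
  rec <- ce
  nonrec <- rec * (1 - efficiency) / efficiency
  list(amounts = fraction_amounts(
         domain_name, amounts,
         pdc1_amounts = c(E_igg = e / fold_excess_elution),
         recombined = rec, nonrecombined = nonrec),
       truth = list(recovery = true_recovery, loss = loss,
                    fold_excess_elution = fold_excess_elution,
                    efficiency = efficiency))
}
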