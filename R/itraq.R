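## Comparative iTRAQ enrichment analysis.
##
## Per replicate, each protein's ratio (domain channel / control channel)
## is background-corrected by the mean ratio of housekeeping + ribosomal
## proteins, then averaged over the replicates in which the protein was
## identified and called against tiered ratio/peptide-count thresholds.

TIER_LEVELS <- c("STRICT", "RELAXED_A", "RELAXED_B", "NONE")

#' Default enrichment thresholds
#'
#' Strict calls require a background-corrected average ratio of at least
#' 1.5 with at least 2 peptides; the relaxed tiers lower either the
#' peptide count (to 1) or the ratio bound (to strictly greater than 1
#' with at least 2 peptides).
#'
#' @return Named list of thresholds.
#' @export
enrichment_thresholds <- function() {
  list(ratio_strict = 1.5, peptides_strict = 2L,
       peptides_relaxed = 1L, ratio_relaxed = 1.0)
}

#' Per-protein iTRAQ ratios from peptide intensities
#'
#' For every (protein, replicate), peptide-level ratios
#' domain/control are aggregated (median by default; the median is robust
#' to single aberrant peptides, the mean is available). Peptides with a
#' zero control or domain intensity carry no defined ratio and are
#' dropped; proteins whose peptides all lack a usable ratio in a
#' replicate are excluded from that replicate with a warning.
#'
#' @param quant `quant_table`.
#' @param domain_channel,control_channel channel column labels.
#' @param aggregation `"median"` (default) or `"mean"`.
#' @return Data frame: `protein_id`, `replicate_id`, `raw_ratio`,
#'   `n_peptides`.
#' @export
protein_ratio_from_peptides <- function(quant, domain_channel,
                                        control_channel,
                                        aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(quant, "quant_table"))
  channels <- attr(quant, "channels")
  if (!all(c(domain_channel, control_channel) %in% channels))
    stop("channel(s) not present in quant table: ",
         paste(setdiff(c(domain_channel, control_channel), channels),
               collapse = ", "))
  agg <- if (aggregation == "median") stats::median else mean
  dom <- quant[[domain_channel]]
  ctl <- quant[[control_channel]]
  usable <- ctl > 0 & dom > 0
  grp <- interaction(quant$replicate_id, quant$protein_id, drop = TRUE)
  n_dropped_prot <- 0L
  rows <- lapply(split(seq_len(nrow(quant)), grp), function(idx) {
    ok <- idx[usable[idx]]
    if (!length(ok)) {
      n_dropped_prot <<- n_dropped_prot + 1L
      return(NULL)
    }
    data.frame(protein_id = quant$protein_id[idx[1]],
               replicate_id = quant$replicate_id[idx[1]],
               raw_ratio = agg(dom[ok] / ctl[ok]),
               n_peptides = length(ok), stringsAsFactors = FALSE)
  })
  if (n_dropped_prot > 0L)
    warning(n_dropped_prot,
            " (protein, replicate) group(s) without usable control",
            " intensity excluded")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$replicate_id, out$protein_id), , drop = FALSE]
}

#' Background normalization factor for one replicate
#'
#' Arithmetic mean of the raw ratios of all background proteins
#' (housekeeping + ribosomal) identified in the replicate. Dividing every
#' ratio in the replicate by this factor centres the background cluster
#' at 1.
#'
#' @param ratios output of [protein_ratio_from_peptides()].
#' @param annotation `annotation_table`.
#' @param replicate_id replicate to use.
#' @return Scalar factor.
#' @export
background_factor <- function(ratios, annotation, replicate_id) {
  stopifnot(inherits(annotation, "annotation_table"))
  bg_ids <- annotation$protein_id[annotation$is_background]
  sel <- ratios$replicate_id == replicate_id & ratios$protein_id %in% bg_ids
  if (!any(sel))
    stop("no background (housekeeping/ribosomal) protein identified in ",
         "replicate '", replicate_id, "'; provide annotation covering ",
         "background proteins")
  mean(ratios$raw_ratio[sel])
}

#' Background-correct ratios and average over replicates
#'
#' Each raw ratio is divided by its replicate's background factor; the
#' per-protein average is the mean of corrected ratios over the
#' replicates in which the protein was identified, and `total_peptides`
#' is the peptide sum over those replicates.
#'
#' @param ratios output of [protein_ratio_from_peptides()].
#' @param annotation `annotation_table`.
#' @param average `"arithmetic"` (default) or `"geometric"` replicate mean.
#' @return Data frame (`enrichment_summary`): `protein_id`, `avg_ratio`,
#'   `total_peptides`, `n_replicates`, `tier` (NA until
#'   [call_enrichment_tier()]).
#' @export
correct_and_summarize <- function(ratios, annotation,
                                  average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  reps <- unique(ratios$replicate_id)
  if (!length(reps)) stop("no replicates in ratio table")
  factors <- vapply(reps, function(r)
    background_factor(ratios, annotation, r), 0)
  corrected <- ratios$raw_ratio /
    factors[match(ratios$replicate_id, reps)]
  avg_fun <- if (average == "arithmetic") mean
             else function(x) exp(mean(log(x)))
  rows <- lapply(split(seq_len(nrow(ratios)), ratios$protein_id),
                 function(idx)
    data.frame(protein_id = ratios$protein_id[idx[1]],
               avg_ratio = avg_fun(corrected[idx]),
               total_peptides = sum(ratios$n_peptides[idx]),
               n_replicates = length(idx), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$tier <- factor(NA, levels = TIER_LEVELS)
  structure(out, class = c("enrichment_summary", "data.frame"))
}

#' Call the enrichment tier
#'
#' Tiers (checked in order):
#' `STRICT` — avg ratio >= 1.5 and >= 2 peptides;
#' `RELAXED_A` — avg ratio >= 1.5 and >= 1 peptide;
#' `RELAXED_B` — avg ratio strictly > 1 and >= 2 peptides;
#' otherwise `NONE`. Boundary inclusivity is exactly as stated (>= at
#' 1.5, strict > at 1.0).
#'
#' @param avg_ratio numeric vector of corrected average ratios, or an
#'   `enrichment_summary` (in which case its `tier` column is filled).
#' @param total_peptides integer vector (ignored when a summary is given).
#' @param thresholds see [enrichment_thresholds()].
#' @return Factor of tiers, or the summary with `tier` set.
#' @export
call_enrichment_tier <- function(avg_ratio, total_peptides = NULL,
                                 thresholds = enrichment_thresholds()) {
  if (inherits(avg_ratio, "enrichment_summary")) {
    s <- avg_ratio
    s$tier <- call_enrichment_tier(s$avg_ratio, s$total_peptides, thresholds)
    return(s)
  }
  t <- thresholds
  tier <- rep("NONE", length(avg_ratio))
  tier[avg_ratio > t$ratio_relaxed & total_peptides >= t$peptides_strict] <-
    "RELAXED_B"
  tier[avg_ratio >= t$ratio_strict & total_peptides >= t$peptides_relaxed] <-
    "RELAXED_A"
  tier[avg_ratio >= t$ratio_strict & total_peptides >= t$peptides_strict] <-
    "STRICT"
  factor(tier, levels = TIER_LEVELS)
}

#' Summarize a protein complex
#'
#' Coverage is the fraction of annotated subunits whose tier is at least
#' `qualifying_tier`; the complex is depicted when coverage reaches
#' `coverage_threshold` (default 50%). Ratio and peptide averages are
#' over identified subunits only.
#'
#' @param complex_name name.
#' @param members character vector of annotated subunit proteins (>= 2).
#' @param summaries tier-called `enrichment_summary`.
#' @param qualifying_tier worst tier that counts as passing
#'   (default `"RELAXED_B"`, i.e. any tier).
#' @param coverage_threshold minimum passing fraction (default 0.5).
#' @return One-row data frame: `complex_name`, `n_annotated`, `n_passing`,
#'   `coverage`, `avg_ratio`, `avg_peptides`, `n_identified`, `depicted`.
#' @export
summarize_complex <- function(complex_name, members, summaries,
                              qualifying_tier = "RELAXED_B",
                              coverage_threshold = 0.5) {
  if (length(members) < 2L)
    stop("complex '", complex_name, "' must have >= 2 annotated members")
  qualifying_tier <- match.arg(qualifying_tier, TIER_LEVELS[1:3])
  idx <- match(members, summaries$protein_id)
  found <- !is.na(idx)
  tiers <- summaries$tier[idx[found]]
  passing <- as.integer(tiers) <= match(qualifying_tier, TIER_LEVELS)
  n_pass <- sum(passing)
  coverage <- n_pass / length(members)
  identified <- idx[found]
  data.frame(
    complex_name = complex_name,
    n_annotated = length(members),
    n_passing = n_pass,
    coverage = coverage,
    avg_ratio = if (length(identified)) mean(summaries$avg_ratio[identified])
                else NA_real_,
    avg_peptides = if (length(identified))
                     mean(summaries$total_peptides[identified])
                   else NA_real_,
    n_identified = length(identified),
    depicted = coverage >= coverage_threshold,
    stringsAsFactors = FALSE)
}

#' Summarize all complexes
#'
#' @param complexes named list: complex -> member proteins (from
#'   [read_complexes()] or annotation).
#' @param summaries tier-called `enrichment_summary`.
#' @param ... passed to [summarize_complex()].
#' @return Data frame, one row per complex.
#' @export
summarize_complexes <- function(complexes, summaries, ...) {
  out <- do.call(rbind, lapply(names(complexes), function(cx)
    summarize_complex(cx, complexes[[cx]], summaries, ...)))
  rownames(out) <- NULL
  out
}

#' Functional-class composition of an identified proteome
#'
#' Fraction of identified proteins per functional class; proteins absent
#' from the annotation count as `"other"`. Fractions sum to 1.
#'
#' @param summaries `enrichment_summary` (or any data frame with
#'   `protein_id`).
#' @param annotation `annotation_table`.
#' @return Named numeric vector of fractions.
#' @export
functional_composition <- function(summaries, annotation) {
  cls <- annotation$functional_class[match(summaries$protein_id,
                                           annotation$protein_id)]
  cls[is.na(cls)] <- "other"
  tab <- table(cls)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Run the full iTRAQ enrichment pipeline
#'
#' Ratio computation, background correction, replicate averaging, tier
#' calling, complex summaries and functional composition in one call.
#'
#' @param quant `quant_table` covering all replicates.
#' @param annotation `annotation_table`.
#' @param domain_channel,control_channel channel labels.
#' @param complexes optional named list of complex memberships.
#' @param thresholds see [enrichment_thresholds()].
#' @param aggregation peptide-to-protein aggregation, see
#'   [protein_ratio_from_peptides()].
#' @param average replicate averaging, see [correct_and_summarize()].
#' @param ... passed to [summarize_complexes()].
#' @return List with `proteins` (tier-called summary), `complexes`
#'   (or NULL), `composition`.
#' @export
itraq_enrichment <- function(quant, annotation, domain_channel,
                             control_channel, complexes = NULL,
                             thresholds = enrichment_thresholds(),
                             aggregation = "median",
                             average = "arithmetic", ...) {
  ratios <- protein_ratio_from_peptides(quant, domain_channel,
                                        control_channel, aggregation)
  summaries <- correct_and_summarize(ratios, annotation, average)
  summaries <- call_enrichment_tier(summaries, thresholds = thresholds)
  cls <- annotation$functional_class[match(summaries$protein_id,
                                           annotation$protein_id)]
  summaries$functional_class <- ifelse(is.na(cls), "other", cls)
  list(proteins = summaries,
       complexes = if (!is.null(complexes))
         summarize_complexes(complexes, summaries, ...) else NULL,
       composition = functional_composition(summaries, annotation))
}
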