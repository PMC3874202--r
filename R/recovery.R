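## Purification-recovery accounting: recovery percentages, fold-excess
## over the PDC1 reference locus, recombination efficiency, mass-balance
## QC, restriction-accessibility normalization and ChIP percent-of-input.

#' Recovery of a domain in an elution fraction
#'
#' 100 x elution / cellular extract, reported both unrounded and as the
#' round-half-up integer percent used in tabular presentation.
#'
#' @param amounts `fraction_amounts`.
#' @param elution_label `"E_igg"` (default) or `"E_cam"`.
#' @return List: `percent` (integer), `percent_unrounded`.
#' @export
#' @examples
#' a <- fraction_amounts("demo", c(CE = 1234, E_igg = 161))
#' recovery_percent(a)$percent  # 13
recovery_percent <- function(amounts, elution_label = "E_igg") {
  stopifnot(inherits(amounts, "fraction_amounts"))
  ce <- amounts$amounts[["CE"]]
  if (is.na(ce) || ce <= 0) stop("recovery undefined: CE must be > 0")
  if (!(elution_label %in% names(amounts$amounts)))
    stop("elution fraction '", elution_label, "' not present for domain ",
         amounts$domain_name)
  e <- amounts$amounts[[elution_label]]
  pct <- 100 * e / ce
  list(percent = as.integer(round_half_up(pct)), percent_unrounded = pct)
}

#' Fold excess of a domain over the reference locus
#'
#' Quotient of domain amount over reference (PDC1) amount in the same
#' fraction.
#'
#' @param domain_amount fmoles of the domain.
#' @param reference_amount fmoles of the reference locus (> 0).
#' @return Dimensionless ratio (vectorized).
#' @export
fold_excess <- function(domain_amount, reference_amount) {
  if (any(reference_amount <= 0))
    stop("reference amount must be > 0")
  domain_amount / reference_amount
}

#' Recombination efficiency
#'
#' Default `fraction_of_total` mode reports 100 x rec / (rec + nonrec),
#' which is bounded by 100%. The `literal` mode reports the raw quotient
#' 100 x rec / nonrec, which is not.
#'
#' @param recombined,nonrecombined fmoles.
#' @param mode `"fraction_of_total"` (default) or `"literal"`.
#' @return Percent.
#' @export
#' @examples
#' recombination_efficiency(55, 45)            # 55
#' recombination_efficiency(1, 1, "literal")   # 100
recombination_efficiency <- function(recombined, nonrecombined,
                                     mode = c("fraction_of_total",
                                              "literal")) {
  mode <- match.arg(mode)
  if (recombined + nonrecombined <= 0)
    stop("recombined + nonrecombined must be > 0")
  if (mode == "fraction_of_total")
    100 * recombined / (recombined + nonrecombined)
  else {
    if (nonrecombined <= 0)
      stop("literal mode undefined: nonrecombined must be > 0")
    100 * recombined / nonrecombined
  }
}

#' Mass-balance QC over extraction fractions
#'
#' Flags (informationally, never fatally) when pellet + supernatant
#' deviates from the cellular extract by more than `tolerance`
#' (relative, default 0.25 — blot quantification is noisy).
#'
#' @param amounts `fraction_amounts` with CE, P and SUP.
#' @param tolerance relative deviation threshold.
#' @return List: `pass`, `relative_deviation`, `flags` (character).
#' @export
mass_balance_qc <- function(amounts, tolerance = 0.25) {
  stopifnot(inherits(amounts, "fraction_amounts"))
  need <- c("CE", "P", "SUP")
  if (!all(need %in% names(amounts$amounts)))
    stop("mass balance needs CE, P and SUP amounts")
  ce <- amounts$amounts[["CE"]]
  dev <- abs(amounts$amounts[["P"]] + amounts$amounts[["SUP"]] - ce) / ce
  pass <- dev <= tolerance
  list(pass = pass, relative_deviation = dev,
       flags = if (pass) character()
               else sprintf("mass_balance: |P+SUP-CE|/CE = %.3f > %.2f",
                            dev, tolerance))
}

#' Normalize a restriction-accessibility series
#'
#' Cut fractions are expressed as a percentage of the cut fraction at
#' the highest enzyme amount, which is by construction 100%.
#'
#' @param enzyme_amount enzyme units per point.
#' @param cut_fraction fraction of DNA cut, in \[0, 1\].
#' @return Data frame: `enzyme_amount`, `cut_fraction`, `normalized_pct`,
#'   ordered by enzyme amount.
#' @export
#' @examples
#' normalized_cut_percent(c(2, 10, 20), c(0.10, 0.25, 0.30))
normalized_cut_percent <- function(enzyme_amount, cut_fraction) {
  stopifnot(length(enzyme_amount) == length(cut_fraction),
            length(enzyme_amount) >= 1L,
            all(cut_fraction >= 0 & cut_fraction <= 1))
  o <- order(enzyme_amount)
  enzyme_amount <- enzyme_amount[o]; cut_fraction <- cut_fraction[o]
  ref <- cut_fraction[length(cut_fraction)]
  if (ref <= 0)
    stop("cut fraction at the highest enzyme amount must be > 0")
  data.frame(enzyme_amount = enzyme_amount, cut_fraction = cut_fraction,
             normalized_pct = 100 * cut_fraction / ref)
}

#' ChIP percent of input
#'
#' 100 x IP signal / (input signal x input dilution factor).
#'
#' @param ip_signal immunoprecipitated signal.
#' @param input_signal diluted total-input signal (> 0).
#' @param input_dilution_factor dilution of the input aliquot (default 1).
#' @return Percent (vectorized).
#' @export
percent_of_input <- function(ip_signal, input_signal,
                             input_dilution_factor = 1) {
  if (any(input_signal <= 0)) stop("input signal must be > 0")
  if (any(input_dilution_factor <= 0))
    stop("input dilution factor must be > 0")
  100 * ip_signal / (input_signal * input_dilution_factor)
}

#' Full recovery report for one domain
#'
#' Recovery per available elution fraction, fold-excess over the
#' reference locus per fraction where reference amounts exist,
#' recombination efficiency (when recombined/non-recombined amounts are
#' present; reported as NA otherwise) and mass-balance QC flags.
#'
#' @param amounts `fraction_amounts`.
#' @param efficiency_mode see [recombination_efficiency()].
#' @param qc_tolerance see [mass_balance_qc()].
#' @return `recovery_report` list.
#' @export
recovery_report <- function(amounts,
                            efficiency_mode = "fraction_of_total",
                            qc_tolerance = 0.25) {
  stopifnot(inherits(amounts, "fraction_amounts"))
  elutions <- intersect(c("E_igg", "E_cam"), names(amounts$amounts))
  rec <- lapply(elutions, function(e) recovery_percent(amounts, e))
  names(rec) <- elutions
  fx <- NULL
  if (!is.null(amounts$pdc1_amounts)) {
    common <- intersect(names(amounts$amounts),
                        names(amounts$pdc1_amounts))
    fx <- stats::setNames(
      fold_excess(amounts$amounts[common], amounts$pdc1_amounts[common]),
      common)
  }
  eff <- if (!is.na(amounts$recombined) && !is.na(amounts$nonrecombined))
    recombination_efficiency(amounts$recombined, amounts$nonrecombined,
                             efficiency_mode)
  else NA_real_
  qc <- if (all(c("CE", "P", "SUP") %in% names(amounts$amounts)))
    mass_balance_qc(amounts, qc_tolerance)
  else list(pass = NA, relative_deviation = NA_real_,
            flags = "mass_balance: not computable (missing fraction)")
  structure(list(domain_name = amounts$domain_name,
                 recovery = rec, fold_excess = fx,
                 efficiency_pct = eff, efficiency_mode = efficiency_mode,
                 qc = qc),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report:", x$domain_name, "\n")
  for (e in names(x$recovery))
    cat(sprintf("  %s recovery: %d%% (%.3f%%)\n", e,
                x$recovery[[e]]$percent,
                x$recovery[[e]]$percent_unrounded))
  if (!is.null(x$fold_excess))
    for (f in names(x$fold_excess))
      cat(sprintf("  fold excess over reference (%s): %.0f\n", f,
                  x$fold_excess[[f]]))
  if (!is.na(x$efficiency_pct))
    cat(sprintf("  recombination efficiency (%s): %.0f%%\n",
                x$efficiency_mode, x$efficiency_pct))
  if (isFALSE(x$qc$pass)) cat("  QC:", x$qc$flags, "\n")
  invisible(x)
}
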