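## Propionylation-aware histone PTM quantification from centroided MALDI
## peak lists.
##
## Chemistry assumed throughout: propionic-anhydride derivatization before
## trypsin digestion propionylates free and monomethylated lysines and the
## peptide N-terminus. Cleavage therefore occurs after arginine only
## (Arg-C-like; never before proline), and every lysine carries one of
## {propionyl, acetyl, me1+propionyl, me2, me3}. Only mass bins are
## resolved at the MS1 level: positional isomers with the same state
## multiset are grouped.

SITE_STATES <- c("prop", "ac", "me1+prop", "me2", "me3")

#' In-silico digest of a derivatized histone
#'
#' Cleaves after R only (all K blocked by propionylation or endogenous
#' modification), never before P. Ranges are 1-based inclusive in histone
#' numbering.
#'
#' @param seq `histone_sequence`.
#' @param max_missed maximum missed cleavages (default 0).
#' @return Data frame: `start`, `end`, `peptide`.
#' @export
#' @examples
#' d <- derivatized_digest(histone_sequence("H4"))
#' d[d$start == 4 & d$end == 17, ]
derivatized_digest <- function(seq, max_missed = 0L) {
  stopifnot(inherits(seq, "histone_sequence"))
  res <- strsplit(seq$residues, "")[[1]]
  n <- length(res)
  ## cut after position i when res[i] == R and res[i+1] != P
  cuts <- which(res == "R" & c(res[-1], "") != "P")
  bounds <- c(0L, cuts[cuts < n], n)
  starts0 <- bounds[-length(bounds)] + 1L
  ends0 <- bounds[-1]
  rows <- list()
  for (i in seq_along(starts0)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > length(ends0)) break
      rows[[length(rows) + 1L]] <- c(starts0[i], ends0[j])
    }
  }
  m <- do.call(rbind, rows)
  off <- seq$numbering_offset - 1L
  data.frame(start = m[, 1] + off, end = m[, 2] + off,
             peptide = vapply(seq_len(nrow(m)), function(k)
               paste(res[m[k, 1]:m[k, 2]], collapse = ""), ""),
             stringsAsFactors = FALSE)
}

#' Enumerate mass-distinct modification forms of a peptide
#'
#' All multisets of lysine site states from `alphabet` are enumerated
#' (positional isomers are mass-degenerate and collapse to one multiset),
#' then grouped into mass bins at `bin_decimals` decimal places with
#' composition labels such as `"2ac+2prop"`. A peptide without lysines
#' yields the single (N-terminally derivatized) form.
#'
#' @param peptide peptide string.
#' @param alphabet subset of
#'   `c("prop", "ac", "me1+prop", "me2", "me3")`.
#' @param nterm `"prop"` (derivatized, default) or `"free"`.
#' @param bin_decimals mass-rounding used to merge degenerate
#'   compositions (default 4).
#' @return Data frame (`modform_table`): `bin`, `composition`,
#'   `mono_mass`, `mz_mh`, `n_forms` (number of state multisets in the
#'   bin).
#' @export
#' @examples
#' enumerate_modforms("GKGGKGLGKGGAKR", c("prop", "ac"))
enumerate_modforms <- function(peptide, alphabet = SITE_STATES,
                               nterm = c("prop", "free"),
                               bin_decimals = 4L) {
  nterm <- match.arg(nterm)
  if (!length(alphabet) || !all(alphabet %in% SITE_STATES))
    stop("alphabet must be a nonempty subset of: ",
         paste(SITE_STATES, collapse = ", "))
  n_k <- sum(strsplit(peptide, "")[[1]] == "K")
  base <- peptide_mono_mass(peptide) +
    if (nterm == "prop") MOD_DELTAS[["prop"]] else 0
  ## multisets of size n_k over the alphabet: counts per state
  combos <- if (n_k == 0L) {
    matrix(integer(), nrow = 1, ncol = length(alphabet))
  } else {
    as.matrix(expand_multisets(n_k, length(alphabet)))
  }
  colnames(combos) <- alphabet
  masses <- base + as.numeric(combos %*% mod_delta(alphabet))
  label <- apply(combos, 1, function(cnt) {
    parts <- paste0(cnt[cnt > 0], names(cnt)[cnt > 0])
    if (!length(parts)) "unmod" else paste(parts, collapse = "+")
  })
  key <- round(masses, bin_decimals)
  ord <- order(key)
  key <- key[ord]; masses <- masses[ord]; label <- label[ord]
  grp <- match(key, unique(key))
  out <- data.frame(
    bin = vapply(split(label, grp), function(l) paste(l, collapse = "|"), ""),
    composition = vapply(split(label, grp), function(l)
      paste(l, collapse = "|"), ""),
    mono_mass = vapply(split(masses, grp), function(m) m[1], 0),
    mz_mh = vapply(split(masses, grp), function(m) m[1], 0) + MASS_PROTON,
    n_forms = as.integer(table(grp)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "peptide") <- peptide
  out
}

## counts of each of k states summing to n (multiset enumeration)
expand_multisets <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (first in 0:n) {
    rest <- expand_multisets(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Theoretical singly protonated m/z of a modified peptide
#'
#' \[M+H\]+ = sum of residue monoisotopic masses + water + modification
#' deltas + proton.
#'
#' @param peptide peptide string.
#' @param site_states character vector of lysine states (one per K), or a
#'   named count vector; states among
#'   `c("prop", "ac", "me1+prop", "me2", "me3", "none")`.
#' @param nterm `"prop"` or `"free"`.
#' @return m/z in Da.
#' @export
#' @examples
#' theoretical_mz("G", nterm = "free")  # 76.0393
theoretical_mz <- function(peptide, site_states = character(),
                           nterm = c("prop", "free")) {
  nterm <- match.arg(nterm)
  peptide_mono_mass(peptide) + sum(mod_delta(site_states)) +
    (if (nterm == "prop") MOD_DELTAS[["prop"]] else 0) + MASS_PROTON
}

#' Match recalibration anchor peptides in a peak list
#'
#' @param pl `peaklist`.
#' @param anchor_mz numeric vector of theoretical anchor \[M+H\]+ values.
#' @param tolerance coarse match tolerance in Da (default 0.5).
#' @return Data frame `theoretical`, `observed` for the anchors found.
#' @export
match_anchors <- function(pl, anchor_mz, tolerance = 0.5) {
  rows <- lapply(anchor_mz, function(tz) {
    d <- abs(pl$mz - tz)
    i <- which.min(d)
    if (length(i) && d[i] <= tolerance)
      data.frame(theoretical = tz, observed = pl$mz[i])
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(theoretical = numeric(),
                               observed = numeric()) else out
}

#' Recalibrate a peak list against anchor peptides
#'
#' With two or more anchors a linear map observed -> theoretical is fit by
#' least squares and applied to every m/z; with one anchor an offset-only
#' correction is applied; with none the list is returned unchanged with a
#' warning.
#'
#' @param pl `peaklist`.
#' @param anchors data frame `theoretical`, `observed` (see
#'   [match_anchors()]).
#' @return Recalibrated `peaklist`.
#' @export
recalibrate <- function(pl, anchors) {
  stopifnot(inherits(pl, "peaklist"))
  n <- nrow(anchors)
  if (n == 0L) {
    warning("no anchor matched; recalibration skipped for spot ",
            attr(pl, "spot_id"))
    return(pl)
  }
  if (n == 1L) {
    shift <- anchors$theoretical - anchors$observed
    newmz <- pl$mz + shift
  } else {
    fit <- stats::lm(theoretical ~ observed, data = anchors)
    newmz <- unname(stats::predict(fit,
                                   newdata = data.frame(observed = pl$mz)))
  }
  peaklist(attr(pl, "spot_id"), newmz, pl$intensity,
           window = attr(pl, "window"))
}

#' Assign peaks to modification-form mass bins
#'
#' Bins whose theoretical masses lie closer than `2 * tolerance` are
#' merged into ambiguity groups (e.g. acetyl vs trimethyl, 0.0364 Da
#' apart) and quantified jointly. Each group receives the intensity of
#' the nearest peak within `tolerance`, else 0. A peak equidistant
#' between two non-merged groups raises an error.
#'
#' @param pl recalibrated `peaklist`.
#' @param modforms `modform_table` from [enumerate_modforms()].
#' @param tolerance match tolerance in Da (default 0.15, half of a
#'   typical 0.3-Da parent-selection window).
#' @return Data frame: `group` (merged bin label), `mz_mh`, `intensity`,
#'   `n_bins_merged`.
#' @export
assign_peaks <- function(pl, modforms, tolerance = 0.15) {
  stopifnot(inherits(pl, "peaklist"))
  mf <- modforms[order(modforms$mz_mh), , drop = FALSE]
  ## merge chains of bins closer than 2 * tolerance
  grp <- cumsum(c(1, diff(mf$mz_mh) >= 2 * tolerance))
  groups <- split(seq_len(nrow(mf)), grp)
  out <- lapply(groups, function(idx) {
    gm <- mean(mf$mz_mh[idx])
    lab <- paste(mf$bin[idx], collapse = " / ")
    data.frame(group = lab, mz_mh = gm, n_bins_merged = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$intensity <- 0
  if (nrow(pl)) {
    ## peak-centric: each peak belongs to its nearest group (ties within
    ## tolerance are an error); each group takes its nearest owned peak
    ## within tolerance, else 0
    dist <- abs(outer(pl$mz, out$mz_mh, "-"))
    owner <- apply(dist, 1, which.min)
    for (p in seq_len(nrow(pl))) {
      d <- dist[p, ]
      if (sum(d == min(d)) > 1L && min(d) <= tolerance)
        stop("peak at m/z ", format(pl$mz[p]),
             " is equidistant between two mass bins")
    }
    for (g in seq_len(nrow(out))) {
      cand <- which(owner == g & dist[, g] <= tolerance)
      if (length(cand))
        out$intensity[g] <- pl$intensity[cand[which.min(dist[cand, g])]]
    }
  }
  attr(out, "peptide") <- attr(modforms, "peptide")
  out
}

#' Modification proportions from peak assignments
#'
#' Proportion of each modification form = its assigned intensity divided
#' by the summed intensity over all forms of the same peptide. A peptide
#' with no assigned signal is reported as not detected (zero rows).
#'
#' @param assignments output of [assign_peaks()].
#' @return Data frame (`proportion_table`): `group`, `proportion`;
#'   attribute `detected`.
#' @export
modification_proportions <- function(assignments) {
  tot <- sum(assignments$intensity)
  if (tot <= 0) {
    out <- data.frame(group = character(), proportion = numeric())
    attr(out, "detected") <- FALSE
    return(out)
  }
  out <- data.frame(group = assignments$group,
                    proportion = assignments$intensity / tot,
                    stringsAsFactors = FALSE)
  attr(out, "detected") <- TRUE
  out
}

#' Average proportions over MALDI spot replicas
#'
#' Unweighted mean per form over the replicas in which the peptide was
#' detected, renormalized to sum to 1.
#'
#' @param tables list of proportion tables from
#'   [modification_proportions()].
#' @return Averaged proportion table.
#' @export
average_replicas <- function(tables) {
  det <- Filter(function(t) isTRUE(attr(t, "detected")) && nrow(t) > 0,
                tables)
  if (!length(det)) stop("peptide not detected in any replica")
  groups <- det[[1]]$group
  for (t in det) if (!identical(t$group, groups))
    stop("replica proportion tables disagree on mass-bin groups")
  m <- rowMeans(vapply(det, function(t) t$proportion,
                       numeric(length(groups))))
  out <- data.frame(group = groups, proportion = m / sum(m),
                    stringsAsFactors = FALSE)
  attr(out, "detected") <- TRUE
  out
}

#' Full histone-PTM quantification pipeline for one peptide
#'
#' Recalibrates each spot's peak list against anchor peptides, assigns
#' peaks to the peptide's modification-form bins, computes per-spot
#' proportions and averages the replicas.
#'
#' @param peaklists list of `peaklist` objects (spot replicas).
#' @param histone `histone_sequence`.
#' @param peptide_range `c(start, end)` residue numbers of the quantified
#'   peptide (e.g. `c(4, 17)` for the H4 N-terminal tail).
#' @param alphabet lysine site-state alphabet.
#' @param anchor_ranges list of `c(start, end)` anchor peptides (default:
#'   H4 46–55 and 79–92 style pairs must be supplied by the caller).
#' @param tolerance assignment tolerance in Da.
#' @param anchor_tolerance coarse anchor-match tolerance in Da.
#' @param calibration `"linear"` (default) or `"offset"`; offset mode
#'   uses only the first matched anchor.
#' @return List: `modforms`, `per_spot` (list of proportion tables),
#'   `averaged`.
#' @export
histone_ptm_pipeline <- function(peaklists, histone, peptide_range,
                                 alphabet = c("prop", "ac"),
                                 anchor_ranges = list(),
                                 tolerance = 0.15, anchor_tolerance = 0.5,
                                 calibration = c("linear", "offset")) {
  calibration <- match.arg(calibration)
  digest <- derivatized_digest(histone)
  pick <- function(rng) {
    hit <- digest$start == rng[1] & digest$end == rng[2]
    if (!any(hit)) stop("peptide ", rng[1], "-", rng[2],
                        " not produced by the derivatized digest")
    digest$peptide[hit][1]
  }
  pep <- pick(peptide_range)
  modforms <- enumerate_modforms(pep, alphabet)
  anchor_mz <- vapply(anchor_ranges, function(rng) {
    p <- pick(rng)
    nk <- sum(strsplit(p, "")[[1]] == "K")
    theoretical_mz(p, rep("prop", nk))
  }, 0)
  per_spot <- lapply(peaklists, function(pl) {
    if (length(anchor_mz)) {
      anch <- match_anchors(pl, anchor_mz, anchor_tolerance)
      if (calibration == "offset" && nrow(anch) > 1L)
        anch <- anch[1, , drop = FALSE]
      pl <- recalibrate(pl, anch)
    }
    modification_proportions(assign_peaks(pl, modforms, tolerance))
  })
  list(modforms = modforms, per_spot = per_spot,
       averaged = average_replicas(per_spot))
}
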