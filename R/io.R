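## Validated TSV readers/writers for all pipeline inputs and outputs.
## Conventions: every table is TSV with a one-line header; coordinates are
## 0-based half-open; circular coordinates are taken modulo the ring length.

BACKGROUND_CLASSES <- c("housekeeping", "ribosomal protein")

FRACTION_LABELS <- c("CE", "P", "SUP",
                     "FT_igg", "E_igg", "B_igg",
                     "FT_cam", "E_cam", "B_cam")

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path, digits = 9) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

## ---- quant tables -----------------------------------------------------

#' Read a peptide-level reporter-intensity table
#'
#' The TSV has columns `replicate`, `protein`, `peptide` followed by one
#' column per reporter channel (free channel labels, e.g. `114`, `115`).
#' Intensities must be nonnegative and each (replicate, protein, peptide)
#' triple unique.
#'
#' @param path TSV file.
#' @return A `quant_table`: data frame with columns `replicate_id`,
#'   `protein_id`, `peptide_seq` and one numeric column per channel;
#'   attribute `channels` lists the channel labels.
#' @export
read_quant_table <- function(path) {
  df <- read_tsv_checked(path, c("replicate", "protein", "peptide"))
  channels <- setdiff(names(df), c("replicate", "protein", "peptide"))
  if (length(channels) < 2L)
    stop("quant table must declare at least 2 channel columns")
  names(df)[match(c("replicate", "protein", "peptide"), names(df))] <-
    c("replicate_id", "protein_id", "peptide_seq")
  for (ch in channels) df[[ch]] <- as.numeric(df[[ch]])
  quant_table(df, channels)
}

#' Construct and validate a quant_table
#'
#' @param df data frame with columns `replicate_id`, `protein_id`,
#'   `peptide_seq` plus one numeric column per channel.
#' @param channels character vector of channel column names.
#' @return Validated `quant_table`.
#' @export
quant_table <- function(df, channels) {
  stopifnot(all(c("replicate_id", "protein_id", "peptide_seq") %in% names(df)),
            all(channels %in% names(df)), length(channels) >= 2L)
  for (ch in channels) {
    v <- df[[ch]]
    if (anyNA(v)) stop("NA intensity in channel ", ch)
    if (any(v < 0)) {
      row <- which(v < 0)[1]
      stop("negative intensity in channel ", ch, " at row ", row)
    }
  }
  key <- paste(df$replicate_id, df$protein_id, df$peptide_seq, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (replicate, protein, peptide) row(s), first at row ",
         which(duplicated(key))[1])
  structure(df, channels = channels, class = c("quant_table", "data.frame"))
}

#' Write a quant_table to TSV
#' @param x `quant_table`.
#' @param path output file.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  df <- as.data.frame(x)
  names(df)[match(c("replicate_id", "protein_id", "peptide_seq"),
                  names(df))] <- c("replicate", "protein", "peptide")
  write_tsv(df, path)
}

## ---- annotation -------------------------------------------------------

#' Read a protein annotation table
#'
#' TSV columns: `protein`, `class`, optional `complexes`
#' (semicolon-separated complex names). Proteins of class `housekeeping`
#' or `ribosomal protein` are flagged as background (the set used for
#' iTRAQ ratio normalization). Classes outside `taxonomy` are mapped to
#' `"other"` with a warning.
#'
#' @param path TSV file.
#' @param taxonomy character vector of accepted functional classes;
#'   `NULL` (default) accepts any class.
#' @return `annotation_table`: data frame with `protein_id`,
#'   `functional_class`, `complexes` (list column) and `is_background`.
#' @export
read_annotation <- function(path, taxonomy = NULL) {
  df <- read_tsv_checked(path, c("protein", "class"))
  complexes <- if ("complexes" %in% names(df)) {
    lapply(strsplit(as.character(df$complexes), ";", fixed = TRUE),
           function(x) x[nzchar(x)])
  } else rep(list(character()), nrow(df))
  annotation_table(df$protein, df$class, complexes, taxonomy)
}

#' Construct and validate an annotation_table
#'
#' @param protein_id character vector of accessions.
#' @param functional_class character vector of class labels.
#' @param complexes list of character vectors (complex memberships).
#' @param taxonomy accepted classes, or NULL for any.
#' @return `annotation_table` data frame.
#' @export
annotation_table <- function(protein_id, functional_class,
                             complexes = NULL, taxonomy = NULL) {
  protein_id <- as.character(protein_id)
  functional_class <- as.character(functional_class)
  if (is.null(complexes)) complexes <- rep(list(character()),
                                           length(protein_id))
  stopifnot(length(functional_class) == length(protein_id),
            length(complexes) == length(protein_id))
  if (anyDuplicated(protein_id)) stop("duplicate protein annotation")
  if (!is.null(taxonomy)) {
    unknown <- !(functional_class %in% c(taxonomy, BACKGROUND_CLASSES,
                                         "other"))
    if (any(unknown)) {
      warning(sum(unknown), " protein(s) with unknown functional class",
              " mapped to 'other'")
      functional_class[unknown] <- "other"
    }
  }
  if (any(vapply(complexes, function(x) any(!nzchar(x)), logical(1))))
    stop("complex names must be nonempty strings")
  df <- data.frame(protein_id = protein_id,
                   functional_class = functional_class,
                   is_background = functional_class %in% BACKGROUND_CLASSES,
                   stringsAsFactors = FALSE)
  df$complexes <- complexes
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Read complex membership
#'
#' TSV columns `complex`, `protein`.
#'
#' @param path TSV file.
#' @return Named list: complex name -> character vector of member proteins.
#' @export
read_complexes <- function(path) {
  df <- read_tsv_checked(path, c("complex", "protein"))
  lapply(split(as.character(df$protein), df$complex), unique)
}

## ---- peak lists -------------------------------------------------------

#' Construct and validate a centroided peak list
#'
#' @param spot_id spot label.
#' @param mz numeric vector of m/z values (Da).
#' @param intensity nonnegative intensities.
#' @param window optional `c(mz_min, mz_max)` acquisition window.
#' @return `peaklist` object (data frame `mz`, `intensity` with attributes).
#' @export
peaklist <- function(spot_id, mz, intensity, window = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity")
  if (is.unsorted(mz, strictly = TRUE) && length(mz) > 1L) {
    warning("m/z not strictly increasing in spot ", spot_id, "; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) stop("duplicate m/z values in spot ", spot_id)
  }
  if (is.null(window))
    window <- if (length(mz)) range(mz) + c(-1, 1) else c(1, Inf)
  if (!(length(window) == 2L && all(window > 0) && window[1] < window[2]))
    stop("invalid acquisition window")
  structure(data.frame(mz = mz, intensity = intensity),
            spot_id = spot_id, window = window,
            class = c("peaklist", "data.frame"))
}

#' Read centroided peak lists
#'
#' TSV columns `spot`, `mz`, `intensity`; one `peaklist` per spot.
#'
#' @param path TSV file.
#' @return List of `peaklist` objects, named by spot.
#' @export
read_peaklists <- function(path) {
  df <- read_tsv_checked(path, c("spot", "mz", "intensity"))
  if (nrow(df) == 0L) {
    warning("empty peak list file: ", path)
    return(list())
  }
  spots <- split(df, df$spot)
  out <- lapply(names(spots), function(s)
    peaklist(s, as.numeric(spots[[s]]$mz), as.numeric(spots[[s]]$intensity)))
  names(out) <- names(spots)
  out
}

## ---- molecules --------------------------------------------------------

#' Construct and validate a single-molecule table
#'
#' One row per molecule; `bubbles` is a list column of two-column matrices
#' of (start, end) single-stranded bubble intervals, 0-based half-open in
#' the molecule's unit. On circular molecules an interval with end < start
#' wraps through the origin. Overlapping bubbles on one molecule are
#' rejected.
#'
#' @param molecule_id identifiers.
#' @param total_length lengths (bp or nm).
#' @param unit `"bp"` or `"nm"` (single value).
#' @param topology `"circular"` or `"linear"` per molecule.
#' @param bubbles list of n-by-2 matrices (possibly 0-row).
#' @return `molecule_table` data frame.
#' @export
molecule_table <- function(molecule_id, total_length, unit, topology,
                           bubbles) {
  unit <- match.arg(unit, c("bp", "nm"))
  n <- length(molecule_id)
  stopifnot(length(total_length) == n, length(bubbles) == n)
  topology <- rep_len(topology, n)
  stopifnot(all(topology %in% c("circular", "linear")))
  for (i in seq_len(n)) {
    b <- bubbles[[i]]
    if (is.null(b) || length(b) == 0L) {
      bubbles[[i]] <- matrix(numeric(), ncol = 2,
                             dimnames = list(NULL, c("start", "end")))
      next
    }
    b <- matrix(as.numeric(b), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    L <- total_length[i]
    if (topology[i] == "linear") {
      ## linear: 0 <= start < end <= L
      if (any(b[, 1] < 0) || any(b[, 2] > L) || any(b[, 2] <= b[, 1]))
        stop("bubble interval outside [0, total_length] or empty on ",
             "linear molecule ", molecule_id[i])
    } else {
      ## circular: both endpoints in [0, L); end < start wraps
      if (any(b < 0) || any(b >= L))
        stop("bubble coordinate outside [0, total_length) for molecule ",
             molecule_id[i])
    }
    if (bubbles_overlap(b, L, topology[i]))
      stop("overlapping bubbles on molecule ", molecule_id[i])
    bubbles[[i]] <- b[order(b[, 1]), , drop = FALSE]
  }
  df <- data.frame(molecule_id = as.character(molecule_id),
                   total_length = as.numeric(total_length),
                   topology = topology, stringsAsFactors = FALSE)
  df$bubbles <- bubbles
  structure(df, unit = unit, class = c("molecule_table", "data.frame"))
}

## bubble occupancy test on the (possibly circular) axis
unroll_bubble <- function(b, L) {
  ## returns list of (start, end) pieces on the linear axis [0, L)
  if (b[2] > b[1]) list(b) else list(c(b[1], L), c(0, b[2]))
}

bubbles_overlap <- function(b, L, topology) {
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    bi <- b[i, ]
    pieces <- c(pieces,
                if (topology == "circular") unroll_bubble(bi, L)
                else list(bi))
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2])
}

#' Read a molecule table
#'
#' TSV columns: `molecule`, `total_length`, `unit` (`nm`|`bp`), `topology`
#' (`circular`|`linear`), `bubble_start`, `bubble_end` — one row per
#' bubble; a molecule without bubbles has a single row with empty
#' bubble fields.
#'
#' @param path TSV file.
#' @return `molecule_table`.
#' @export
read_molecules <- function(path) {
  df <- read_tsv_checked(path, c("molecule", "total_length", "unit",
                                 "topology", "bubble_start", "bubble_end"))
  units <- unique(df$unit)
  if (length(units) != 1L) stop("molecule table mixes units: ",
                                paste(units, collapse = ", "))
  ids <- unique(as.character(df$molecule))
  rows <- split(df, factor(as.character(df$molecule), levels = ids))
  bubbles <- lapply(rows, function(r) {
    s <- suppressWarnings(as.numeric(r$bubble_start))
    e <- suppressWarnings(as.numeric(r$bubble_end))
    keep <- !is.na(s) & !is.na(e)
    cbind(start = s[keep], end = e[keep])
  })
  molecule_table(ids,
                 vapply(rows, function(r) as.numeric(r$total_length[1]), 0),
                 units,
                 vapply(rows, function(r) as.character(r$topology[1]), ""),
                 bubbles)
}

#' Write a molecule table to TSV
#' @param x `molecule_table`.
#' @param path output file.
#' @export
write_molecules <- function(x, path) {
  stopifnot(inherits(x, "molecule_table"))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    b <- x$bubbles[[i]]
    if (nrow(b) == 0L)
      data.frame(molecule = x$molecule_id[i], total_length = x$total_length[i],
                 unit = attr(x, "unit"), topology = x$topology[i],
                 bubble_start = NA_real_, bubble_end = NA_real_)
    else
      data.frame(molecule = x$molecule_id[i], total_length = x$total_length[i],
                 unit = attr(x, "unit"), topology = x$topology[i],
                 bubble_start = b[, 1], bubble_end = b[, 2])
  })
  write_tsv(do.call(rbind, rows), path)
}

## ---- feature map ------------------------------------------------------

#' Construct a ring feature map
#'
#' @param ring_length ring length in bp.
#' @param features data frame with `name`, `start`, `end` (0-based
#'   half-open, bp).
#' @param cut_site bp position of the linearizing restriction site.
#' @return `feature_map` object.
#' @export
feature_map <- function(ring_length, features, cut_site) {
  stopifnot(ring_length > 0, cut_site >= 0, cut_site < ring_length,
            all(c("name", "start", "end") %in% names(features)))
  if (any(features$start < 0) || any(features$start >= ring_length) ||
      any(features$end <= features$start))
    stop("feature intervals must be nonempty with 0 <= start < ring_length")
  structure(list(ring_length = ring_length,
                 features = features[, c("name", "start", "end")],
                 cut_site = cut_site),
            class = "feature_map")
}

#' Read a BED-like feature map
#'
#' 3+ column BED-like file (`name` taken from column 4 when present;
#' columns: chrom/ring id, start, end, name). Ring length and cut site
#' come from arguments (configuration, not data).
#'
#' @param path BED-like file (tab-separated, no header).
#' @param ring_length ring length (bp).
#' @param cut_site linearization site (bp).
#' @return `feature_map`.
#' @export
read_feature_map <- function(path, ring_length, cut_site) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("feature map needs >= 3 columns")
  feats <- data.frame(
    name = if (ncol(df) >= 4L) as.character(df[[4]])
           else paste0("feature", seq_len(nrow(df))),
    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]))
  feature_map(ring_length, feats, cut_site)
}

## ---- fraction amounts -------------------------------------------------

#' Construct purification fraction amounts for one domain
#'
#' Amounts are fmoles of domain DNA in each purification fraction
#' (`CE`, `P`, `SUP`, `FT_igg`, `E_igg`, `B_igg`, `FT_cam`, `E_cam`,
#' `B_cam`). Optional companions: reference-locus amounts per fraction
#' (for fold-excess) and recombined/non-recombined amounts (for
#' recombination efficiency).
#'
#' @param domain_name domain label.
#' @param amounts named numeric vector of fmoles, names among the
#'   fraction labels; must contain `CE` and at least one elution.
#' @param pdc1_amounts optional named numeric vector (reference locus).
#' @param recombined,nonrecombined optional fmoles.
#' @return `fraction_amounts` object.
#' @export
fraction_amounts <- function(domain_name, amounts, pdc1_amounts = NULL,
                             recombined = NA_real_,
                             nonrecombined = NA_real_) {
  bad <- setdiff(names(amounts), FRACTION_LABELS)
  if (length(bad)) stop("unknown fraction label(s): ",
                        paste(bad, collapse = ", "))
  if (any(amounts < 0, na.rm = TRUE)) stop("amounts must be >= 0")
  if (!("CE" %in% names(amounts)))
    stop("amounts must include the cellular extract (CE)")
  if (!any(c("E_igg", "E_cam") %in% names(amounts)))
    stop("amounts must include at least one elution fraction")
  if (!is.null(pdc1_amounts)) {
    bad <- setdiff(names(pdc1_amounts), FRACTION_LABELS)
    if (length(bad)) stop("unknown reference fraction label(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(domain_name = domain_name, amounts = amounts,
                 pdc1_amounts = pdc1_amounts, recombined = recombined,
                 nonrecombined = nonrecombined),
            class = "fraction_amounts")
}

#' Read fraction-amount tables
#'
#' TSV columns: `domain`, `locus` (`domain` or `pdc1`), `fraction`
#' (fraction label, or `recombined`/`nonrecombined` for the recombination
#' rows), `fmoles`.
#'
#' @param path TSV file.
#' @return Named list of `fraction_amounts`, one per domain.
#' @export
read_amounts <- function(path) {
  df <- read_tsv_checked(path, c("domain", "locus", "fraction", "fmoles"))
  df$fmoles <- as.numeric(df$fmoles)
  out <- lapply(split(df, df$domain), function(d) {
    dom <- d[d$locus == "domain", ]
    main <- dom[!(dom$fraction %in% c("recombined", "nonrecombined")), ]
    amounts <- stats::setNames(main$fmoles, main$fraction)
    ref <- d[d$locus == "pdc1", ]
    pdc1 <- if (nrow(ref)) stats::setNames(ref$fmoles, ref$fraction) else NULL
    getv <- function(lab) {
      v <- dom$fmoles[dom$fraction == lab]
      if (length(v)) v[1] else NA_real_
    }
    fraction_amounts(d$domain[1], amounts, pdc1,
                     recombined = getv("recombined"),
                     nonrecombined = getv("nonrecombined"))
  })
  out
}

## ---- generic results writer ------------------------------------------

#' Write a results table deterministically
#'
#' Columns are written in their current order; doubles are serialized with
#' 9 significant digits so a write/read round trip reproduces values to
#' within 1e-9 relative.
#'
#' @param results data frame.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as.data.frame(results), path)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(NULL)
}
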