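## Shared fixture builders; all tables are constructed in code.

make_quant_df <- function(rows) {
  ## rows: list of list(rep, prot, pep, ctl, dom)
  do.call(rbind, lapply(rows, function(r)
    data.frame(replicate_id = r[[1]], protein_id = r[[2]],
               peptide_seq = r[[3]], `114` = r[[4]], `115` = r[[5]],
               check.names = FALSE, stringsAsFactors = FALSE)))
}

make_quant <- function(rows) quant_table(make_quant_df(rows), c("114", "115"))

## quant table where protein `prot` has the given peptide-level ratios in
## one replicate (control fixed at 100)
quant_from_ratios <- function(ratios_by_protein, replicate = "rep1") {
  rows <- list()
  for (p in names(ratios_by_protein)) {
    rs <- ratios_by_protein[[p]]
    for (i in seq_along(rs))
      rows[[length(rows) + 1L]] <- list(replicate, p, paste0(p, "_", i),
                                        100, 100 * rs[i])
  }
  make_quant(rows)
}

simple_annotation <- function(proteins, classes) {
  annotation_table(proteins, classes)
}

make_molecules <- function(specs, unit = "bp", topology = "linear") {
  ## specs: named list molecule_id -> list(L, bubbles matrix)
  molecule_table(names(specs),
                 vapply(specs, function(s) s$L, 0),
                 unit,
                 vapply(specs, function(s)
                   if (is.null(s$topology)) topology else s$topology, ""),
                 lapply(specs, function(s) s$bubbles))
}

ring_map <- function(L = 2500, f_start = 1100, f_end = 1221, cut = 50) {
  feature_map(L, data.frame(name = "gene", start = f_start, end = f_end),
              cut_site = cut)
}

## brute-force oracles -------------------------------------------------

## per-protein ratio oracle: plain loops over the raw data frame
oracle_protein_ratios <- function(df, dom = "115", ctl = "114",
                                  agg = stats::median) {
  out <- list()
  for (r in unique(df$replicate_id)) {
    for (p in unique(df$protein_id[df$replicate_id == r])) {
      sel <- df$replicate_id == r & df$protein_id == p
      num <- df[[dom]][sel]; den <- df[[ctl]][sel]
      ok <- den > 0 & num > 0
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        protein_id = p, replicate_id = r,
        raw_ratio = agg(num[ok] / den[ok]), n_peptides = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  o <- do.call(rbind, out)
  o[order(o$replicate_id, o$protein_id), , drop = FALSE]
}

## exhaustive multiset oracle for modform mass bins
oracle_modform_bins <- function(peptide, alphabet, decimals = 4L) {
  ks <- sum(strsplit(peptide, "")[[1]] == "K")
  base <- peptide_mono_mass(peptide) + mod_delta("prop")  # N-term
  if (ks == 0L) return(round(base, decimals))
  states <- expand.grid(rep(list(alphabet), ks), stringsAsFactors = FALSE)
  masses <- apply(states, 1, function(s) base + sum(mod_delta(unlist(s))))
  sort(unique(round(masses, decimals)))
}

## brute-force EM oracles
oracle_bubble_lengths <- function(mol) {
  lens <- c()
  for (i in seq_len(nrow(mol))) {
    b <- mol$bubbles[[i]]
    if (nrow(b)) lens <- c(lens, b[, 2] - b[, 1])
  }
  lens
}

oracle_size_label <- function(l) {
  if (l < 130) "sub"
  else if (l < 180) "mono"
  else if (l < 260) "intermediate"
  else if (l < 280) "gap"
  else if (l <= 360) "di"
  else "supra"
}

oracle_class_key <- function(b, feature) {
  if (nrow(b) == 0L) return("0:crosslinked")
  parts <- character(nrow(b))
  for (k in seq_len(nrow(b))) {
    l <- b[k, 2] - b[k, 1]
    ov <- min(b[k, 2], feature[2]) - max(b[k, 1], feature[1])
    rel <- if (ov >= 1) "overlaps_feature"
           else if (b[k, 2] <= feature[1]) "upstream" else "downstream"
    parts[k] <- paste0(oracle_size_label(l), ":", rel)
  }
  paste0(nrow(b), ":", paste(sort(parts), collapse = ","))
}

## random linear molecule population with non-overlapping bubbles
random_molecules <- function(n, L = 3000, max_bubbles = 3) {
  specs <- list()
  for (i in seq_len(n)) {
    nb <- sample(0:max_bubbles, 1)
    b <- matrix(numeric(), ncol = 2)
    if (nb > 0) {
      ## partition the axis to guarantee non-overlap
      cuts <- sort(sample(seq(10, L - 10, by = 10), nb * 2))
      b <- cbind(cuts[seq(1, 2 * nb, by = 2)], cuts[seq(2, 2 * nb, by = 2)])
    }
    specs[[sprintf("m%03d", i)]] <- list(L = L, bubbles = b)
  }
  make_molecules(specs)
}
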