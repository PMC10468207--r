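#' Mass constants for crosslink channel arithmetic
#'
#' Immutable constants used to compute the four isotope-channel masses of a
#' DSS-crosslinked peptide pair under 14N/15N metabolic labeling: the DSS
#' linker mass added to a crosslinked pair (138.068 Da), the DSS mono-link
#' mass (156.079 Da, stored for completeness; mono-links are not quantified
#' here), the standard 15N-14N mass difference per nitrogen atom, the proton
#' mass, and the monoisotopic residue masses of the 20 standard amino acids.
#'
#' @return a list of class `mass_constants`.
#' @export
mass_constants <- function() {
  structure(list(
    linker_mass = 138.068,
    mono_mass = 156.079,
    n15_shift_per_N = 0.997035,
    proton_mass = 1.007276,
    water_mass = 18.0105646863,
    residue_mass = c(
      A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
      C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
      H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
      M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
      T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
    ),
    # nitrogen atoms per residue (backbone + side chain)
    residue_N = c(
      A = 1L, R = 4L, N = 2L, D = 1L, C = 1L, E = 1L, Q = 2L, G = 1L,
      H = 3L, I = 1L, L = 1L, K = 2L, M = 1L, F = 1L, P = 1L, S = 1L,
      T = 1L, W = 2L, Y = 1L, V = 1L
    )
  ), class = "mass_constants")
}

check_peptide <- function(peptide, constants) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    abort_validation("peptide must be a non-empty character string")
  }
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(constants$residue_N))
  if (length(bad)) {
    abort_validation(sprintf("unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  }
  chars
}

#' Nitrogen atoms in a peptide
#'
#' Total nitrogen count of a peptide (backbone plus side chains; the termini
#' add H and OH, no nitrogen), the quantity that sets the 15N mass shift of
#' each labeling channel.
#'
#' @param peptide uppercase one-letter peptide sequence.
#' @param constants a [mass_constants()] object.
#' @return integer nitrogen count.
#' @examples
#' nitrogen_count("GK")   # 3
#' nitrogen_count("R")    # 4
#' @export
nitrogen_count <- function(peptide, constants = mass_constants()) {
  chars <- check_peptide(peptide, constants)
  sum(constants$residue_N[chars])
}

#' Monoisotopic mass of a neutral peptide
#'
#' @param peptide peptide sequence.
#' @param constants a [mass_constants()] object.
#' @return mass in Da (residue masses + one water).
#' @export
peptide_mono_mass <- function(peptide, constants = mass_constants()) {
  chars <- check_peptide(peptide, constants)
  sum(constants$residue_mass[chars]) + constants$water_mass
}

#' Masses of the four isotope channels of a crosslinked pair
#'
#' A DSS crosslink joins two intact peptides through the linker, so the
#' light-light neutral mass is `mono(pep_a) + mono(pep_b) + linker_mass`.
#' Replacing a peptide's nitrogens with 15N (complete incorporation assumed)
#' shifts its mass by `n15_shift_per_N * nitrogen_count`, giving the other
#' three channels arithmetically.
#'
#' @param pep_a,pep_b peptide sequences (alpha and beta peptides).
#' @param constants a [mass_constants()] object.
#' @return named numeric vector `c(M_LL, M_LH, M_HL, M_HH)` in Da, where the
#'   first letter is the label of `pep_a` (L = 14N, H = 15N).
#' @export
channel_masses <- function(pep_a, pep_b, constants = mass_constants()) {
  m_ll <- peptide_mono_mass(pep_a, constants) + peptide_mono_mass(pep_b, constants) +
    constants$linker_mass
  shift_a <- constants$n15_shift_per_N * nitrogen_count(pep_a, constants)
  shift_b <- constants$n15_shift_per_N * nitrogen_count(pep_b, constants)
  c(M_LL = m_ll, M_LH = m_ll + shift_b, M_HL = m_ll + shift_a,
    M_HH = m_ll + shift_a + shift_b)
}

#' Construct a table of crosslink records
#'
#' One row per identified crosslinked residue pair and replicate, carrying the
#' four MS1 channel intensities (L = 14N, H = 15N; `I_LL` is the 14N:14N
#' channel, `I_LH` 14N:15N, `I_HL` 15N:14N, `I_HH` 15N:15N).
#'
#' @param pep_a,pep_b peptide sequences.
#' @param pos_a,pos_b crosslinked residue positions, 1-based protein numbering.
#' @param replicate replicate id.
#' @param condition condition label (e.g. "basal", "activated").
#' @param I_LL,I_LH,I_HL,I_HH channel intensities, arbitrary units, `>= 0`.
#' @param incubation incubation time, min (optional metadata).
#' @return a `data.frame` of class `xl_table`.
#' @export
xl_table <- function(pep_a, pep_b, pos_a, pos_b, replicate, condition,
                     I_LL, I_LH, I_HL, I_HH, incubation = NA_real_) {
  if (any(c(I_LL, I_LH, I_HL, I_HH) < 0)) abort_validation("intensities must be >= 0")
  n <- length(pep_a)
  df <- data.frame(pep_a = rep_len(pep_a, n), pep_b = rep_len(pep_b, n),
                   pos_a = rep_len(as.integer(pos_a), n),
                   pos_b = rep_len(as.integer(pos_b), n),
                   replicate = rep_len(replicate, n),
                   condition = rep_len(condition, n),
                   incubation = rep_len(incubation, n),
                   I_LL = rep_len(I_LL, n), I_LH = rep_len(I_LH, n),
                   I_HL = rep_len(I_HL, n), I_HH = rep_len(I_HH, n))
  class(df) <- c("xl_table", "data.frame")
  df
}

#' Heterotypic/homotypic mixing ratio R of crosslink records
#'
#' For each record, the ratio of mixed-isotope (heterotypic: 14N:15N and
#' 15N:14N) to uni-isotope (homotypic) MS1 intensities.  Two denominator
#' conventions are provided:
#'
#' * `"homotypic_sum"` (default): `R = (I_LH + I_HL) / (I_LL + I_HH)`,
#'   consistent with the definition of homotypic crosslinks as the two
#'   uni-isotopic channels.
#' * `"as_printed"`: `R = (I_LH + I_HL) / (I_LL + I_LH)`, reproducing the
#'   originally typeset equation exactly.
#'
#' Records whose denominator is zero have no defined R; they are flagged
#' (`R_defined = FALSE`, `R = NA`) and excluded from downstream means.
#'
#' @param records an [xl_table()].
#' @param denominator `"homotypic_sum"` or `"as_printed"`.
#' @param map a [domain_map()] used to classify both residue positions.
#' @param hetero_floor intensity floor above which a heterotypic channel
#'   counts as detected.
#' @return records augmented with `R`, `R_defined`, `domain_a`, `domain_b`,
#'   `domain_pair` (unordered, "kinase-kinase" style), and
#'   `is_heterotypic_capable` columns; class `xl_quant`.
#' @examples
#' tab <- xl_table("GK", "AK", 42, 344, 1, "activated", 100, 20, 30, 150)
#' compute_R(tab)$R                      # 0.2
#' compute_R(tab, "as_printed")$R        # 0.41667
#' @export
compute_R <- function(records, denominator = c("homotypic_sum", "as_printed"),
                      map = domain_map(), hetero_floor = 0) {
  denominator <- match.arg(denominator)
  num <- records$I_LH + records$I_HL
  den <- switch(denominator,
                homotypic_sum = records$I_LL + records$I_HH,
                as_printed = records$I_LL + records$I_LH)
  defined <- den > 0
  out <- records
  out$R <- ifelse(defined, num / den, NA_real_)
  out$R_defined <- defined
  out$domain_a <- vapply(records$pos_a, classify_domain, character(1), map = map)
  out$domain_b <- vapply(records$pos_b, classify_domain, character(1), map = map)
  out$domain_pair <- unordered_pair(out$domain_a, out$domain_b)
  out$is_heterotypic_capable <- records$I_LH > hetero_floor | records$I_HL > hetero_floor
  class(out) <- c("xl_quant", class(records))
  out
}

unordered_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Classify a residue position into a subunit domain
#'
#' @param pos 1-based residue position.
#' @param map a [domain_map()].
#' @return the name of the unique domain range containing `pos`.
#' @export
classify_domain <- function(pos, map = domain_map()) {
  for (nm in names(unclass(map))) {
    r <- map[[nm]]
    if (pos >= r[1] && pos <= r[2]) return(nm)
  }
  abort_validation(sprintf("position %s is outside all domain ranges", pos))
}

#' Domain-pair crosslink heatmap
#'
#' Counts unique crosslinked residue-position pairs per unordered domain pair,
#' separately for homotypic and heterotypic crosslinks.  A crosslink is
#' heterotypic when either mixed-isotope channel is detected above
#' `hetero_floor`, homotypic otherwise.  With `require_both_replicates`
#' (mirroring the convention that only peptides identified in both samples of
#' a condition are counted), only residue pairs present in both of the two
#' expected replicates are counted, once.
#'
#' @param records an `xl_quant` (see [compute_R()]) or [xl_table()]; the
#'   latter is classified on the fly.
#' @param mode `"heterotypic"` or `"homotypic"`.
#' @param require_both_replicates logical; intersect the two replicates.
#' @param map a [domain_map()].
#' @param hetero_floor detection floor for the heterotypic channels.
#' @return a symmetric `n_domain x n_domain` integer matrix of counts (class
#'   `xl_heatmap`), with the counted unique pairs in `attr(, "pairs")`.
#' @export
build_heatmap <- function(records, mode = c("heterotypic", "homotypic"),
                          require_both_replicates = FALSE, map = domain_map(),
                          hetero_floor = 0) {
  mode <- match.arg(mode)
  dn <- domain_names(map)
  m <- matrix(0L, length(dn), length(dn), dimnames = list(dn, dn))

  if (nrow(records) == 0L) {
    return(structure(m, class = c("xl_heatmap", class(m)), pairs = character(0)))
  }
  if (!"R" %in% names(records)) {
    records <- compute_R(records, map = map, hetero_floor = hetero_floor)
  }

  is_het <- records$is_heterotypic_capable
  keep <- if (mode == "heterotypic") is_het else !is_het
  rec <- records[keep, , drop = FALSE]

  # crosslink identity: the unordered residue-position pair, so missed-cleavage
  # peptide variants collapse onto one site pair
  site_key <- paste(pmin(rec$pos_a, rec$pos_b), pmax(rec$pos_a, rec$pos_b), sep = "_")

  if (require_both_replicates) {
    reps <- unique(records$replicate)
    if (length(reps) != 2L) {
      abort_validation(sprintf(
        "replicate intersection expects exactly 2 replicate labels, found %d", length(reps)))
    }
    in1 <- unique(site_key[rec$replicate == reps[1]])
    in2 <- unique(site_key[rec$replicate == reps[2]])
    counted <- intersect(in1, in2)
  } else {
    counted <- unique(site_key)
  }

  if (length(counted)) {
    first <- rec[match(counted, site_key), , drop = FALSE]
    for (i in seq_len(nrow(first))) {
      da <- first$domain_a[i]; db <- first$domain_b[i]
      m[da, db] <- m[da, db] + 1L
      if (da != db) m[db, da] <- m[db, da] + 1L
    }
  }
  structure(m, class = c("xl_heatmap", class(m)), pairs = counted, mode = mode)
}

#' Total unique crosslinks counted in a heatmap
#'
#' Sums each unordered domain pair once (off-diagonal cells are mirrored).
#'
#' @param heatmap an `xl_heatmap`.
#' @return integer count; equals the number of counted unique site pairs.
#' @export
heatmap_total <- function(heatmap) {
  m <- unclass(heatmap)
  as.integer(sum(m[upper.tri(m, diag = TRUE)]))
}

#' Mean mixing ratio per domain pair
#'
#' @param records an `xl_quant` (see [compute_R()]).
#' @param group_by column to group on (default `"domain_pair"`).
#' @return data.frame with `group`, `mean_R`, `se_R` (NA for n = 1), `n`, and
#'   the number of undefined-R records excluded per group in
#'   `attr(, "n_undefined")`.
#' @export
summarize_ratios <- function(records, group_by = "domain_pair") {
  g <- records[[group_by]]
  def <- records$R_defined
  groups <- sort(unique(g))
  rows <- lapply(groups, function(gr) {
    r <- records$R[g == gr & def]
    if (length(r) == 0L) return(NULL)
    data.frame(group = gr, mean_R = mean(r),
               se_R = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
               n = length(r))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(group = character(0), mean_R = numeric(0),
                                      se_R = numeric(0), n = integer(0))
  attr(out, "n_undefined") <- sum(!def)
  out
}

#' Map crosslinks onto structure coordinates
#'
#' For each crosslinked residue pair, finds the minimal C-alpha--C-alpha
#' Euclidean distance over the allowed chain pairings and flags the crosslink
#' satisfied when the distance is at most `max_dist` (default 30 Angstrom, a
#' common C-alpha criterion for the 11.4 Angstrom DSS spacer).  Crosslinks
#' whose residues are missing from the coordinates are flagged unmapped, not
#' dropped.
#'
#' @param records an [xl_table()] (or `xl_quant`).
#' @param coordinates data.frame with columns `chain`, `resno`, `x`, `y`, `z`
#'   (C-alpha atoms; see [read_ca_coordinates()]).
#' @param pairing `"intra_subunit"` (same chain), `"inter_subunit_min"`
#'   (minimum over pairs of distinct chains), or `"inter_holoenzyme_min"`
#'   (minimum over chains belonging to different assemblies, per
#'   `chain_groups`).
#' @param max_dist satisfaction threshold, Angstrom.
#' @param offset signed integer added to record positions to convert protein
#'   numbering to structure numbering (e.g. constructs lacking N-terminal
#'   residues).
#' @param chain_groups named vector mapping chain id to an assembly/holoenzyme
#'   id, required for `"inter_holoenzyme_min"`.
#' @return data.frame with per-record `pos_a`, `pos_b`, `distance` (Angstrom,
#'   NA when unmapped), `satisfied`, `mapped`, `chain_a`, `chain_b` (chains
#'   achieving the minimum).
#' @export
map_to_structure <- function(records, coordinates,
                             pairing = c("inter_subunit_min", "intra_subunit",
                                         "inter_holoenzyme_min"),
                             max_dist = 30, offset = 0L, chain_groups = NULL) {
  pairing <- match.arg(pairing)
  if (pairing == "inter_holoenzyme_min" && is.null(chain_groups)) {
    abort_validation("inter_holoenzyme_min requires chain_groups mapping chains to assemblies")
  }
  chains <- unique(coordinates$chain)

  locate <- function(pos) {
    hit <- coordinates[coordinates$resno == pos + offset, , drop = FALSE]
    hit
  }

  out <- lapply(seq_len(nrow(records)), function(i) {
    ca_a <- locate(records$pos_a[i])
    ca_b <- locate(records$pos_b[i])
    if (nrow(ca_a) == 0L || nrow(ca_b) == 0L) {
      return(data.frame(pos_a = records$pos_a[i], pos_b = records$pos_b[i],
                        distance = NA_real_, satisfied = NA, mapped = FALSE,
                        chain_a = NA_character_, chain_b = NA_character_))
    }
    best <- c(Inf, NA_integer_, NA_integer_)
    for (ia in seq_len(nrow(ca_a))) {
      for (ib in seq_len(nrow(ca_b))) {
        same_chain <- ca_a$chain[ia] == ca_b$chain[ib]
        allowed <- switch(pairing,
          intra_subunit = same_chain,
          inter_subunit_min = !same_chain,
          inter_holoenzyme_min =
            chain_groups[[ca_a$chain[ia]]] != chain_groups[[ca_b$chain[ib]]]
        )
        # degenerate single-chain coordinates: allow intra pairing as fallback
        if (!allowed) next
        d <- sqrt((ca_a$x[ia] - ca_b$x[ib])^2 + (ca_a$y[ia] - ca_b$y[ib])^2 +
                  (ca_a$z[ia] - ca_b$z[ib])^2)
        if (d < best[1]) best <- c(d, ia, ib)
      }
    }
    if (!is.finite(best[1]) && pairing != "intra_subunit" && length(chains) == 1L) {
      # only one chain present: fall back to the intra-chain distance
      for (ia in seq_len(nrow(ca_a))) {
        for (ib in seq_len(nrow(ca_b))) {
          d <- sqrt((ca_a$x[ia] - ca_b$x[ib])^2 + (ca_a$y[ia] - ca_b$y[ib])^2 +
                    (ca_a$z[ia] - ca_b$z[ib])^2)
          if (d < best[1]) best <- c(d, ia, ib)
        }
      }
    }
    if (!is.finite(best[1])) {
      return(data.frame(pos_a = records$pos_a[i], pos_b = records$pos_b[i],
                        distance = NA_real_, satisfied = NA, mapped = FALSE,
                        chain_a = NA_character_, chain_b = NA_character_))
    }
    data.frame(pos_a = records$pos_a[i], pos_b = records$pos_b[i],
               distance = best[1], satisfied = best[1] <= max_dist, mapped = TRUE,
               chain_a = ca_a$chain[best[2]], chain_b = ca_b$chain[best[3]])
  })
  do.call(rbind, out)
}

#' Write crosslinks as a pseudobond file
#'
#' One line per mapped crosslink, in the `/chain:resno@CA /chain:resno@CA`
#' atom-spec format understood by structure viewers.
#'
#' @param mapped output of [map_to_structure()].
#' @param path output file path.
#' @param offset numbering offset applied in the mapping (recorded for audit).
#' @return invisibly, the number of lines written.
#' @export
write_pseudobonds <- function(mapped, path, offset = 0L) {
  ok <- !is.na(mapped$mapped) & mapped$mapped
  lines <- sprintf("/%s:%d@CA /%s:%d@CA",
                   mapped$chain_a[ok], mapped$pos_a[ok] + offset,
                   mapped$chain_b[ok], mapped$pos_b[ok] + offset)
  writeLines(lines, path)
  invisible(length(lines))
}
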