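# Tabular and image I/O.  All tabular outputs are TSV with a commented header
# naming units and conventions (1-based residues, kDa, minutes).

write_tsv_commented <- function(df, path, comment_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a time-course table as TSV
#'
#' Columns: `conc_nM`, `time_min`, `replicate`, `phospho`, `total`,
#' `normalized`.
#'
#' @param table a [timecourse_table()].
#' @param path file path.
#' @return `write_timecourse_tsv` returns the path invisibly;
#'   `read_timecourse_tsv` returns a [timecourse_table()].
#' @export
write_timecourse_tsv <- function(table, path) {
  write_tsv_commented(as.data.frame(table), path,
                      c("phospho time course", "units: conc_nM = nM, time_min = min",
                        "normalized = phospho/total on the fitted 0-1 scale"))
}

#' @rdname write_timecourse_tsv
#' @export
read_timecourse_tsv <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("input file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  timecourse_table(df$conc_nM, df$time_min, df$replicate, df$phospho, df$total,
                   normalized = df$normalized)
}

#' Write / read a crosslink table as TSV
#'
#' @param table an [xl_table()].
#' @param path file path.
#' @return path (write) or an [xl_table()] (read).
#' @export
write_xl_tsv <- function(table, path) {
  write_tsv_commented(as.data.frame(table), path,
                      c("crosslink records", "positions: 1-based protein numbering",
                        "channels: L = 14N, H = 15N; intensities in a.u."))
}

#' @rdname write_xl_tsv
#' @export
read_xl_tsv <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("input file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tab <- xl_table(df$pep_a, df$pep_b, df$pos_a, df$pos_b, df$replicate,
                  df$condition, df$I_LL, df$I_LH, df$I_HL, df$I_HH,
                  incubation = df$incubation %||% NA_real_)
  tab
}

#' Read a pLink2-style crosslink CSV
#'
#' Reads identification tables in the wide pLink2 export style, with a
#' configurable column mapping, and merges the four MS1 channel intensities
#' (either present as columns or supplied as a sidecar table keyed by
#' peptide pair).
#'
#' @param path CSV path.
#' @param columns named character vector mapping the canonical names
#'   (`pep_a`, `pep_b`, `pos_a`, `pos_b`, `replicate`, `condition`, `I_LL`,
#'   `I_LH`, `I_HL`, `I_HH`) to the file's column names.
#' @param intensities optional sidecar data.frame carrying the four channel
#'   intensities plus `pep_a`/`pep_b` keys.
#' @return an [xl_table()].
#' @export
read_plink_csv <- function(path,
                           columns = c(pep_a = "Peptide_A", pep_b = "Peptide_B",
                                       pos_a = "Position_A", pos_b = "Position_B",
                                       replicate = "Replicate", condition = "Condition",
                                       I_LL = "I_14N_14N", I_LH = "I_14N_15N",
                                       I_HL = "I_15N_14N", I_HH = "I_15N_15N"),
                           intensities = NULL) {
  if (!file.exists(path)) abort_validation(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(intensities)) {
    df <- merge(df, intensities,
                by.x = c(columns[["pep_a"]], columns[["pep_b"]]),
                by.y = c("pep_a", "pep_b"))
  }
  need <- columns[c("pep_a", "pep_b", "pos_a", "pos_b", "replicate", "condition",
                    "I_LL", "I_LH", "I_HL", "I_HH")]
  missing <- setdiff(unname(need), names(df))
  if (length(missing)) {
    abort_validation(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  xl_table(df[[need[["pep_a"]]]], df[[need[["pep_b"]]]],
           df[[need[["pos_a"]]]], df[[need[["pos_b"]]]],
           df[[need[["replicate"]]]], df[[need[["condition"]]]],
           df[[need[["I_LL"]]]], df[[need[["I_LH"]]]],
           df[[need[["I_HL"]]]], df[[need[["I_HH"]]]])
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one row per C-alpha atom: `chain`, `resno`, `x`, `y`, `z`.
#'
#' @param path PDB file path.
#' @return data.frame suitable for [map_to_structure()].
#' @export
read_ca_coordinates <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("input file not found: %s", path))
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  data.frame(chain = ca$chain, resno = ca$resno,
             x = ca$x, y = ca$y, z = ca$z)
}

#' Write / read a mass event list as single-column CSV
#'
#' @param events numeric vector of masses, kDa.
#' @param path file path.
#' @return path (write) or numeric vector (read).
#' @export
write_mass_csv <- function(events, path) {
  utils::write.csv(data.frame(mass_kDa = as.numeric(events)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_csv
#' @export
read_mass_csv <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("input file not found: %s", path))
  utils::read.csv(path)$mass_kDa
}

#' Write / read a two-channel image pair as TIFF
#'
#' Channels are written as separate 32-bit float TIFF files
#' (`<stem>_ch1.tif`, `<stem>_ch2.tif`), intensities rescaled to `[0, 1]` by
#' the pair-wide maximum (recorded nowhere: TIFF round trips are for
#' visualization; quantitative workflows should pass matrices directly).
#'
#' @param pair an `image_pair` (see [gen_spot_images()]) or list with
#'   `channel_1`, `channel_2` matrices.
#' @param stem output path stem.
#' @return character vector of the two file paths.
#' @export
write_image_pair_tiff <- function(pair, stem) {
  mx <- max(pair$channel_1, pair$channel_2, 1e-12)
  paths <- paste0(stem, c("_ch1.tif", "_ch2.tif"))
  tiff::writeTIFF(pair$channel_1 / mx, paths[1], bits.per.sample = 32L)
  tiff::writeTIFF(pair$channel_2 / mx, paths[2], bits.per.sample = 32L)
  paths
}

#' @rdname write_image_pair_tiff
#' @param paths two TIFF paths (channel 1 and channel 2).
#' @export
read_image_pair_tiff <- function(paths) {
  for (p in paths) {
    if (!file.exists(p)) abort_validation(sprintf("input file not found: %s", p))
  }
  structure(list(channel_1 = tiff::readTIFF(paths[1]),
                 channel_2 = tiff::readTIFF(paths[2])),
            class = "image_pair")
}
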