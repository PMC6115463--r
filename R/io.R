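# typed validation failure carrying file / row / field
.parse_error <- function(path, row, field, msg) {
  abort(sprintf("%s [file %s, row %s, field %s]",
                msg, path, paste(row, collapse = ","), field),
        class = "phosksea_parse_error")
}

.validate_site_annotations <- function(tbl, path) {
  dup <- which(duplicated(tbl$site_id))
  if (length(dup)) .parse_error(path, dup, "site_id", "duplicate site_id")
  bad_flank <- which(nchar(tbl$flank) != FLANK_LEN)
  if (length(bad_flank)) {
    .parse_error(path, bad_flank, "flank", "flank is not 15 characters")
  }
  center <- substr(tbl$flank, FLANK_HALF + 1L, FLANK_HALF + 1L)
  bad_center <- which(!center %in% c("S", "T", "Y"))
  if (length(bad_center)) {
    .parse_error(path, bad_center, "flank", "flank center is not S/T/Y")
  }
  bad_pos <- which(!is.finite(tbl$position) | tbl$position < 1)
  if (length(bad_pos)) .parse_error(path, bad_pos, "position", "position must be >= 1")
  invisible(tbl)
}

#' Read and write phosphosite quantification tables
#'
#' Tab-separated site tables in a MaxQuant-"Phospho (STY)Sites"-like dialect:
#' annotation columns `site_id`, `protein_id`, `residue`, `position`, `flank`
#' followed by one numeric intensity column per sample. Empty intensity cells
#' are missing values, never zero. Unknown extra columns are preserved.
#' Round-tripping a table through `write_site_table()` / `read_site_table()`
#' is the identity on values and missingness.
#'
#' @param path File path.
#' @param sites Site tibble.
#' @return `read_site_table()` returns a validated tibble;
#'   `write_site_table()` returns `path` invisibly.
#' @export
read_site_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    protein_id = readr::col_character(),
    residue = readr::col_character(),
    position = readr::col_integer(),
    flank = readr::col_character(),
    .default = readr::col_double()))
  need <- c("site_id", "protein_id", "residue", "position", "flank")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    .parse_error(path, NA, paste(missing_cols, collapse = ","),
                 "required column(s) absent")
  }
  .validate_site_annotations(tbl, path)
  for (s in .sample_cols(tbl)) {
    neg <- which(!is.na(tbl[[s]]) & tbl[[s]] < 0)
    if (length(neg)) .parse_error(path, neg, s, "negative intensity")
  }
  tbl
}

#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path) {
  out <- dplyr::select(sites, -dplyr::any_of("planted_motif"))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write protein FASTA files
#'
#' Standard FASTA (`>`-prefixed headers, sequences wrapped at 60 columns),
#' read and written through Biostrings.
#'
#' @param path File path.
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @return `read_fasta()` returns a tibble `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    .parse_error(path, which(duplicated(ids)), "header", "duplicate protein id")
  }
  tibble(protein_id = ids, sequence = as.character(aa))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$protein_id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read and write linear-motif libraries
#'
#' Tab-separated libraries with columns `name`, `category` (kinase /
#' phosphatase / sh2) and the 15 slot columns `pos_01`..`pos_15`; each slot is
#' `"X"` or a string of allowed one-letter residues.
#'
#' @param path File path.
#' @param motifs Motif tibble.
#' @export
read_motifs <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  slots <- sprintf("pos_%02d", seq_len(FLANK_LEN))
  missing_cols <- setdiff(c("name", "category", slots), names(tbl))
  if (length(missing_cols)) {
    .parse_error(path, NA, paste(missing_cols, collapse = ","),
                 "required column(s) absent")
  }
  dup <- which(duplicated(tbl$name))
  if (length(dup)) .parse_error(path, dup, "name", "duplicate motif name")
  ok_chars <- paste0("^(X|[", paste(AA, collapse = ""), "]+)$")
  for (sc in slots) {
    bad <- which(!grepl(ok_chars, tbl[[sc]]))
    if (length(bad)) {
      .parse_error(path, bad, sc,
                   sprintf("invalid residue character in motif %s",
                           paste(tbl$name[bad], collapse = ",")))
    }
  }
  bad_cat <- which(!tbl$category %in% c("kinase", "phosphatase", "sh2"))
  if (length(bad_cat)) .parse_error(path, bad_cat, "category", "unknown motif category")
  tbl
}

#' @rdname read_motifs
#' @export
write_motifs <- function(motifs, path) {
  readr::write_tsv(motifs, path)
  invisible(path)
}

#' Read and write clinical tables
#'
#' Comma-separated patient records: `patient_id`, ordinal `T`, `N`, `G`, `age`,
#' relapse `event` (0/1), `time` (months, > 0) and per-kinase H-score columns
#' `hs_<kinase>` constrained to `[0, 3]`.
#'
#' @param path File path.
#' @param clinical Clinical tibble.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_double()))
  need <- c("patient_id", "T", "N", "G", "age", "event", "time")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    .parse_error(path, NA, paste(missing_cols, collapse = ","),
                 "required column(s) absent")
  }
  dup <- which(duplicated(tbl$patient_id))
  if (length(dup)) .parse_error(path, dup, "patient_id", "duplicate patient id")
  bad_t <- which(!is.finite(tbl$time) | tbl$time <= 0)
  if (length(bad_t)) .parse_error(path, bad_t, "time", "time must be > 0")
  bad_e <- which(!tbl$event %in% c(0, 1))
  if (length(bad_e)) .parse_error(path, bad_e, "event", "event must be 0/1")
  for (hc in grep("^hs_", names(tbl), value = TRUE)) {
    bad <- which(!is.na(tbl[[hc]]) & (tbl[[hc]] < 0 | tbl[[hc]] > 3))
    if (length(bad)) .parse_error(path, bad, hc, "H-score outside [0, 3]")
  }
  tbl
}

#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, na = "")
  invisible(path)
}

#' Read and write tumor growth tables
#'
#' Comma-separated per-animal series: `animal_id`, `arm`, `day` and either a
#' `volume` column (mm^3) or caliper diameters `D` (largest, mm) and `d`
#' (shortest, mm), from which volume can be derived with [tumor_volume()].
#'
#' @param path File path.
#' @param growth Growth tibble.
#' @export
read_growth <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(), arm = readr::col_character(),
    .default = readr::col_double()))
  need <- c("animal_id", "arm", "day")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    .parse_error(path, NA, paste(missing_cols, collapse = ","),
                 "required column(s) absent")
  }
  if (!("volume" %in% names(tbl)) && !all(c("D", "d") %in% names(tbl))) {
    .parse_error(path, NA, "volume", "need `volume` or both `D` and `d`")
  }
  if (all(c("D", "d") %in% names(tbl))) {
    bad <- which(!is.na(tbl$D) & !is.na(tbl$d) & (tbl$d <= 0 | tbl$D < tbl$d))
    if (length(bad)) .parse_error(path, bad, "D/d", "need D >= d > 0")
  }
  tbl
}

#' @rdname read_growth
#' @export
write_growth <- function(growth, path) {
  readr::write_csv(growth, path, na = "")
  invisible(path)
}

#' Write and read the ground-truth sidecar
#'
#' JSON record of what the generators planted (substrate memberships, planted
#' site flags, clinical status matrix, seed) so downstream recovery can be
#' scored against it.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
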