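#' Extract the 15-residue flanking window around a phosphosite
#'
#' Takes the phosphorylated residue plus seven residues on each side,
#' padding with `"_"` beyond the protein termini.
#'
#' @param protein_seq Protein sequence (single string, one-letter amino acids).
#' @param position 1-based position of the phosphosite within `protein_seq`.
#' @param residue Expected residue at `position` (`"S"`, `"T"` or `"Y"`);
#'   mismatches raise an error.
#'
#' @return A 15-character window with the phosphoresidue at position 8.
#' @export
#' @examples
#' extract_flank("ACDEFGHSKLMNPQR", 8, "S")
extract_flank <- function(protein_seq, position, residue) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  n <- nchar(protein_seq)
  if (position < 1L || position > n) {
    abort(sprintf("position %d outside protein of length %d.", position, n))
  }
  at <- substr(protein_seq, position, position)
  if (!identical(at, residue)) {
    abort(sprintf("residue mismatch at position %d: expected %s, found %s.",
                  position, residue, at))
  }
  idx <- (position - FLANK_HALF):(position + FLANK_HALF)
  chars <- ifelse(idx < 1L | idx > n, "_",
                  vapply(idx, function(i) substr(protein_seq, i, i), character(1)))
  paste(chars, collapse = "")
}

# split a motif row (tibble row or named list) into its 15 slot strings
.motif_slots <- function(motif) {
  cols <- sprintf("pos_%02d", seq_len(FLANK_LEN))
  unlist(motif[cols], use.names = FALSE)
}

#' Match a flanking window against one linear motif
#'
#' A motif is a vector of 15 position constraints; each slot is either `"X"`
#' (any residue) or a string of allowed residues. Terminal padding (`"_"`)
#' satisfies only `"X"` slots.
#'
#' @param window 15-character flanking window.
#' @param motif A motif row (from [simulate_motif_library()] or
#'   [read_motifs()]) or a character vector of 15 slot constraints.
#'
#' @return `TRUE` if every slot is satisfied.
#' @export
#' @examples
#' win <- paste0(strrep("A", 7), "S", strrep("A", 7))
#' match_motif(win, rep("X", 15))
#' motif <- rep("X", 15); motif[5] <- "RK"
#' match_motif(win, motif)
match_motif <- function(window, motif) {
  slots <- if (is.character(motif)) motif else .motif_slots(motif)
  if (length(slots) != FLANK_LEN) abort("motif must have 15 slots.")
  if (nchar(window) != FLANK_LEN) abort("window must be 15 characters.")
  for (i in seq_len(FLANK_LEN)) {
    if (slots[i] == "X") next
    ch <- substr(window, i, i)
    if (ch == "_" || !grepl(ch, slots[i], fixed = TRUE)) return(FALSE)
  }
  TRUE
}

# vectorized matcher: which of `windows` satisfy motif `slots`
.match_windows <- function(windows, slots) {
  keep <- rep(TRUE, length(windows))
  for (i in which(slots != "X")) {
    allowed <- strsplit(slots[i], "", fixed = TRUE)[[1]]
    ch <- substr(windows, i, i)
    keep <- keep & ch != "_" & ch %in% allowed
    if (!any(keep)) break
  }
  keep
}

#' Map phosphosites to motifs and build kinase substrate sets
#'
#' Matches every site's flanking window against every motif in the library and
#' returns one substrate set per motif, dropping sets outside
#' `[min_size, max_size]` (GSEA-style size bounds). Phosphatase and SH2 motifs
#' are matched identically to kinase motifs and keep their category label.
#'
#' @param sites Site tibble with `site_id` and `flank` columns.
#' @param motifs Motif library tibble (`name`, `category`, `pos_01`..`pos_15`).
#' @param min_size,max_size Inclusive substrate-set size bounds (defaults 5 and
#'   500).
#'
#' @return A tibble with columns `kinase`, `category`, `site_id` (one row per
#'   membership). The number of sets excluded by the size filter is attached as
#'   attribute `n_excluded` and reported via a message.
#' @export
build_kinase_sets <- function(sites, motifs, min_size = 5L, max_size = 500L) {
  if (!nrow(motifs)) abort("motif library is empty.")
  stopifnot(all(c("site_id", "flank") %in% names(sites)))
  windows <- sites$flank
  memb <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    slots <- .motif_slots(motifs[i, ])
    hit <- .match_windows(windows, slots)
    if (!any(hit)) return(NULL)
    tibble(kinase = motifs$name[i], category = motifs$category[i],
           site_id = sites$site_id[hit])
  })
  if (!nrow(memb)) {
    warn("no motif matched any site.")
    out <- tibble(kinase = character(), category = character(), site_id = character())
    attr(out, "n_excluded") <- nrow(motifs)
    return(out)
  }
  sizes <- dplyr::count(memb, .data$kinase, name = "size")
  keep <- sizes$kinase[sizes$size >= min_size & sizes$size <= max_size]
  n_excluded <- nrow(motifs) - length(keep)
  if (!length(keep)) warn("all substrate sets fell outside the size bounds.")
  if (n_excluded > 0) {
    message(sprintf("%d motif(s) excluded by set-size bounds [%d, %d].",
                    n_excluded, min_size, max_size))
  }
  out <- dplyr::filter(memb, .data$kinase %in% keep)
  attr(out, "n_excluded") <- n_excluded
  out
}
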