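# Positional saturation library design: NNS site + adjacent silent-codon
# positional barcode over a reference amplicon; covariation library
# enumeration and pooling.

# One preferred E. coli codon per amino acid for building the synthetic
# reference window.  At two-codon families the third-base orientation is
# chosen so that the synonymous partner (the silent barcode) ends in A/T,
# i.e. is NOT an NNS codon: a positional barcode can then never be mimicked
# by a codon drawn at the randomized NNS site, keeping decoding unambiguous.
PREFERRED_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATT", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG"
)

# Hotspot-recognition loop of AID, residues 113-123.
AID_LOOP_RESIDUES <- 113:123
AID_LOOP_SEQ <- c("L", "Y", "F", "C", "E", "D", "R", "K", "A", "E", "P")

#' Synthetic AID amplicon window (residues 71-169)
#'
#' Builds the deterministic reference used throughout the package: a
#' 297-nt coding window covering residues 71-169 (the amplified region of
#' the deaminase gene, nucleotides 211-507 of the CDS).  The
#' hotspot-recognition loop Leu113-Pro123 (`LYFCEDRKAEP`) occupies residues
#' 113-123; flanking residues are a synthetic filler peptide, since the
#' codon-optimized gene sequence outside the loop is not part of the design.
#' All codons come from [PREFERRED_CODON] choices, so the window is free of
#' Met/Trp outside position 1 constraints and every codon has a synonymous
#' partner available for barcoding.
#'
#' @param filler_pattern Character vector of amino-acid symbols cycled to
#'   fill non-loop residues (no Met/Trp, so every barcode slot has a
#'   synonym).
#' @return Object of class `reference_amplicon`: list with `cds_window`
#'   (character scalar), `frame_offset` (0), `residue_of_first_codon` (71),
#'   `protein` (named character vector, names = residue indices).
#' @export
aid_loop_amplicon <- function(filler_pattern = c("A", "S", "T", "G", "V", "L",
                                                 "K", "N", "D", "E", "R", "Q",
                                                 "H", "I")) {
  stopifnot(!any(filler_pattern %in% c("M", "W")))
  first <- 71L; last <- 169L
  residues <- first:last
  protein <- character(length(residues))
  names(protein) <- residues
  protein[as.character(AID_LOOP_RESIDUES)] <- AID_LOOP_SEQ
  filler_idx <- which(protein == "")
  protein[filler_idx] <- rep_len(filler_pattern, length(filler_idx))
  reference_amplicon(paste(PREFERRED_CODON[protein], collapse = ""),
                     frame_offset = 0L, residue_of_first_codon = first)
}

#' Construct a reference amplicon
#'
#' @param cds_window DNA string (uppercase ACGT) holding the amplified
#'   coding window.
#' @param frame_offset Integer 0-2, bases before the first complete codon.
#' @param residue_of_first_codon 1-based residue index of the first codon.
#' @return Object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(cds_window, frame_offset = 0L,
                               residue_of_first_codon = 1L) {
  cds_window <- toupper(cds_window)
  if (grepl("[^ACGT]", cds_window))
    stop("cds_window contains non-ACGT characters", call. = FALSE)
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L || frame_offset > 2L)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  if (nchar(cds_window) - frame_offset < 3L)
    stop("amplicon too short for a single codon", call. = FALSE)
  n_codon <- (nchar(cds_window) - frame_offset) %/% 3L
  starts <- frame_offset + 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(cds_window, starts, starts + 2L)
  protein <- translate_codons(codons)
  names(protein) <- seq(residue_of_first_codon, length.out = n_codon)
  structure(list(cds_window = cds_window,
                 frame_offset = frame_offset,
                 residue_of_first_codon = as.integer(residue_of_first_codon),
                 protein = protein),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat("Reference amplicon:", nchar(x$cds_window), "nt, residues",
      x$residue_of_first_codon, "-",
      x$residue_of_first_codon + length(x$protein) - 1L, "\n")
  invisible(x)
}

# 0-based nt offset of a residue's codon within the amplicon window.
residue_offset <- function(ref, residue_index) {
  idx <- residue_index - ref$residue_of_first_codon
  if (idx < 0L || idx >= length(ref$protein))
    stop("residue ", residue_index, " outside amplicon", call. = FALSE)
  ref$frame_offset + 3L * idx
}

# Codon of a residue in the reference window.
residue_codon <- function(ref, residue_index) {
  off <- residue_offset(ref, residue_index)
  substr(ref$cds_window, off + 1L, off + 3L)
}

# Replace the codon at a 0-based offset (vectorized over seqs).
set_codon <- function(seqs, offset, codon) {
  paste0(substr(seqs, 1L, offset),
         codon,
         substr(seqs, offset + 4L, nchar(seqs)))
}

hamming3 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Default silent-barcode selection rule
#'
#' Chooses a synonymous barcode codon for a wild-type codon.  Preference
#' order: codons outside the NNS set (third base A/T) first — an NNS draw at
#' the randomized site can then never collide with a barcode — then maximal
#' Hamming distance from the wild-type codon, then alphabetical.
#'
#' @param wt_codon Wild-type codon at the barcode slot.
#' @param exclude Codons already used at this slot (collision avoidance).
#' @return A single codon, or `NA_character_` if no synonym remains.
#' @export
default_barcode_rule <- function(wt_codon, exclude = character()) {
  syn <- setdiff(synonymous_codons(wt_codon), exclude)
  if (!length(syn)) return(NA_character_)
  non_nns <- substr(syn, 3L, 3L) %in% c("A", "T")
  dist <- vapply(syn, hamming3, 0, b = wt_codon)
  syn[order(!non_nns, -dist, syn)][1L]
}

#' Design one positional saturation library
#'
#' A positional library randomizes one residue with an NNS codon and marks
#' the library identity with a silent (synonymous) codon substitution —
#' the positional barcode — at the codon `barcode_shift` codons 3' of the
#' randomized one (default: the immediate neighbor).
#'
#' @param ref A [reference_amplicon].
#' @param residue_index 1-based residue to randomize.
#' @param barcode_rule Function `(wt_codon, exclude) -> codon` choosing the
#'   silent barcode; default [default_barcode_rule].
#' @param barcode_shift Codons between the NNS codon and the barcode slot
#'   (>= 1); override when the immediate neighbor is Met/Trp.
#' @param exclude_barcodes Codons unavailable at the barcode slot.
#' @param library_id Label; defaults to the residue number.
#' @return Object of class `positional_library`.
#' @export
design_positional_library <- function(ref, residue_index,
                                      barcode_rule = default_barcode_rule,
                                      barcode_shift = 1L,
                                      exclude_barcodes = character(),
                                      library_id = as.character(residue_index)) {
  barcode_residue <- residue_index + as.integer(barcode_shift)
  nns_start <- residue_offset(ref, residue_index)
  bc_start <- residue_offset(ref, barcode_residue)
  wt_bc <- residue_codon(ref, barcode_residue)
  if (!length(synonymous_codons(wt_bc)))
    stop("barcode slot residue ", barcode_residue, " (",
         translate_codon(wt_bc),
         ") has no synonymous codon; override barcode_shift",
         call. = FALSE)
  bc <- barcode_rule(wt_bc, exclude_barcodes)
  if (is.na(bc))
    stop("no barcode codon available at residue ", barcode_residue,
         " after exclusions; override barcode_shift", call. = FALSE)
  structure(list(library_id = library_id,
                 residue_index = as.integer(residue_index),
                 wt_codon = residue_codon(ref, residue_index),
                 nns_codon_start = nns_start,
                 barcode_residue = as.integer(barcode_residue),
                 barcode_codon_start = bc_start,
                 wt_barcode_codon = wt_bc,
                 barcode_codon = bc),
            class = "positional_library")
}

#' @export
print.positional_library <- function(x, ...) {
  cat(sprintf("Library %s: NNS at residue %d (wt %s), barcode %s>%s at residue %d\n",
              x$library_id, x$residue_index, x$wt_codon,
              x$wt_barcode_codon, x$barcode_codon, x$barcode_residue))
  invisible(x)
}

#' Build the full panel of positional libraries
#'
#' One library per residue in `residues` plus duplicate libraries at the
#' residues named in `duplicates`, each duplicate carrying a different
#' silent barcode (searching further 3' slots when the default slot has no
#' unused synonym).  Duplicated residues get `a`/`b` suffixed ids.
#'
#' @param ref A [reference_amplicon].
#' @param residues Integer vector of residues to randomize (default the
#'   hotspot loop 113-123).
#' @param duplicates Residues to build twice (default 115, the
#'   reproducibility duplicate).
#' @param barcode_rule Barcode selection rule.
#' @param max_shift Furthest barcode slot (codons 3') tried for duplicates.
#' @return List of `positional_library` objects; pairwise-distinct
#'   `(barcode_residue, barcode_codon)` signatures guaranteed.
#' @export
build_library_panel <- function(ref, residues = AID_LOOP_RESIDUES,
                                duplicates = 115L,
                                barcode_rule = default_barcode_rule,
                                max_shift = 10L) {
  used <- data.frame(residue = integer(), codon = character())
  libs <- list()
  add <- function(lib) {
    sig <- paste(lib$barcode_residue, lib$barcode_codon)
    if (sig %in% paste(used$residue, used$codon))
      stop("barcode collision at residue ", lib$barcode_residue,
           " codon ", lib$barcode_codon, call. = FALSE)
    used <<- rbind(used, data.frame(residue = lib$barcode_residue,
                                    codon = lib$barcode_codon))
    libs[[lib$library_id]] <<- lib
  }
  for (res in residues) {
    id <- if (res %in% duplicates) paste0(res, "a") else as.character(res)
    add(design_positional_library(ref, res, barcode_rule,
                                  library_id = id))
  }
  for (res in duplicates) {
    if (!res %in% residues)
      stop("duplicate residue ", res, " not in panel", call. = FALSE)
    lib <- NULL
    for (shift in seq_len(max_shift)) {
      slot_res <- res + shift
      excl <- used$codon[used$residue == slot_res]
      lib <- tryCatch(
        design_positional_library(ref, res, barcode_rule,
                                  barcode_shift = shift,
                                  exclude_barcodes = excl,
                                  library_id = paste0(res, "b")),
        error = function(e) NULL)
      if (!is.null(lib)) break
    }
    if (is.null(lib))
      stop("no distinct barcode found for duplicate library at residue ",
           res, call. = FALSE)
    add(lib)
  }
  libs
}

#' Reference sequence of a library with its barcode applied
#'
#' The amplicon window with the silent barcode codon substituted; the NNS
#' codon remains wild type (variants substitute it later).  Applying the
#' barcode never changes the translation.
#'
#' @param ref A [reference_amplicon].
#' @param lib A `positional_library`.
#' @return DNA string.
#' @export
library_reference_seq <- function(ref, lib) {
  set_codon(ref$cds_window, lib$barcode_codon_start, lib$barcode_codon)
}

#' Panel manifest as a data frame
#'
#' @param libs List of `positional_library` (from [build_library_panel]).
#' @return data.frame with columns `library_id`, `residue`, `wt_codon`,
#'   `nns_offset`, `barcode_residue`, `barcode_offset`, `wt_barcode_codon`,
#'   `barcode_codon`.
#' @export
panel_manifest <- function(libs) {
  data.frame(
    library_id = vapply(libs, `[[`, "", "library_id"),
    residue = vapply(libs, `[[`, 0L, "residue_index"),
    wt_codon = vapply(libs, `[[`, "", "wt_codon"),
    nns_offset = vapply(libs, `[[`, 0L, "nns_codon_start"),
    barcode_residue = vapply(libs, `[[`, 0L, "barcode_residue"),
    barcode_offset = vapply(libs, `[[`, 0L, "barcode_codon_start"),
    wt_barcode_codon = vapply(libs, `[[`, "", "wt_barcode_codon"),
    barcode_codon = vapply(libs, `[[`, "", "barcode_codon"),
    row.names = NULL)
}

# ---- covariation library ----------------------------------------------------

#' Default covariation choice sets
#'
#' Residues of the hotspot loop with, at each position, the wild-type amino
#' acid plus every alternative that exceeded the 20% final-generation
#' threshold in positional selection: F115 F/Y, E117 E/T, D118 D/A/R/P,
#' R119 R/G, K120 K/R, A121 A/R/P, P123 P/R.  Product of set sizes = 384.
#'
#' @return Named list (residue index as name) of amino-acid vectors, wild
#'   type first.
#' @export
default_covariation_spec <- function() {
  list(`113` = "L", `114` = "Y", `115` = c("F", "Y"), `116` = "C",
       `117` = c("E", "T"), `118` = c("D", "A", "R", "P"),
       `119` = c("R", "G"), `120` = c("K", "R"),
       `121` = c("A", "R", "P"), `122` = "E", `123` = c("P", "R"))
}

#' Enumerate a covariation library
#'
#' Full Cartesian product of the per-position amino-acid choice sets, in
#' deterministic lexicographic order of the resulting loop sequences.
#'
#' @param spec Named list of amino-acid choice sets (see
#'   [default_covariation_spec]).
#' @return Character vector of loop amino-acid sequences.
#' @export
enumerate_covariation <- function(spec = default_covariation_spec()) {
  if (!length(spec) || any(!lengths(spec)))
    stop("every covariation choice set must be non-empty", call. = FALSE)
  grid <- expand.grid(rev(lapply(spec, sort)), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(spec)), drop = FALSE], 1L, paste,
             collapse = ""))
}

#' Per-member pooling shares of covariation sublibraries
#'
#' Sublibrary `i` with `size_i` members pooled at relative amount
#' `ratio_i` gives each of its members the share
#' `(ratio_i / size_i) / sum(ratio)`.  The canonical eight-sublibrary pool
#' (sizes 64,64,64,64,32,32,32,32 at ratios 2:2:2:2:1:1:1:1) yields an
#' equal 1/384 share for every member.
#'
#' @param sizes Integer vector of sublibrary member counts.
#' @param ratios Numeric vector of relative pooled amounts, same length.
#' @return Numeric vector, one share per member (grouped by sublibrary),
#'   summing to 1.
#' @export
pooling_shares <- function(sizes, ratios) {
  if (length(sizes) != length(ratios))
    stop("sizes and ratios must have equal length", call. = FALSE)
  if (any(sizes <= 0) || any(ratios <= 0))
    stop("sizes and ratios must be positive", call. = FALSE)
  per_member <- ratios / sizes / sum(ratios)
  rep(per_member, times = sizes)
}

#' Canonical covariation pooling plan
#' @return List with `sizes` and `ratios` for the eight sublibraries.
#' @export
default_pooling_plan <- function() {
  list(sizes = c(64L, 64L, 64L, 64L, 32L, 32L, 32L, 32L),
       ratios = c(2, 2, 2, 2, 1, 1, 1, 1))
}
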