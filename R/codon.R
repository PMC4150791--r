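# Genetic-code arithmetic: degenerate codon expansion, translation,
# NNS library composition, synonymous-codon enumeration.

# IUPAC nucleotide code -> base sets (DNA alphabet)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Standard genetic code (NCBI table 1), codon -> one-letter symbol, "*" = stop.
GENETIC_CODE_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GENETIC_CODE_TABLE) <- names(Biostrings::GENETIC_CODE)

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids plus `"*"` for stop, which is carried as a
#' 21st category in all frequency vectors (the selection system uses a stop
#' codon for added negative selection, so its trajectory is informative).
#'
#' @return Character vector of 21 single-letter symbols.
#' @export
aa_alphabet <- function() {
  c(sort(unique(GENETIC_CODE_TABLE[GENETIC_CODE_TABLE != "*"])), "*")
}

#' All 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
codon_alphabet <- function() sort(names(GENETIC_CODE_TABLE))

# Rare E. coli codons, used for annotation only (never filtering).  The
# criterion for "rare" is a configurable convention, not a fixed standard.
DEFAULT_RARE_CODONS <- c("AGG", "AGA", "CGA", "CTA", "ATA", "CCC")

check_codon <- function(codon, allow_ambiguous = FALSE) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon))
    stop("codon must be a single character string", call. = FALSE)
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    stop("codon must have exactly 3 bases, got '", codon, "'", call. = FALSE)
  bases <- strsplit(codon, "")[[1]]
  alphabet <- if (allow_ambiguous) names(IUPAC_SETS) else c("A", "C", "G", "T")
  bad <- setdiff(bases, alphabet)
  if (length(bad))
    stop("invalid ", if (allow_ambiguous) "IUPAC symbol" else "base",
         " '", bad[1], "' in codon '", codon, "'", call. = FALSE)
  codon
}

#' Expand a degenerate (IUPAC) codon pattern
#'
#' Expands a three-symbol IUPAC pattern into the full Cartesian set of
#' unambiguous codons it covers.  `"NNS"` expands to the 32-codon set used
#' for saturation mutagenesis; `"WRC"` expands to the four deaminase hotspot
#' trinucleotides.
#'
#' @param pattern Character scalar of three IUPAC nucleotide codes.
#' @return Character vector of codons, sorted lexicographically.
#' @examples
#' length(expand_degenerate("NNS"))  # 32
#' expand_degenerate("WRC")
#' @export
expand_degenerate <- function(pattern) {
  pattern <- check_codon(pattern, allow_ambiguous = TRUE)
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  grid <- expand.grid(b3 = sets[[3]], b2 = sets[[2]], b1 = sets[[1]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid$b1, grid$b2, grid$b3))
}

#' Translate an unambiguous codon
#'
#' @param codon Character scalar over `{A,C,G,T}`, length 3.
#' @return Single-letter amino-acid symbol, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- check_codon(codon)
  unname(GENETIC_CODE_TABLE[codon])
}

#' Composition of the NNS saturation library
#'
#' Groups the 32 NNS codons (N at positions 1-2, C/G at position 3) by their
#' translation.  The NNS set covers all 20 amino acids plus a single stop
#' codon (TAG); amino acids differ in codon multiplicity (Arg and Leu have 3
#' NNS codons each), which is what starting-library (G0) correction of
#' enrichment later removes.
#'
#' @param rare_codons Character vector of codons to annotate as rare in
#'   E. coli (annotation only; nothing is filtered).
#' @return Object of class `codon_composition`: list with `entries` (named
#'   list symbol -> codon set), `aa_count`, `stop_count`, and `rare`
#'   (per-symbol count of non-rare codons).
#' @export
nns_composition <- function(rare_codons = DEFAULT_RARE_CODONS) {
  codons <- expand_degenerate("NNS")
  aa <- GENETIC_CODE_TABLE[codons]
  entries <- split(codons, aa)
  entries <- entries[order(names(entries) == "*", names(entries))]
  non_rare <- vapply(entries, function(set) sum(!set %in% rare_codons), 0L)
  structure(list(
    entries = entries,
    aa_count = sum(names(entries) != "*"),
    stop_count = length(entries[["*"]]),
    non_rare_codons = non_rare
  ), class = "codon_composition")
}

#' @export
print.codon_composition <- function(x, ...) {
  cat("NNS codon composition:", x$aa_count, "amino acids,",
      x$stop_count, "stop codon(s)\n")
  for (sym in names(x$entries))
    cat(sprintf("  %s: %s\n", sym, paste(x$entries[[sym]], collapse = " ")))
  invisible(x)
}

#' Synonymous codons of an unambiguous codon
#'
#' All codons other than the input that encode the same amino acid (or
#' stop).  The silent positional barcode of a saturation library is drawn
#' from this set at the codon immediately 3' of the randomized position.
#'
#' @param codon Character scalar, unambiguous codon.
#' @return Character vector (possibly empty: Met and Trp have no synonym),
#'   sorted lexicographically.
#' @export
synonymous_codons <- function(codon) {
  codon <- check_codon(codon)
  aa <- GENETIC_CODE_TABLE[codon]
  syn <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
  sort(setdiff(syn, codon))
}

# Translate a vector of codons (vectorized; no validation).
translate_codons <- function(codons) unname(GENETIC_CODE_TABLE[codons])
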