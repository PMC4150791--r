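# Generational frequency trajectories, normalized logo matrices with
# starting-library (G0) correction, and replicate-concordance metrics.

group_key <- function(lib, gen) paste(lib, gen, sep = ":")

#' Codon and amino-acid frequency matrices from a count table
#'
#' For each (library, generation) sample: codon frequency = count / depth
#' over the 64-codon alphabet, and amino-acid frequency = sum of
#' synonymous codon frequencies over the 21-symbol alphabet (stop
#' included).  Non-NNS codons observed through sequencing error contribute
#' to their translation like any other codon.
#'
#' @param ct A `count_table` (or its `counts` data.frame).
#' @return Object of class `frequency_matrix`: list with `codon` (matrix
#'   samples x 64), `aa` (matrix samples x 21), `depth` (named vector),
#'   `library_id`, `generation` (vectors aligned with rows).  Row names
#'   are `"library:generation"`.
#' @export
frequencies <- function(ct) {
  counts <- if (inherits(ct, "count_table")) ct$counts else ct
  if (!nrow(counts)) stop("empty count table", call. = FALSE)
  key <- group_key(counts$library_id, counts$generation)
  groups <- unique(key)
  codons <- codon_alphabet()
  cmat <- matrix(0, nrow = length(groups), ncol = 64L,
                 dimnames = list(groups, codons))
  for (i in seq_len(nrow(counts)))
    cmat[key[i], counts$codon[i]] <- cmat[key[i], counts$codon[i]] +
      counts$count[i]
  depth <- rowSums(cmat)
  zero <- depth == 0
  if (any(zero)) {
    warning("omitting zero-depth sample(s): ",
            paste(groups[zero], collapse = ", "), call. = FALSE)
    cmat <- cmat[!zero, , drop = FALSE]
    groups <- groups[!zero]
    depth <- depth[!zero]
  }
  fmat <- cmat / depth
  aa_of <- translate_codons(codons)
  amat <- t(apply(fmat, 1L, function(row) tapply(row, aa_of, sum)))
  full <- matrix(0, nrow = nrow(fmat), ncol = 21L,
                 dimnames = list(groups, aa_alphabet()))
  full[, colnames(amat)] <- amat
  parts <- strsplit(groups, ":", fixed = TRUE)
  structure(list(codon = fmat, aa = full,
                 depth = stats::setNames(depth, groups),
                 library_id = vapply(parts, `[[`, "", 1L),
                 generation = vapply(parts, `[[`, "", 2L)),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("Frequency matrix:", nrow(x$aa), "samples (",
      length(unique(x$library_id)), "libraries x",
      length(unique(x$generation)), "generations )\n")
  invisible(x)
}

# Amino-acid counts per sample from a count table (codon counts summed by
# translation), as a samples x 21 matrix.
aa_count_matrix <- function(ct) {
  counts <- if (inherits(ct, "count_table")) ct$counts else ct
  key <- group_key(counts$library_id, counts$generation)
  aa <- translate_codons(counts$codon)
  groups <- unique(key)
  mat <- matrix(0, nrow = length(groups), ncol = 21L,
                dimnames = list(groups, aa_alphabet()))
  for (i in seq_len(nrow(counts)))
    mat[key[i], aa[i]] <- mat[key[i], aa[i]] + counts$count[i]
  mat
}

#' Per-position logo matrix
#'
#' Per library (= randomized position), normalized amino-acid heights at
#' the chosen generation.  `mode = "raw"` uses the amino-acid frequencies
#' directly; `mode = "corrected"` scales them by the starting-library (G0)
#' frequencies — `(c_gen + a) / (c_G0 + a)` on per-symbol counts with
#' pseudocount `a`, renormalized per position — which removes the
#' codon-multiplicity bias of the NNS design (e.g. Arg starts at 3/32
#' rather than 1/32).
#'
#' @param ct A `count_table` covering `generation` (and `g0` in corrected
#'   mode) for every library.
#' @param generation Generation whose distribution is displayed (default
#'   `"G3"`).
#' @param mode `"raw"` or `"corrected"`.
#' @param g0 Label of the starting generation (default `"G0"`).
#' @param pseudocount Per-symbol pseudocount `a` (default 0.5).
#' @param libraries Optional library ids to restrict to (drops stray
#'   cross-talk bins produced by sequencing error).
#' @return Object of class `logo_matrix`: matrix libraries x 21 symbols
#'   (rows sum to 1) with attributes `mode` and `generation`.
#' @export
logo_matrix <- function(ct, generation = "G3",
                        mode = c("raw", "corrected"), g0 = "G0",
                        pseudocount = 0.5, libraries = NULL) {
  mode <- match.arg(mode)
  mat <- aa_count_matrix(ct)
  parts <- strsplit(rownames(mat), ":", fixed = TRUE)
  libs <- vapply(parts, `[[`, "", 1L)
  gens <- vapply(parts, `[[`, "", 2L)
  sel <- gens == generation
  if (!is.null(libraries)) sel <- sel & libs %in% libraries
  if (!any(sel)) stop("no samples at generation ", generation, call. = FALSE)
  target <- mat[sel, , drop = FALSE]
  rownames(target) <- libs[sel]
  if (mode == "raw") {
    heights <- target / rowSums(target)
  } else {
    base_sel <- gens == g0
    if (!any(base_sel))
      stop("corrected mode requires generation ", g0, " in the table",
           call. = FALSE)
    base <- mat[base_sel, , drop = FALSE]
    rownames(base) <- libs[base_sel]
    missing_g0 <- setdiff(rownames(target), rownames(base))
    if (length(missing_g0))
      stop("no ", g0, " sample for library: ",
           paste(missing_g0, collapse = ", "), call. = FALSE)
    base <- base[rownames(target), , drop = FALSE]
    f_gen <- (target + pseudocount) / rowSums(target + pseudocount)
    f_g0 <- (base + pseudocount) / rowSums(base + pseudocount)
    ratio <- f_gen / f_g0
    heights <- ratio / rowSums(ratio)
  }
  structure(heights, class = c("logo_matrix", class(heights)),
            mode = mode, generation = generation)
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Logo matrix (", attr(x, "mode"), " heights at ",
      attr(x, "generation"), "), ", nrow(x), " positions\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Write a logo matrix as TSV
#' @param logo A `logo_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(logo, path) {
  df <- data.frame(library_id = rownames(logo),
                   as.data.frame(unclass(logo), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Concordance between two frequency vectors
#'
#' Euclidean distance `sqrt(sum((f1 - f2)^2))` and cosine similarity
#' `sum(f1 * f2) / (||f1|| ||f2||)` between two amino-acid (or codon)
#' frequency vectors over the same symbol space — the replicate-agreement
#' metrics for duplicate libraries selected independently.
#'
#' @param f1,f2 Non-negative numeric vectors of equal length (aligned by
#'   name when both are named).
#' @return Object of class `concordance_report`: list with
#'   `euclidean_distance` and `cosine_similarity`.
#' @export
concordance <- function(f1, f2) {
  if (!is.null(names(f1)) && !is.null(names(f2))) {
    if (!setequal(names(f1), names(f2)))
      stop("f1 and f2 cover different symbol spaces", call. = FALSE)
    f2 <- f2[names(f1)]
  }
  if (length(f1) != length(f2))
    stop("f1 and f2 must have equal length", call. = FALSE)
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0)
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  structure(list(euclidean_distance = sqrt(sum((f1 - f2)^2)),
                 cosine_similarity = sum(f1 * f2) / (n1 * n2)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: Euclidean distance %.4f, cosine similarity %.4f\n",
              x$euclidean_distance, x$cosine_similarity))
  invisible(x)
}

#' Generational trajectory of every symbol in one library
#'
#' Frequency series across generations with per-generation fixation flags
#' at a configurable threshold.
#'
#' @param freqs A `frequency_matrix`.
#' @param library_id Library to report.
#' @param level `"aa"` (default) or `"codon"`.
#' @param threshold Fixation threshold (default 0.9).
#' @return Object of class `trajectory_report`: list with `series`
#'   (matrix symbols x generations), `fixed` (logical matrix, frequency >
#'   threshold), `threshold`.
#' @export
trajectory_report <- function(freqs, library_id, level = c("aa", "codon"),
                              threshold = 0.9) {
  level <- match.arg(level)
  sel <- freqs$library_id == library_id
  if (sum(sel) < 2L)
    stop("need >= 2 generations for library ", library_id, call. = FALSE)
  mat <- freqs[[level]][sel, , drop = FALSE]
  gens <- freqs$generation[sel]
  mat <- mat[order(gens), , drop = FALSE]
  series <- t(mat)
  colnames(series) <- sort(gens)
  structure(list(series = series, fixed = series > threshold,
                 threshold = threshold, library_id = library_id),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("Trajectory for library", x$library_id, "\n")
  keep <- rowSums(x$series) > 0
  print(round(x$series[keep, , drop = FALSE], 3))
  fixed <- which(x$fixed[, ncol(x$fixed)])
  if (length(fixed))
    cat("Fixed (>", x$threshold, ") at ", colnames(x$fixed)[ncol(x$fixed)],
        ": ", paste(rownames(x$fixed)[fixed], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
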