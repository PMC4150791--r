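# Dual-barcode read decoding: generational barcode + single positional
# silent-codon barcode; codon tabulation at the randomized position and
# off-target mutation tracking.
#
# Reads are anchored by exact match of a constant 12-bp flank (the first
# 12 nt of the amplicon window) immediately after the generational barcode;
# there is no alignment step, so indels are outside the error model.

ANCHOR_LEN <- 12L

# Per-base Hamming distance between equal-length string vectors (vectorized
# over x, scalar or recycled y).
string_mismatches <- function(x, y, n) {
  mm <- integer(length(x))
  for (i in seq_len(n))
    mm <- mm + (substr(x, i, i) != substr(y, i, i))
  mm
}

reverse_complement <- function(reads) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
}

#' Assign reads to a generation by their 8-bp barcode
#'
#' Exact match (default) of the barcode-length substring at the expected
#' offset (after the leader) against the barcode map.  With
#' `max_mismatch = 1`, nearest-unique semantics apply: a read within one
#' mismatch of exactly one barcode is assigned, ties are rejected.
#'
#' @param reads Character vector of reads (already oriented).
#' @param barcodes A [generation_barcode_set].
#' @param max_mismatch 0 (default) or 1.
#' @return Character vector: generation label, or `"REJECT:too_short"` /
#'   `"REJECT:no_generation_barcode"`.
#' @export
assign_generation <- function(reads, barcodes, max_mismatch = 0L) {
  off <- nchar(barcodes$leader)
  blen <- barcodes$barcode_length
  out <- rep("REJECT:no_generation_barcode", length(reads))
  too_short <- nchar(reads) < off + blen
  out[too_short] <- "REJECT:too_short"
  obs <- substr(reads, off + 1L, off + blen)
  if (max_mismatch == 0L) {
    hit <- match(obs, barcodes$barcodes)
    ok <- !is.na(hit) & !too_short
    out[ok] <- names(barcodes$barcodes)[hit[ok]]
  } else {
    mm <- vapply(barcodes$barcodes,
                 function(b) string_mismatches(obs, b, blen),
                 integer(length(obs)))
    mm <- matrix(mm, ncol = length(barcodes$barcodes))
    within <- mm <= max_mismatch
    n_hit <- rowSums(within)
    ok <- n_hit == 1L & !too_short
    out[ok] <- names(barcodes$barcodes)[max.col(within)[ok]]
  }
  out
}

#' Assign read payloads to a positional library
#'
#' Tests, for every library, whether the codon at its silent-barcode slot
#' equals the library's barcode codon.  Exactly one hit assigns the read.
#' With multiple hits, a hit that falls inside a candidate library's own
#' randomized (NNS) codon is discounted for that candidate: the codon at a
#' library's variable position may legitimately coincide with a neighboring
#' library's barcode.  If exactly one candidate explains all other hits
#' this way the read is assigned to it; otherwise it is rejected as
#' carrying multiple positional barcodes (chimera).
#'
#' @param payloads Character vector of amplicon-aligned payloads (read with
#'   leader + generational barcode stripped).
#' @param libraries List of `positional_library` objects.
#' @param amplicon_length Expected payload length; shorter payloads are
#'   rejected as length mismatches, longer ones are truncated.
#' @return Character vector: `library_id`, or
#'   `"REJECT:no_positional_barcode"` /
#'   `"REJECT:multiple_positional_barcodes"` / `"REJECT:length_mismatch"`.
#' @export
assign_position <- function(payloads, libraries, amplicon_length) {
  short <- nchar(payloads) < amplicon_length
  hits <- vapply(libraries, function(lib) {
    off <- lib$barcode_codon_start
    substr(payloads, off + 1L, off + 3L) == lib$barcode_codon
  }, logical(length(payloads)))
  hits <- matrix(hits, ncol = length(libraries))
  n_hit <- rowSums(hits)
  out <- rep("REJECT:no_positional_barcode", length(payloads))
  lib_ids <- vapply(libraries, `[[`, "", "library_id")
  one <- n_hit == 1L
  out[one] <- lib_ids[max.col(hits)[one]]
  multi <- which(n_hit >= 2L)
  if (length(multi)) {
    # excused[m, l]: library m's barcode slot lies inside library l's NNS
    # codon, so a hit on m does not disqualify candidate l
    bc_start <- vapply(libraries, `[[`, 0L, "barcode_codon_start")
    nns_start <- vapply(libraries, `[[`, 0L, "nns_codon_start")
    excused <- outer(bc_start, nns_start, "==")
    for (i in multi) {
      hit_idx <- which(hits[i, ])
      consistent <- vapply(hit_idx, function(l)
        all(excused[setdiff(hit_idx, l), l]), NA)
      out[i] <- if (sum(consistent) == 1L) lib_ids[hit_idx[consistent]]
        else "REJECT:multiple_positional_barcodes"
    }
  }
  out[short] <- "REJECT:length_mismatch"
  out
}

# Amplicon positions (1-based nt) excluded from off-target comparison:
# the anchor flank, every silent-barcode slot, and every NNS-capable codon
# in the panel.
excluded_positions <- function(ref, libraries) {
  excl <- seq_len(ANCHOR_LEN)
  for (lib in libraries) {
    excl <- c(excl,
              lib$nns_codon_start + 1:3,
              lib$barcode_codon_start + 1:3)
  }
  sort(unique(excl))
}

#' Decode a batch of reads
#'
#' Full Sat-Sel-Seq decoding: orientation (forward, then reverse
#' complement, anchored on a constant 12-bp flank), generational barcode,
#' positional barcode, codon observation at the assigned library's NNS
#' slot, and off-target mismatch counting over comparable bases (all
#' amplicon positions outside the anchor, the NNS-capable codons and the
#' barcode slots).
#'
#' @param reads Character vector of reads.
#' @param ref A [reference_amplicon].
#' @param libraries List of `positional_library` objects.
#' @param barcodes A [generation_barcode_set].
#' @param ids Optional read identifiers.
#' @param max_mismatch Generational-barcode mismatch tolerance (0 or 1).
#' @return A data.frame ledger (class `decoded_reads`) with one row per
#'   read: `read_id`, `generation`, `library_id`, `codon`, `reject`
#'   (`NA` for accepted reads), `off_target_mismatches`,
#'   `comparable_bases`.
#' @export
decode_reads <- function(reads, ref, libraries, barcodes,
                         ids = NULL, max_mismatch = 0L) {
  n <- length(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  off <- nchar(barcodes$leader) + barcodes$barcode_length
  amplen <- nchar(ref$cds_window)
  anchor <- substr(ref$cds_window, 1L, ANCHOR_LEN)

  reject <- rep(NA_character_, n)
  too_short <- nchar(reads) < off + ANCHOR_LEN
  reject[too_short] <- "too_short"

  # orientation: forward anchor, else reverse complement, else reject
  oriented <- reads
  fwd_ok <- !too_short &
    substr(reads, off + 1L, off + ANCHOR_LEN) == anchor
  retry <- !too_short & !fwd_ok
  if (any(retry)) {
    rc <- reverse_complement(reads[retry])
    rc_ok <- substr(rc, off + 1L, off + ANCHOR_LEN) == anchor
    oriented[retry][rc_ok] <- rc[rc_ok]
    reject[retry][!rc_ok] <- "orientation"
  }
  live <- is.na(reject)

  generation <- rep(NA_character_, n)
  gen <- assign_generation(oriented[live], barcodes, max_mismatch)
  gen_rej <- startsWith(gen, "REJECT:")
  reject[live][gen_rej] <- sub("^REJECT:", "", gen[gen_rej])
  generation[live][!gen_rej] <- gen[!gen_rej]
  live <- is.na(reject)

  library_id <- rep(NA_character_, n)
  codon <- rep(NA_character_, n)
  mm_count <- rep(NA_integer_, n)
  comp_count <- rep(NA_integer_, n)
  if (any(live)) {
    payloads <- substr(oriented[live], off + 1L, off + amplen)
    pos <- assign_position(payloads, libraries, amplen)
    pos_rej <- startsWith(pos, "REJECT:")
    reject[live][pos_rej] <- sub("^REJECT:", "", pos[pos_rej])
    library_id[live][!pos_rej] <- pos[!pos_rej]

    acc <- which(live)[!pos_rej]
    if (length(acc)) {
      acc_payloads <- payloads[!pos_rej]
      lib_by_id <- stats::setNames(
        libraries, vapply(libraries, `[[`, "", "library_id"))
      nns_off <- vapply(lib_by_id[library_id[acc]], `[[`, 0L,
                        "nns_codon_start")
      codon[acc] <- substr(acc_payloads, nns_off + 1L, nns_off + 3L)
      comparable <- setdiff(seq_len(amplen),
                            excluded_positions(ref, libraries))
      mm <- integer(length(acc))
      ref_chars <- strsplit(ref$cds_window, "")[[1]]
      for (p in comparable)
        mm <- mm + (substr(acc_payloads, p, p) != ref_chars[p])
      mm_count[acc] <- mm
      comp_count[acc] <- length(comparable)
    }
  }
  structure(data.frame(read_id = ids, generation = generation,
                       library_id = library_id, codon = codon,
                       reject = reject,
                       off_target_mismatches = mm_count,
                       comparable_bases = comp_count),
            class = c("decoded_reads", "data.frame"))
}

#' Tabulate decoded reads into a count table
#'
#' Per accepted read, increments the count of
#' `(library, generation, observed NNS-slot codon)`; rejected reads are
#' tallied by reason.  Accepted + rejected always equals the total.  The
#' observed codon is tabulated even when it is not a legal NNS codon
#' (third base A/T arises from sequencing error); the `is_nns` QC column
#' flags such codons.
#'
#' @param reads Character vector of reads (or a `decoded_reads` ledger).
#' @param ref,libraries,barcodes,ids,max_mismatch Passed to
#'   [decode_reads()] when `reads` is a character vector.
#' @return Object of class `count_table`: list with `counts` (data.frame
#'   `library_id`, `generation`, `codon`, `count`, `is_nns`), `rejects`
#'   (named integer), `total_reads`, `ledger`.
#' @export
tabulate_reads <- function(reads, ref, libraries, barcodes, ids = NULL,
                           max_mismatch = 0L) {
  ledger <- if (inherits(reads, "decoded_reads")) reads else
    decode_reads(reads, ref, libraries, barcodes, ids, max_mismatch)
  acc <- ledger[is.na(ledger$reject), ]
  counts <- as.data.frame(table(library_id = acc$library_id,
                                generation = acc$generation,
                                codon = acc$codon),
                          stringsAsFactors = FALSE)
  names(counts)[names(counts) == "Freq"] <- "count"
  counts <- counts[counts$count > 0, ]
  counts <- counts[order(counts$library_id, counts$generation,
                         counts$codon), ]
  rownames(counts) <- NULL
  counts$is_nns <- counts$codon %in% expand_degenerate("NNS")
  rej_tab <- table(ledger$reject[!is.na(ledger$reject)])
  rejects <- stats::setNames(as.integer(rej_tab), names(rej_tab))
  structure(list(counts = counts, rejects = rejects,
                 total_reads = nrow(ledger), ledger = ledger),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", sum(x$counts$count), "reads accepted,",
      sum(x$rejects), "rejected, of", x$total_reads, "total\n")
  if (length(x$rejects)) {
    cat("Rejects:\n")
    for (r in names(x$rejects))
      cat(sprintf("  %s: %d\n", r, x$rejects[[r]]))
  }
  invisible(x)
}

#' Off-target substitution rate per base
#'
#' Pooled mismatch rate over accepted reads:
#' `sum(off_target_mismatches) / sum(comparable_bases)`.  Comparable bases
#' exclude the anchor flank, every NNS-capable codon and every barcode
#' slot, so the estimate is not conditioned on the decoding filters.
#'
#' @param ledger A `decoded_reads` ledger (or a `count_table`).
#' @return Rate per base (numeric scalar).
#' @export
off_target_rate <- function(ledger) {
  if (inherits(ledger, "count_table")) ledger <- ledger$ledger
  acc <- ledger[is.na(ledger$reject), ]
  if (!nrow(acc)) stop("no accepted reads", call. = FALSE)
  total <- sum(acc$comparable_bases)
  if (total == 0) stop("zero comparable bases", call. = FALSE)
  sum(acc$off_target_mismatches) / total
}

#' Write / read a count table as TSV
#'
#' Long-format TSV with columns `library_id`, `generation`, `codon`,
#' `count`, `is_nns`.
#'
#' @param ct A `count_table` (or its `counts` data.frame).
#' @param path File path.
#' @return `path` invisibly ([write_count_table]); a `count_table` without
#'   ledger ([read_count_table]).
#' @export
write_count_table <- function(ct, path) {
  counts <- if (inherits(ct, "count_table")) ct$counts else ct
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = c(codon = "character"))
  structure(list(counts = counts, rejects = integer(),
                 total_reads = sum(counts$count), ledger = NULL),
            class = "count_table")
}
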