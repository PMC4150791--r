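# In-silico selection campaign: NNS starting populations, fitness-weighted
# multinomial bottleneck selection (the counterpart of iterated
# rifampin-plate selection rounds), and barcoded amplicon reads with
# substitution noise.

#' Construct an amino-acid level fitness map
#'
#' Relative fitness per amino-acid symbol; synonymous codons share the
#' amino acid's fitness unless a codon-level override is given.  Stop
#' defaults to fitness 0 (the expression cassette carries a stop codon for
#' negative selection, so truncations are non-functional).
#'
#' @param values Named numeric vector, names in [aa_alphabet()]; symbols
#'   not named default to 1 (stop: 0).
#' @param codon_overrides Optional named numeric vector keyed by codon.
#' @return Object of class `fitness_map`.
#' @export
fitness_map <- function(values = numeric(), codon_overrides = numeric()) {
  w <- stats::setNames(rep(1, 21L), aa_alphabet())
  w["*"] <- 0
  if (length(values)) {
    bad <- setdiff(names(values), aa_alphabet())
    if (length(bad)) stop("unknown symbol(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    w[names(values)] <- values
  }
  if (any(w < 0)) stop("fitness must be >= 0", call. = FALSE)
  if (!any(w > 0)) stop("at least one fitness must be > 0", call. = FALSE)
  structure(list(aa = w, codon_overrides = codon_overrides),
            class = "fitness_map")
}

#' Demonstration fitness landscape
#'
#' A fixed, fully ranked landscape for simulated campaigns: the 20 amino
#' acids receive distinct relative fitnesses on a geometric ladder from
#' 0.25 to 2.5 (alphabetical order, so the map is deterministic and easy to
#' rank against), stop 0.  A ten-fold spread between best and worst variant
#' echoes the dynamic range over which loop substitutions modulate
#' deaminase activity.
#'
#' @return A [fitness_map].
#' @export
demo_fitness_map <- function() {
  aas <- setdiff(aa_alphabet(), "*")
  fitness_map(stats::setNames(0.25 * 10^(seq(0, 1, length.out = 20)), aas))
}

# Per-codon fitness over an arbitrary codon set.
codon_fitness <- function(fitness, codons) {
  w <- unname(fitness$aa[translate_codons(codons)])
  if (length(fitness$codon_overrides)) {
    hit <- match(codons, names(fitness$codon_overrides))
    w[!is.na(hit)] <- fitness$codon_overrides[hit[!is.na(hit)]]
  }
  stats::setNames(w, codons)
}

#' Draw a starting (G0) population for one positional library
#'
#' Multinomial draw of `depth` variants over the 32 NNS codons,
#' uniform by default or with a user skew (cloning efficiency differences).
#'
#' @param depth Number of variant molecules drawn.
#' @param skew Optional numeric vector of length 32 (order of
#'   `expand_degenerate("NNS")`), renormalized internally.
#' @param seed Integer RNG seed.
#' @return Object of class `population`: list with `counts` (named integer
#'   over the 32 NNS codons) and `generation` (0).
#' @export
initial_population <- function(depth, skew = NULL, seed = 1L) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  codons <- expand_degenerate("NNS")
  p <- if (is.null(skew)) rep(1 / 32, 32L) else {
    if (length(skew) != 32L)
      stop("skew must have length 32", call. = FALSE)
    skew / sum(skew)
  }
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, depth, p))
  structure(list(counts = stats::setNames(counts, codons), generation = 0L),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population at generation", x$generation, ":", sum(x$counts),
      "individuals,", sum(x$counts > 0), "variants\n")
  invisible(x)
}

#' One round of fitness-weighted bottleneck selection
#'
#' Survivors of a selection plate are a multinomial draw of `B` individuals
#' with probability proportional to `count * fitness`; the pooled survivors
#' are regrown, so relative fitness absorbs both plating survival and
#' growth effects.
#'
#' @param pop A `population`.
#' @param fitness A [fitness_map].
#' @param B Bottleneck size (number of surviving colonies).  A warning is
#'   issued when `B` is below 10x the number of distinct variants
#'   (representation falls under the 10-fold coverage rule).
#' @param seed Integer RNG seed.
#' @return A `population` at generation + 1.
#' @export
select_generation <- function(pop, fitness, B, seed = 1L) {
  w <- codon_fitness(fitness, names(pop$counts))
  mass <- pop$counts * w
  if (sum(mass) <= 0)
    stop("extinction: no variant carries positive fitness mass",
         call. = FALSE)
  n_var <- sum(pop$counts > 0 & w > 0)
  if (B < 10 * n_var)
    warning("bottleneck ", B, " is below 10-fold representation of ",
            n_var, " viable variants", call. = FALSE)
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, B, mass / sum(mass)))
  structure(list(counts = stats::setNames(counts, names(pop$counts)),
                 generation = pop$generation + 1L),
            class = "population")
}

#' Deterministic expectation of selection dynamics
#'
#' Expected variant frequencies after `t` rounds of selection:
#' `p' = p * w / sum(p * w)` iterated.  Used as the analytic oracle for the
#' stochastic simulator.
#'
#' @param p Numeric vector of starting frequencies (normalized internally).
#' @param w Numeric vector of fitnesses, same length.
#' @param t Number of selection rounds.
#' @return Numeric vector of expected frequencies.
#' @export
expected_frequencies <- function(p, w, t = 1L) {
  p <- p / sum(p)
  for (i in seq_len(t)) p <- p * w / sum(p * w)
  p
}

#' Default generational barcode set
#'
#' Four 8-bp barcodes (G0-G3) at pairwise Hamming distance 8, preceded by a
#' fixed 10-nt sequencing leader.
#'
#' @return Object of class `generation_barcode_set`.
#' @export
default_generation_barcodes <- function() {
  generation_barcode_set(c(G0 = "ATCGATCG", G1 = "CAGTCAGT",
                           G2 = "GCTAGCTA", G3 = "TGACTGAC"),
                         leader = "CGTATCGCCT")
}

#' Construct a generational barcode set
#'
#' @param barcodes Named character vector, generation label -> barcode;
#'   equal lengths, unique.  A warning is issued when any pair is closer
#'   than Hamming distance 2.
#' @param leader Constant leader sequence preceding the barcode in every
#'   read (may be `""`).
#' @return Object of class `generation_barcode_set`.
#' @export
generation_barcode_set <- function(barcodes, leader = "") {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    stop("barcodes must be named by generation label", call. = FALSE)
  if (length(unique(nchar(barcodes))) != 1L)
    stop("barcodes must have equal length", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("barcodes must be unique", call. = FALSE)
  n <- length(barcodes)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      d <- sum(strsplit(barcodes[[i]], "")[[1]] !=
               strsplit(barcodes[[j]], "")[[1]])
      if (d < 2L)
        warning("barcodes ", names(barcodes)[i], " and ",
                names(barcodes)[j], " are at Hamming distance ", d,
                call. = FALSE)
    }
  }
  structure(list(barcodes = barcodes, leader = leader,
                 barcode_length = nchar(barcodes[[1]])),
            class = "generation_barcode_set")
}

#' Simulate amplicon reads from a population
#'
#' Each read samples a variant proportionally to its population count,
#' renders `leader + generational barcode + amplicon` with the library's
#' silent barcode and the variant codon substituted, then applies i.i.d.
#' substitution errors at rate `epsilon` per base (uniform over the three
#' alternative bases).
#'
#' @param pop A `population`.
#' @param ref A [reference_amplicon].
#' @param lib A `positional_library`.
#' @param generation Generation label (must be in `barcodes`).
#' @param barcodes A [generation_barcode_set].
#' @param R Number of reads.
#' @param epsilon Substitution rate per base in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return List with `reads` (character vector), `ids`, and `truth`
#'   (data.frame `read_id`, `library_id`, `generation`, `codon`).
#' @export
simulate_reads <- function(pop, ref, lib, generation, barcodes, R,
                           epsilon = 7e-4, seed = 1L) {
  if (R <= 0) stop("R must be positive", call. = FALSE)
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must be in [0, 1)", call. = FALSE)
  if (!generation %in% names(barcodes$barcodes))
    stop("unknown generation label '", generation, "'", call. = FALSE)
  set.seed(seed)
  variants <- sample(names(pop$counts), R, replace = TRUE,
                     prob = pop$counts / sum(pop$counts))
  payload <- library_reference_seq(ref, lib)
  payloads <- set_codon(rep(payload, R), lib$nns_codon_start, variants)
  reads <- paste0(barcodes$leader, barcodes$barcodes[[generation]], payloads)
  reads <- add_substitution_noise(reads, epsilon)
  ids <- sprintf("%s_%s_%06d", lib$library_id, generation, seq_len(R))
  list(reads = reads, ids = ids,
       truth = data.frame(read_id = ids, library_id = lib$library_id,
                          generation = generation, codon = variants))
}

# Apply i.i.d. substitution noise at rate eps to equal-length reads.
# Draws the total number of mutated cells Binomial(N*L, eps), then a
# uniform subset of cells, which is distributionally identical to
# independent per-base mutation.
add_substitution_noise <- function(reads, eps) {
  if (eps == 0 || !length(reads)) return(reads)
  L <- nchar(reads[1])
  n_cell <- length(reads) * L
  k <- stats::rbinom(1L, n_cell, eps)
  if (k == 0L) return(reads)
  cells <- sample.int(n_cell, k)
  read_i <- (cells - 1L) %/% L + 1L
  pos_j <- (cells - 1L) %% L + 1L
  old <- substr(reads[read_i], pos_j, pos_j)
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3)
  new <- alt[cbind(sample.int(3L, k, replace = TRUE),
                   match(old, c("A", "C", "G", "T")))]
  for (m in seq_len(k))
    substr(reads[read_i[m]], pos_j[m], pos_j[m]) <- new[m]
  reads
}

#' Campaign configuration
#'
#' @param libraries List of `positional_library` objects.
#' @param ref A [reference_amplicon].
#' @param fitness A [fitness_map].
#' @param depth Initial population size per library.
#' @param bottleneck Survivors per selection round (`B`).
#' @param generations Number of selection rounds after G0 (`T`).
#' @param reads_per_sample Reads emitted per (library, generation) (`R`).
#' @param epsilon Substitution error rate per base.
#' @param barcodes A [generation_barcode_set]; must provide labels for
#'   G0..G`generations`.
#' @param seed Master RNG seed; all per-stage seeds derive from it.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(libraries, ref = aid_loop_amplicon(),
                            fitness = demo_fitness_map(),
                            depth = 1e4, bottleneck = 1e4,
                            generations = 3L, reads_per_sample = 5000L,
                            epsilon = 7e-4,
                            barcodes = default_generation_barcodes(),
                            seed = 1L) {
  gens <- paste0("G", 0:generations)
  missing_bc <- setdiff(gens, names(barcodes$barcodes))
  if (length(missing_bc))
    stop("barcode set lacks generation(s): ",
         paste(missing_bc, collapse = ", "), call. = FALSE)
  structure(list(libraries = libraries, ref = ref, fitness = fitness,
                 depth = depth, bottleneck = bottleneck,
                 generations = as.integer(generations),
                 reads_per_sample = as.integer(reads_per_sample),
                 epsilon = epsilon, barcodes = barcodes,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' Run a full in-silico selection campaign
#'
#' For each library: draw the G0 population, iterate bottleneck selection
#' for `generations` rounds, and emit reads for every generation.  All
#' randomness derives from the master seed through per-stage sub-seeds, so
#' campaigns are reproducible stage by stage.
#'
#' @param config A [campaign_config].
#' @return Object of class `campaign`: list with `reads`, `ids`,
#'   `truth_reads` (per-read truth), `truth_pop` (data.frame `library_id`,
#'   `generation`, `codon`, `count`, `freq`: true population composition),
#'   and `config`.
#' @export
run_campaign <- function(config) {
  set.seed(config$seed)
  n_stage <- length(config$libraries) * (3L * config$generations + 3L)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_stage)
  s <- 0L
  next_seed <- function() { s <<- s + 1L; subseeds[s] }

  reads <- character(); ids <- character()
  truth_reads <- list(); truth_pop <- list()
  for (lib in config$libraries) {
    pop <- initial_population(config$depth, seed = next_seed())
    for (g in 0:config$generations) {
      gen <- paste0("G", g)
      if (g > 0)
        pop <- select_generation(pop, config$fitness, config$bottleneck,
                                 seed = next_seed())
      sim <- simulate_reads(pop, config$ref, lib, gen, config$barcodes,
                            config$reads_per_sample, config$epsilon,
                            seed = next_seed())
      reads <- c(reads, sim$reads); ids <- c(ids, sim$ids)
      truth_reads[[length(truth_reads) + 1L]] <- sim$truth
      keep <- pop$counts > 0
      truth_pop[[length(truth_pop) + 1L]] <- data.frame(
        library_id = lib$library_id, generation = gen,
        codon = names(pop$counts)[keep],
        count = unname(pop$counts[keep]),
        freq = unname(pop$counts[keep] / sum(pop$counts)))
    }
  }
  structure(list(reads = reads, ids = ids,
                 truth_reads = do.call(rbind, truth_reads),
                 truth_pop = do.call(rbind, truth_pop),
                 config = config),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat("Sat-Sel-Seq campaign:", length(x$config$libraries), "libraries x",
      x$config$generations + 1L, "generations,", length(x$reads),
      "reads\n")
  invisible(x)
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads Character vector of read sequences.
#' @param ids Read identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, ids, path) {
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- ids
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), ""))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' Qualities are ignored (the decoder is quality-blind by design).
#'
#' @param path Input file.
#' @param format `"fastq"` or `"fasta"`; guessed from the extension by
#'   default.
#' @return List with `reads` (character) and `ids`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "fastq"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  list(reads = unname(as.character(seqs)), ids = names(seqs))
}
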