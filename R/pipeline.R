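# Pipeline binding: simulate -> demux -> enrichment -> reports, plus
# packaged demo fixtures.  All randomness flows from one master seed; every
# output is stamped with the seed and a config hash.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Build a pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param residues Residues to randomize (default the hotspot loop).
#' @param duplicates Residues built in duplicate (default 115).
#' @param depth,bottleneck,generations,reads_per_sample,epsilon Simulator
#'   parameters (see [campaign_config()]).
#' @param mode Logo mode, `"raw"` or `"corrected"`.
#' @param fixation_threshold Fixation-flag threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            residues = AID_LOOP_RESIDUES,
                            duplicates = 115L,
                            depth = 1e4, bottleneck = 1e4,
                            generations = 3L, reads_per_sample = 2000L,
                            epsilon = 7e-4,
                            mode = c("corrected", "raw"),
                            fixation_threshold = 0.9) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 residues = residues, duplicates = duplicates,
                 depth = depth, bottleneck = bottleneck,
                 generations = as.integer(generations),
                 reads_per_sample = as.integer(reads_per_sample),
                 epsilon = epsilon, mode = match.arg(mode),
                 fixation_threshold = fixation_threshold),
            class = "pipeline_config")
}

#' Run the full Sat-Sel-Seq pipeline
#'
#' Designs the library panel, simulates a selection campaign, writes and
#' re-reads the FASTQ, decodes and tabulates reads, and emits frequency,
#' logo, trajectory, concordance and QC reports.  Outputs are
#' deterministic for a fixed seed.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory artifacts (`panel`,
#'   `campaign`, `count_table`, `freqs`, `logo`, `concordance`, `qc`) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  hash <- config_hash(unclass(config))

  ref <- aid_loop_amplicon()
  panel <- build_library_panel(ref, config$residues, config$duplicates)
  barcodes <- default_generation_barcodes()
  camp_cfg <- campaign_config(panel, ref,
                              depth = config$depth,
                              bottleneck = config$bottleneck,
                              generations = config$generations,
                              reads_per_sample = config$reads_per_sample,
                              epsilon = config$epsilon,
                              barcodes = barcodes, seed = config$seed)
  camp <- run_campaign(camp_cfg)

  fq <- path("reads.fastq")
  write_reads_fastq(camp$reads, camp$ids, fq)
  io <- read_reads(fq)
  ct <- tabulate_reads(io$reads, ref, panel, barcodes, ids = io$ids)
  write_count_table(ct, path("counts.tsv"))
  utils::write.table(panel_manifest(panel), path("manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  freqs <- frequencies(ct)
  logo <- logo_matrix(ct, generation = paste0("G", config$generations),
                      mode = config$mode,
                      libraries = names(panel))
  write_logo_matrix(logo, path("logo.tsv"))

  conc <- NULL
  dup_ids <- grep("[ab]$", rownames(logo), value = TRUE)
  if (length(dup_ids) >= 2L) {
    g3 <- paste0("G", config$generations)
    k1 <- group_key(dup_ids[1L], g3); k2 <- group_key(dup_ids[2L], g3)
    if (all(c(k1, k2) %in% rownames(freqs$aa)))
      conc <- concordance(freqs$aa[k1, ], freqs$aa[k2, ])
  }

  qc <- list(seed = config$seed, config_hash = hash,
             total_reads = ct$total_reads,
             accepted_reads = sum(ct$counts$count),
             rejects = as.list(ct$rejects),
             off_target_rate = off_target_rate(ct))
  if (!is.null(conc))
    qc$duplicate_concordance <- unclass(conc)
  writeLines(jsonlite::toJSON(qc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path("qc.json"))

  invisible(list(panel = panel, campaign = camp, count_table = ct,
                 freqs = freqs, logo = logo, concordance = conc, qc = qc,
                 files = path(c("reads.fastq", "counts.tsv",
                                "manifest.tsv", "logo.tsv", "qc.json"))))
}

#' Write a packaged demo dataset
#'
#' Emits the 12-library manifest, the 4-generation barcode map, a small
#' simulated campaign FASTQ, toy assay tables (XXC panel, fluctuation
#' counts, kinetic series) and a 10-frame toy trajectory PDB.  Everything
#' is synthetic and deterministic in `seed`.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)

  ref <- aid_loop_amplicon()
  panel <- build_library_panel(ref)
  barcodes <- default_generation_barcodes()
  utils::write.table(panel_manifest(panel), path("manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(generation = names(barcodes$barcodes),
               barcode = unname(barcodes$barcodes),
               leader = barcodes$leader),
    path("barcodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  samples <- expand.grid(library_id = names(panel),
                         generation = names(barcodes$barcodes),
                         stringsAsFactors = FALSE)
  utils::write.table(samples[order(samples$library_id), ],
                     path("samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  camp <- run_campaign(campaign_config(
    panel, ref, depth = 1000, bottleneck = 1000,
    generations = 3L, reads_per_sample = 100L, epsilon = 0, seed = seed))
  write_reads_fastq(camp$reads, camp$ids, path("reads.fastq"))

  set.seed(seed)
  grid <- expand.grid(x2 = XXC_SYMBOLS, x1 = XXC_SYMBOLS,
                      stringsAsFactors = FALSE)
  w1 <- c(A = 0.30, mC = 0.08, G = 0.30, T = 0.12)  # WRC-flavored -1
  w2 <- c(A = 0.25, mC = 0.10, G = 0.15, T = 0.25)  # W-flavored -2
  grid$product_fraction <- round(pmin(
    w1[grid$x1] + w2[grid$x2] + stats::runif(16, 0, 0.02), 1), 4)
  utils::write.table(grid, path("xxc_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  utils::write.table(
    data.frame(strain = rep(c("WT", "R119G"), each = 5),
               resistant = c(stats::rpois(5, 30), stats::rpois(5, 120)),
               viable = 1e8),
    path("fluctuation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  S <- c(12.5, 25, 50, 100, 200, 400)
  v <- 10 * S / (50 + S) * (1 + stats::rnorm(6, 0, 0.03))
  utils::write.table(data.frame(conc_nM = S, rate = round(v, 4)),
                     path("kinetics.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_trajectory_pdb(toy_trajectory(seed = seed), path("trajectory.pdb"))
  invisible(path(c("manifest.tsv", "barcodes.tsv", "samples.tsv",
                   "reads.fastq", "xxc_panel.tsv", "fluctuation.tsv",
                   "kinetics.tsv", "trajectory.pdb")))
}

#' Build a small synthetic protein-DNA trajectory
#'
#' A toy 10-frame system: three protein residues (a Leu-Tyr-Arg tripeptide
#' skeleton of heavy atoms) near a 2-nucleotide DNA strand, with mild
#' frame-to-frame jitter.  Purely synthetic geometry for demonstrations
#' and tests.
#'
#' @param n_frames Number of frames (default 10).
#' @param seed RNG seed.
#' @return A [trajectory].
#' @export
toy_trajectory <- function(n_frames = 10L, seed = 1L) {
  protein <- data.frame(
    atom_id = 1:9,
    name = rep(c("N", "CA", "C"), 3),
    element = rep(c("N", "C", "C"), 3),
    resno = rep(113:115, each = 3),
    resid = rep(c("LEU", "TYR", "ARG"), each = 3))
  dna <- data.frame(
    atom_id = 10:15,
    name = rep(c("P", "C1'", "N1"), 2),
    element = rep(c("P", "C", "N"), 2),
    resno = rep(1:2, each = 3),
    resid = rep(c("DG", "DC"), each = 3))
  atoms <- rbind(protein, dna)
  base <- cbind(
    x = c(rep(c(0, 1.5, 3), 3), rep(c(6, 7.5, 9), 2)),
    y = c(rep(c(0, 3, 6), each = 3), rep(c(0, 3), each = 3)),
    z = rep(0, 15))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f)
    base + matrix(stats::rnorm(45, 0, 0.15), ncol = 3))
  trajectory(atoms, frames)
}
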