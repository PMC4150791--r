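# Build a read from parts for decoding tests.
make_read <- function(payload, generation = "G0",
                      barcodes = barcodes_fixture) {
  paste0(barcodes$leader, barcodes$barcodes[[generation]], payload)
}

test_that("generation assignment matches the 8-bp barcode at its offset", {
  bc <- barcodes_fixture
  reads <- c(make_read(ref_fixture$cds_window, "G1"),
             paste0(bc$leader, "AAAAAAAA", ref_fixture$cds_window),
             "ACGTA")
  out <- assign_generation(reads, bc)
  expect_identical(out, c("G1", "REJECT:no_generation_barcode",
                          "REJECT:too_short"))
  # tolerance 1 with nearest-unique semantics
  near <- make_read(ref_fixture$cds_window, "G2")
  substr(near, nchar(bc$leader) + 1L, nchar(bc$leader) + 1L) <- "T"
  expect_identical(assign_generation(near, bc, max_mismatch = 1L), "G2")
  amb <- generation_barcode_set(c(X = "AAAAAAAA", Y = "AAAAAACC"))
  expect_identical(assign_generation("AAAAAAAC", amb, max_mismatch = 1L),
                   "REJECT:no_generation_barcode")
})

test_that("close generation barcodes trigger a design warning", {
  expect_warning(generation_barcode_set(c(A = "AAAAAAAA", B = "AAAAAAAC")),
                 "Hamming distance 1")
  expect_error(generation_barcode_set(c(A = "AAAA", B = "AAAAAAAC")),
               "equal length")
})

test_that("positional assignment needs exactly one barcode hit", {
  libs <- panel_fixture
  wt <- ref_fixture$cds_window
  single <- library_reference_seq(ref_fixture, libs[["115a"]])
  chimera <- set_codon(single, libs[["113"]]$barcode_codon_start,
                       libs[["113"]]$barcode_codon)
  out <- assign_position(c(single, chimera, wt, substr(wt, 1, 50)),
                         libs, nchar(wt))
  expect_identical(out, c("115a", "REJECT:multiple_positional_barcodes",
                          "REJECT:no_positional_barcode",
                          "REJECT:length_mismatch"))
})

test_that("tabulation conserves reads and counts the observed NNS codon", {
  libs <- panel_fixture
  base115 <- library_reference_seq(ref_fixture, libs[["115a"]])
  r1 <- make_read(set_codon(base115, libs[["115a"]]$nns_codon_start, "TAC"))
  r3 <- make_read(set_codon(base115, libs[["115a"]]$nns_codon_start, "TTT"),
                  "G3")
  ct <- tabulate_reads(c(r1, r1, r3), ref_fixture, libs, barcodes_fixture)
  expect_identical(ct$total_reads, 3L)
  expect_identical(sum(ct$rejects), 0L)
  counts <- ct$counts[order(ct$counts$generation), ]
  expect_identical(counts$codon, c("TAC", "TTT"))
  expect_identical(counts$count, c(2L, 1L))
  # chimera rejected, conservation holds
  chim <- make_read(set_codon(base115, libs[["113"]]$barcode_codon_start,
                              libs[["113"]]$barcode_codon))
  ct2 <- tabulate_reads(c(r1, r1, r3, chim), ref_fixture, libs,
                        barcodes_fixture)
  expect_identical(ct2$total_reads, 4L)
  expect_identical(unname(ct2$rejects["multiple_positional_barcodes"]), 1L)
  expect_identical(sum(ct2$counts$count) + sum(ct2$rejects), 4L)
})

test_that("noise-free simulator output decodes to its exact truth", {
  cfg <- campaign_config(panel_fixture, ref_fixture, depth = 1000,
                         bottleneck = 1000, generations = 1L,
                         reads_per_sample = 50L, epsilon = 0, seed = 31)
  camp <- run_campaign(cfg)
  led <- decode_reads(camp$reads, ref_fixture, panel_fixture,
                      barcodes_fixture, ids = camp$ids)
  expect_true(all(is.na(led$reject)))
  m <- merge(led, camp$truth_reads, by = "read_id")
  expect_identical(m$library_id.x, m$library_id.y)
  expect_identical(m$generation.x, m$generation.y)
  expect_identical(m$codon.x, m$codon.y)
  expect_identical(off_target_rate(led), 0)
})

test_that("reverse-complement reads decode identically to forward reads", {
  cfg <- campaign_config(panel_fixture["117"], ref_fixture, depth = 500,
                         bottleneck = 500, generations = 0L,
                         reads_per_sample = 40L, epsilon = 0, seed = 5)
  camp <- run_campaign(cfg)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(camp$reads)))
  fwd <- decode_reads(camp$reads, ref_fixture, panel_fixture,
                      barcodes_fixture, ids = camp$ids)
  rev <- decode_reads(rc, ref_fixture, panel_fixture, barcodes_fixture,
                      ids = camp$ids)
  expect_identical(fwd, rev)
  # garbage fails orientation
  bad <- decode_reads(strrep("A", 320), ref_fixture, panel_fixture,
                      barcodes_fixture)
  expect_identical(bad$reject, "orientation")
})

test_that("off-target rate estimates the configured substitution rate", {
  eps <- 0.004
  cfg <- campaign_config(panel_fixture["115a"], ref_fixture, depth = 2000,
                         bottleneck = 2000, generations = 0L,
                         reads_per_sample = 4000L, epsilon = eps, seed = 17)
  camp <- run_campaign(cfg)
  led <- decode_reads(camp$reads, ref_fixture, panel_fixture,
                      barcodes_fixture, ids = camp$ids)
  rate <- off_target_rate(led)
  n <- sum(led$comparable_bases[is.na(led$reject)])
  se <- sqrt(eps * (1 - eps) / n)
  expect_lt(abs(rate - eps), 3 * se)
})

test_that("count tables round-trip through TSV", {
  cfg <- campaign_config(panel_fixture["113"], ref_fixture, depth = 500,
                         bottleneck = 500, generations = 0L,
                         reads_per_sample = 30L, epsilon = 0, seed = 2)
  camp <- run_campaign(cfg)
  ct <- tabulate_reads(camp$reads, ref_fixture, panel_fixture,
                       barcodes_fixture, ids = camp$ids)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, tsv)
  back <- read_count_table(tsv)
  expect_identical(back$counts$codon, ct$counts$codon)
  expect_identical(back$counts$count, ct$counts$count)
})
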