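test_that("initial populations are multinomial over the 32 NNS codons", {
  pop <- initial_population(3200, seed = 9)
  expect_identical(sum(pop$counts), 3200L)
  expect_setequal(names(pop$counts), expand_degenerate("NNS"))
  # uniform draw: each count within 5 SD of 100
  sd <- sqrt(3200 * (1 / 32) * (31 / 32))
  expect_true(all(abs(pop$counts - 100) < 5 * sd))
  # determinism and one-hot skew
  expect_identical(initial_population(3200, seed = 9)$counts, pop$counts)
  skew <- rep(0, 32); skew[5] <- 1
  one <- initial_population(100, skew = skew, seed = 1)
  expect_identical(unname(one$counts[5]), 100L)
  expect_error(initial_population(10, skew = c(1, 2)), "length 32")
})

test_that("neutral selection leaves expected frequencies unchanged", {
  pop <- initial_population(1e5, seed = 3)
  neutral <- fitness_map(stats::setNames(rep(1, 21), aa_alphabet()))
  sel <- select_generation(pop, neutral, 1e5, seed = 4)
  chi <- suppressWarnings(stats::chisq.test(
    sel$counts, p = pop$counts / sum(pop$counts)))
  expect_gt(chi$p.value, 0.01)
  expect_identical(sel$generation, 1L)
})

test_that("stop codons vanish under default negative selection", {
  pop <- initial_population(5000, seed = 8)
  sel <- select_generation(pop, demo_fitness_map(), 5000, seed = 2)
  expect_identical(unname(sel$counts["TAG"]), 0L)
  # all-zero fitness mass is an extinction error
  dead <- make_population(c(TAG = 100L))
  expect_error(select_generation(dead, demo_fitness_map(), 100),
               "extinction")
})

test_that("two-variant selection matches p' = p*w / sum(p*w)", {
  # w = (2, 1) from p0 = (0.5, 0.5): expected p1 = 2/3
  fit <- fitness_map(stats::setNames(c(2, 1), c("K", "N")))
  pop <- make_population(c(AAG = 500L, AAC = 500L))
  p1 <- vapply(1:50, function(seed) {
    s <- select_generation(pop, fit, 1000, seed = seed)
    s$counts[["AAG"]] / sum(s$counts)
  }, 0)
  se <- sd(p1) / sqrt(length(p1))
  expect_lt(abs(mean(p1) - 2 / 3), 2 * se + 1e-12)
  expect_equal(expected_frequencies(c(0.5, 0.5), c(2, 1)), c(2 / 3, 1 / 3))
})

test_that("neutral drift is a martingale across generations", {
  probe <- c("AAC", "CTG", "TAG")
  f0 <- 1 / 32
  neutral <- fitness_map(stats::setNames(rep(1, 21), aa_alphabet()))
  f3 <- vapply(1:100, function(s) {
    pop <- initial_population(3200, seed = s)
    for (g in 1:3)
      pop <- select_generation(pop, neutral, 3200, seed = s * 7L + g)
    pop$counts[probe] / sum(pop$counts)
  }, numeric(3))
  for (i in seq_along(probe)) {
    se <- sd(f3[i, ]) / sqrt(ncol(f3))
    expect_lt(abs(mean(f3[i, ]) - f0), 3 * se)
  }
})

test_that("simulated reads carry the configured structure and noise", {
  pop <- initial_population(1000, seed = 6)
  lib <- panel_fixture[["115a"]]
  sim <- simulate_reads(pop, ref_fixture, lib, "G0", barcodes_fixture,
                        R = 1000, epsilon = 0, seed = 3)
  expect_length(sim$reads, 1000L)
  expect_identical(unique(nchar(sim$reads)),
                   10L + 8L + nchar(ref_fixture$cds_window))
  led <- decode_reads(sim$reads, ref_fixture, list(lib), barcodes_fixture,
                      ids = sim$ids)
  expect_identical(led$codon, sim$truth$codon)
  # empirical mismatch fraction vs configured rate (binomial oracle)
  eps <- 0.003
  noisy <- simulate_reads(pop, ref_fixture, lib, "G0", barcodes_fixture,
                          R = 1000, epsilon = eps, seed = 3)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                  strsplit(b, "")[[1]]),
               noisy$reads, sim$reads)
  n <- sum(nchar(sim$reads))
  se <- sqrt(eps * (1 - eps) / n)
  expect_lt(abs(sum(mm) / n - eps), 3 * se)
})

test_that("campaigns iterate selection and expose a consistent truth table", {
  # T = 0: only G0 reads
  cfg0 <- campaign_config(panel_fixture["113"], ref_fixture, depth = 500,
                          bottleneck = 500, generations = 0L,
                          reads_per_sample = 20L, epsilon = 0, seed = 1)
  camp0 <- run_campaign(cfg0)
  expect_identical(unique(camp0$truth_reads$generation), "G0")
  # a strongly favored variant rises monotonically in expectation
  fav <- fitness_map(stats::setNames(
    c(10, rep(1, 19)), c("G", setdiff(setdiff(aa_alphabet(), "*"), "G"))))
  traj <- sapply(1:3, function(s) {
    cfg <- campaign_config(panel_fixture["119"], ref_fixture, depth = 5000,
                           bottleneck = 5000, generations = 3L,
                           reads_per_sample = 10L, epsilon = 0,
                           fitness = fav, seed = s)
    tp <- run_campaign(cfg)$truth_pop
    g_codons <- names(which(
      satselseq:::GENETIC_CODE_TABLE[expand_degenerate("NNS")] == "G"))
    vapply(paste0("G", 0:3), function(g) {
      sub <- tp[tp$generation == g, ]
      sum(sub$freq[sub$codon %in% g_codons])
    }, 0)
  })
  expect_true(all(diff(rowMeans(traj)) > 0))
  # determinism under fixed seed
  c1 <- run_campaign(cfg0); c2 <- run_campaign(cfg0)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$truth_pop, c2$truth_pop)
})

test_that("fastq output round-trips through Biostrings", {
  cfg <- campaign_config(panel_fixture["121"], ref_fixture, depth = 200,
                         bottleneck = 200, generations = 0L,
                         reads_per_sample = 25L, epsilon = 0, seed = 12)
  camp <- run_campaign(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(camp$reads, camp$ids, fq)
  back <- read_reads(fq)
  expect_identical(back$reads, camp$reads)
  expect_identical(back$ids, camp$ids)
})
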