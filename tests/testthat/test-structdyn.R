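# A minimal protein+DNA system builder for geometry tests.
make_system <- function(xyz_list, resno, chain, element = "C",
                        resid = NULL) {
  n <- nrow(xyz_list[[1]])
  if (is.null(resid))
    resid <- ifelse(chain == "dna", "DG", "ALA")
  atoms <- data.frame(atom_id = seq_len(n),
                      element = rep_len(element, n),
                      resno = resno, resid = rep_len(resid, n))
  atoms$chain_class <- chain
  trajectory(atoms, xyz_list)
}

test_that("minimum residue-to-DNA distance matches brute force", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0))
  tr <- make_system(list(xyz), resno = c(1, 101, 102),
                    chain = c("protein", "dna", "dna"))
  expect_equal(min_residue_dna_distance(tr, 1), 4)
  # coincident atoms give 0
  xyz2 <- rbind(c(1, 1, 1), c(1, 1, 1))
  tr2 <- make_system(list(xyz2), resno = c(1, 101),
                     chain = c("protein", "dna"))
  expect_equal(min_residue_dna_distance(tr2, 1), 0)
  # 50-atom random frame vs O(n^2) oracle
  set.seed(13)
  xyz3 <- matrix(rnorm(150, sd = 4), ncol = 3)
  tr3 <- make_system(list(xyz3),
                     resno = c(rep(1:3, each = 10), rep(101:102, each = 10)),
                     chain = rep(c("protein", "dna"), c(30, 20)))
  for (res in 1:3)
    expect_equal(min_residue_dna_distance(tr3, res),
                 brute_min_dist(xyz3, which(tr3$atoms$resno == res), 31:50))
  expect_error(min_residue_dna_distance(tr3, 99), "no protein atoms")
})

test_that("time-averaged contacts are means of per-frame minima", {
  f1 <- rbind(c(0, 0, 0), c(4, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  tr <- make_system(list(f1, f2), resno = c(1, 101),
                    chain = c("protein", "dna"))
  cm <- time_averaged_contacts(tr, 1)
  expect_equal(cm$mean_min_dist, 5)
  # single frame equals the frame minimum
  expect_equal(time_averaged_contacts(tr, 1, frames = 1L)$mean_min_dist, 4)
  # frame-range restriction on 4 crafted frames
  fr <- lapply(c(2, 4, 8, 10), function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  tr4 <- make_system(fr, resno = c(1, 101), chain = c("protein", "dna"))
  expect_equal(time_averaged_contacts(tr4, 1)$mean_min_dist, 6)
  expect_equal(time_averaged_contacts(tr4, 1, frames = 3:4)$mean_min_dist, 9)
  expect_error(time_averaged_contacts(tr4, 1, frames = integer()), "empty")
  # concatenation: overall average is the length-weighted mean
  m12 <- time_averaged_contacts(tr4, 1, frames = 1:2)$mean_min_dist
  m34 <- time_averaged_contacts(tr4, 1, frames = 3:4)$mean_min_dist
  expect_equal(time_averaged_contacts(tr4, 1)$mean_min_dist,
               (2 * m12 + 2 * m34) / 4)
})

test_that("distances and SASA are rigid-motion invariant", {
  set.seed(19)
  xyz <- matrix(rnorm(60, sd = 3), ncol = 3)
  tr <- make_system(list(xyz), resno = c(rep(1:2, each = 8), rep(101, 4)),
                    chain = rep(c("protein", "dna"), c(16, 4)))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3)
  moved <- sweep(xyz %*% rot, 2, c(5, -3, 2), "+")
  tr_m <- make_system(list(moved), resno = tr$atoms$resno,
                      chain = tr$atoms$chain_class)
  expect_equal(min_residue_dna_distance(tr_m, 1),
               min_residue_dna_distance(tr, 1), tolerance = 1e-6)
  s0 <- sasa(tr); s1 <- sasa(tr_m)
  expect_equal(sum(s0), sum(s1), tolerance = 5e-3)
  s0f <- sasa(tr, n_points = 4000L); s1f <- sasa(tr_m, n_points = 4000L)
  expect_equal(as.numeric(s1f), as.numeric(s0f), tolerance = 5e-3)
})

test_that("hydrogen-bond occupancy counts frames meeting the criteria", {
  # donor-acceptor pair within 3.5 A in 30 of 120 frames
  dists <- c(rep(3.0, 30), rep(6.0, 90))
  frames <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  tr <- make_system(frames, resno = c(1, 101), chain = c("protein", "dna"),
                    element = c("N", "O"))
  expect_equal(suppressWarnings(hbond_occupancy(tr, 1, 2)), 0.25)
  # boundary: exactly at the threshold counts (closed interval)
  at <- make_system(list(rbind(c(0, 0, 0), c(3.5, 0, 0))),
                    resno = c(1, 101), chain = c("protein", "dna"))
  expect_equal(suppressWarnings(hbond_occupancy(at, 1, 2)), 1)
  # never within distance
  far <- make_system(list(rbind(c(0, 0, 0), c(9, 0, 0))),
                     resno = c(1, 101), chain = c("protein", "dna"))
  expect_equal(suppressWarnings(hbond_occupancy(far, 1, 2)), 0)
  # angle criterion with explicit hydrogen: linear D-H...A passes,
  # bent arrangement fails
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))     # D, H, A
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.2, 0))
  atoms3 <- data.frame(atom_id = 1:3, element = c("N", "H", "O"),
                       resno = c(1, 1, 101),
                       resid = c("ALA", "ALA", "DG"))
  tr_lin <- trajectory(atoms3, list(lin))
  tr_bent <- trajectory(atoms3, list(bent))
  expect_equal(hbond_occupancy(tr_lin, 1, 3, hydrogens = 2), 1)
  expect_equal(hbond_occupancy(tr_bent, 1, 3, hydrogens = 2), 0)
  # monotone in the distance threshold
  mid <- make_system(lapply(c(2, 3, 4, 5), function(d)
    rbind(c(0, 0, 0), c(d, 0, 0))), resno = c(1, 101),
    chain = c("protein", "dna"))
  occ <- vapply(c(2.5, 3.5, 4.5, 5.5), function(dmax)
    suppressWarnings(hbond_occupancy(mid, 1, 2,
                                     criteria = hbond_criteria(dmax))), 0)
  expect_true(all(diff(occ) >= 0))
})

test_that("Shrake-Rupley SASA matches analytic and refined references", {
  lone <- make_system(list(matrix(c(0, 0, 0), 1)), resno = 1,
                      chain = "protein")
  expect_equal(sasa(lone)[["1"]], 4 * pi * 3.1^2, tolerance = 0.01)
  # fully enclosed atom has ~zero SASA
  shell_pts <- satselseq:::sphere_points(60) * 2.0
  caged <- rbind(c(0, 0, 0), shell_pts)
  trc <- make_system(list(caged), resno = c(1, rep(2, 60)),
                     chain = "protein")
  expect_lt(sasa(trc)[["1"]], 1e-6)
  # two overlapping spheres: less than 2x one sphere; quadrature refinement
  two <- make_system(list(rbind(c(0, 0, 0), c(2, 0, 0))), resno = c(1, 2),
                     chain = "protein")
  s960 <- sum(sasa(two, n_points = 960L))
  expect_lt(s960, 2 * 4 * pi * 3.1^2)
  s10k <- sum(sasa(two, n_points = 10000L))
  expect_equal(s960, s10k, tolerance = 0.02)
  expect_error(sasa(make_system(list(matrix(0, 1, 3)), 1, "protein",
                                element = "XX")), "XX")
})

test_that("burial fractions compare trajectory SASA to a reference state", {
  lone <- make_system(list(matrix(c(0, 0, 0), 1)), resno = 1,
                      chain = "protein")
  iso <- unname(sasa(lone))
  expect_equal(fraction_buried(lone, 1, reference = iso), 0)
  shell_pts <- satselseq:::sphere_points(60) * 2.0
  caged <- make_system(list(rbind(c(0, 0, 0), shell_pts)),
                       resno = c(1, rep(2, 60)), chain = "protein")
  expect_equal(fraction_buried(caged, 1, reference = iso), 1,
               tolerance = 1e-6)
  # default reference comes from the residue-type table
  expect_error(fraction_buried(lone, 1, reference_table = c(GLY = 104)),
               "missing from reference")
  expect_lt(fraction_buried(lone, 1), 1)
})

test_that("multi-model PDB files round-trip as trajectories", {
  tt <- toy_trajectory(seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tt, pdb)
  back <- read_trajectory_pdb(pdb)
  expect_length(back$frames, 10L)
  expect_identical(nrow(back$atoms), 15L)
  expect_identical(back$atoms$chain_class, tt$atoms$chain_class)
  expect_equal(back$frames[[7]], tt$frames[[7]], tolerance = 1e-3,
               ignore_attr = TRUE)
  # analyses agree across the round trip (coordinates quantized to 1e-3)
  expect_equal(time_averaged_contacts(back, 113:115)$mean_min_dist,
               time_averaged_contacts(tt, 113:115)$mean_min_dist,
               tolerance = 1e-3)
})
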