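test_that("the ligand internal-energy term is the shifted, weighted linear form", {
  p <- scoring_params()
  expect_identical(ligand_energy_term(473.58, p), 0)
  expect_equal(ligand_energy_term(573.58, p), 10.0)
  expect_equal(ligand_energy_term(1000, scoring_params(w = 0)), 0)
  expect_error(ligand_energy_term(Inf, p), class = "rls_data_error")
  expect_error(ligand_energy_term(NA_real_, p), class = "rls_data_error")
  expect_error(scoring_params(w = -1), class = "rls_usage_error")
})

test_that("a constant-probability stub gives the exact negative contact sum", {
  # two beads + two LIPO points, all within range: 4 contacts
  beads <- rbind("P" = c(0, 0, 0), "C4'" = c(1.5, 0, 0))
  res <- toy_cg_residue(beads, normal = c(0, 0, 1))
  pts <- structure(list(rligscore:::pharm_point("LIPO", c(3, 1, 0)),
                        rligscore:::pharm_point("LIPO", c(3, -1, 0))),
                   class = "pharm_set")
  m05 <- stub_model(0.5)
  sc <- suppressWarnings(score_pose(res, pts, m05))
  expect_equal(sc$n_contacts, 4)
  expect_identical(sc$E_rna_ligand, -2.0)
  expect_identical(sc$E_total, sc$E_rna_ligand + sc$E_ligand)
  # with p == 1 the score is exactly minus the modelled contact count
  m1 <- stub_model(1)
  sc1 <- suppressWarnings(score_pose(res, pts, m1))
  expect_identical(sc1$E_rna_ligand, -4)
  # adding one more in-range point strictly decreases the total
  pts3 <- structure(c(unclass(pts), list(rligscore:::pharm_point("LIPO", c(4, 0, 0)))),
                    class = "pharm_set")
  sc3 <- suppressWarnings(score_pose(res, pts3, m1))
  expect_lt(sc3$E_total, sc1$E_total)
  # ligand term feeds E_total per the two-term decomposition
  scE <- suppressWarnings(score_pose(res, pts, m05, E_GAFF = 573.58))
  expect_equal(scE$E_ligand, 10.0)
  expect_identical(scE$E_total, scE$E_rna_ligand + scE$E_ligand)
  # out-of-range ligand with w irrelevant: empty sum
  far <- toy_pharm_point("LIPO", c(100, 0, 0))
  sc0 <- suppressWarnings(score_pose(res, far, m05, E_GAFF = 473.58))
  expect_identical(sc0$E_total, 0)
  expect_equal(sc0$n_contacts, 0)
})

test_that("contacts in unmodelled groups are skipped and counted, not penalised", {
  cd <- make_contact_dataset(100, groups = "G:N9:HDON", seed = 51)
  model <- suppressWarnings(rlsf_train(cd, "knn", grid = list(list(k = 5)), seed = 1))
  beads <- rbind("P" = c(0, 0, 0), "C4'" = c(1.5, 0, 0))
  res <- toy_cg_residue(beads, normal = c(0, 0, 1))
  pts <- toy_pharm_point("LIPO", c(3, 0, 0))   # G:P:LIPO, G:C4':LIPO unmodelled
  sc <- suppressWarnings(score_pose(res, pts, model))
  expect_equal(sc$n_contacts, 0)
  expect_equal(sc$n_skipped, 2)
  expect_identical(sc$E_rna_ligand, 0)
})

test_that("pose-set scoring ranks ascending with stable ties and is deterministic", {
  fx <- make_pose_set(c(0.5, 5, 0.5, 7), seed = 8)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$rna, tmp)
  rna <- read_rna_pdb(tmp)
  df <- score_poses(rna, fx$poses, stub_model(1))
  expect_identical(df$rank, seq_len(4L))
  expect_true(all(diff(df$E_total) >= 0))
  # duplicated pose scores identically (bitwise)
  dup <- score_poses(rna, fx$poses[c(1, 1)], stub_model(1))
  expect_identical(dup$E_total[1], dup$E_total[2])
  expect_identical(dup$pose_id[dup$rank == 1], 1L)  # tie -> earlier pose first
  # CSV writer emits the ranked schema
  csv <- withr::local_tempfile(fileext = ".csv")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(fx$poses, sdf)
  out <- score_pose_file(tmp, sdf, stub_model(1), out_csv = csv)
  got <- read.csv(csv)
  expect_identical(names(got),
                   c("complex_id", "pose_id", "E_total", "E_rna_ligand",
                     "E_ligand", "n_contacts", "n_skipped", "rank"))
  expect_equal(got$E_total, got$E_rna_ligand + got$E_ligand)
})

test_that("scores are invariant under a rigid motion of the whole complex", {
  fx <- make_pose_set(c(0.4, 5.5), seed = 13)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$rna, tmp)
  rna <- read_rna_pdb(tmp)
  model <- stub_model(0.5)
  base_scores <- score_poses(rna, fx$poses, model)
  R <- rligscore:::rotation_matrix(c(1, 1, -2), 49)
  tr <- c(-3, 5, 2)
  rna2 <- rna
  rna2$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(rna$atoms[, c("x", "y", "z")]) %*% t(R), 2, -tr)
  poses2 <- lapply(fx$poses, function(m)
    rligscore:::ligand_set_coords(m, sweep(rligscore:::ligand_coords(m) %*% t(R), 2, -tr)))
  moved <- score_poses(rna2, poses2, model)
  expect_equal(moved$E_total, base_scores$E_total, tolerance = 1e-6)
  expect_identical(moved$rank, base_scores$rank)
})

test_that("greedy pose clustering matches the full-matrix oracle", {
  # ten poses planted in three spatial groups
  offsets <- c(0, 0.3, 0.6, 0.9, 8, 8.3, 8.6, 16, 16.3, 16.6)
  base <- ligand_template("chain_amine")
  poses <- lapply(offsets, function(o) translate_ligand(base, c(o, 0, 0)))
  set.seed(17)
  scores <- rnorm(10)
  got <- cluster_poses(poses, scores, rmsd_threshold = 2)
  # brute-force greedy oracle over the full RMSD matrix
  D <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) D[i, j] <- abs(offsets[i] - offsets[j])
  cl <- rep(NA_integer_, 10); k <- 0L
  while (anyNA(cl)) {
    un <- which(is.na(cl)); seed <- un[which.min(scores[un])]
    k <- k + 1L; cl[seed] <- k
    cl[un[D[seed, un] <= 2]] <- k
  }
  expect_identical(got$cluster, cl)
  expect_length(got$seeds, 3)
  # threshold behaviour on two poses
  two_near <- list(base, translate_ligand(base, c(0.5, 0, 0)))
  expect_equal(max(cluster_poses(two_near, c(1, 2))$cluster), 1)
  two_far <- list(base, translate_ligand(base, c(3.5, 0, 0)))
  expect_equal(max(cluster_poses(two_far, c(1, 2))$cluster), 2)
  expect_equal(max(cluster_poses(list(base), 1)$cluster), 1)
})

test_that("centroid poses average member coordinates through the symmetry mapping", {
  base <- ligand_template("chain_amine")
  shifted <- translate_ligand(base, c(1, 0, 0))
  cent <- centroid_pose(list(base, shifted))
  expect_equal(rligscore:::ligand_coords(cent),
               rligscore:::ligand_coords(translate_ligand(base, c(0.5, 0, 0))),
               tolerance = 1e-9)
  expect_identical(centroid_pose(list(base)), base)
  # symmetric ring: centroid independent of member atom labelling
  ring <- make_c6_ring()
  rot <- rotate_ligand(ring, c(0, 0, 1), 60)   # same geometry, relabelled
  cent2 <- centroid_pose(list(ring, rot))
  # oracle: under the optimal automorphism the two members coincide, so the
  # centroid must equal the ring itself (atomwise, up to 1e-9)
  expect_equal(symmetry_rmsd(ring, cent2), 0, tolerance = 1e-9)
  expect_error(centroid_pose(list()), class = "rls_data_error")
})

test_that("local optimisation descends a planted quadratic score field and respects fixed points", {
  base <- ligand_template("charged_acid")
  target <- colMeans(rligscore:::ligand_coords(base))
  bowl <- function(mol) sum((colMeans(rligscore:::ligand_coords(mol)) - target)^2)
  # start at the optimum: stays near it, score not worsened
  r0 <- local_optimize(base, bowl)
  expect_lte(r0$score, bowl(base))
  expect_lt(sqrt(sum((colMeans(rligscore:::ligand_coords(r0$pose)) - target)^2)), 0.6)
  # start 1 A off the optimum: strictly improves
  off <- translate_ligand(base, c(1, 0, 0))
  r1 <- local_optimize(off, bowl)
  expect_lt(r1$score, bowl(off))
  expect_lte(r1$n_eval, 200)
  # flat landscape: pose unchanged
  flat <- function(mol) 0
  r2 <- local_optimize(base, flat)
  expect_identical(rligscore:::ligand_coords(r2$pose),
                   rligscore:::ligand_coords(base))
  # rigidity: interatomic distances preserved
  d0 <- dist(rligscore:::ligand_coords(off))
  d1 <- dist(rligscore:::ligand_coords(r1$pose))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})
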