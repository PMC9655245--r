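crit_b <- interaction_criteria("bace1")
crit_a <- interaction_criteria("ache")

test_that("hydrogen-bond counting applies distance and element rules", {
  rec <- manual_receptor()
  res <- data.frame(resid = c("ASP", "GLY"), resno = c(32L, 34L),
                    chain = "A", role = c("catalytic", "hbond"))
  # ligand N at 3.0 A from the ASP carboxylate O (OD1 at (0.5, -1.4, 0))
  pose <- manual_pose("N", c(0.5, -4.4, 0))
  hb <- count_hbonds(pose, rec, res, crit_b)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$resno, 32)
  expect_equal(hb$distance, 3.0, tolerance = 1e-9)
  # same geometry at 3.6 A: just outside the cutoff
  hb2 <- count_hbonds(manual_pose("N", c(0.5, -5.0, 0)), rec, res, crit_b)
  expect_equal(nrow(hb2), 0)
  # carbon at 3.0 A is not a donor/acceptor element
  hb3 <- count_hbonds(manual_pose("C", c(0.5, -4.4, 0)), rec, res, crit_b)
  expect_equal(nrow(hb3), 0)
  # sulfur ligand atom can accept from receptor N/O
  hb4 <- count_hbonds(manual_pose("S", c(0.5, -4.4, 0)), rec, res, crit_b)
  expect_equal(nrow(hb4), 1)
  # multiple pairs to one residue count separately
  pose5 <- manual_pose(c("N", "O"), c(0.5, -4.4, 0, 0.5, 1.6, 0))
  hb5 <- count_hbonds(pose5, rec, res, crit_b)
  expect_gte(nrow(hb5), 2)
  # listed residue absent from the structure
  res_bad <- rbind(res, data.frame(resid = "THR", resno = 232L, chain = "A",
                                   role = "hbond"))
  expect_error(count_hbonds(pose, rec, res_bad, crit_b), "THR232")
})

test_that("contact detection respects the 5 A boundary", {
  rec <- manual_receptor()
  res <- data.frame(resid = c("ASP", "GLY"), resno = c(32L, 34L),
                    chain = "A", role = "vdw")
  # nearest GLY atom is O at (21.8, 1.9, 0): place ligand C at 4.9 then 5.1
  ct <- count_vdw_contacts(manual_pose("C", c(21.8, 1.9, 4.9)), rec, res,
                           crit_b)
  expect_true(34 %in% ct$resno)
  ct2 <- count_vdw_contacts(manual_pose("C", c(21.8, 1.9, 5.1)), rec, res,
                            crit_b)
  expect_false(34 %in% ct2$resno)
  # restricted scan equals the any-residue scan filtered to the list
  pose <- manual_pose(c("C", "N"), c(2, 0, 3, 20, 0, 2))
  ct_l <- count_vdw_contacts(pose, rec, res, crit_b)
  crit_any <- interaction_criteria("bace1", any_residue = TRUE)
  ct_a <- count_vdw_contacts(pose, rec, res, crit_any)
  keep <- paste(ct_a$resid, ct_a$resno) %in% paste(res$resid, res$resno)
  expect_setequal(paste(ct_l$resid, ct_l$resno),
                  paste(ct_a$resid, ct_a$resno)[keep])
})

test_that("pose classification reproduces the target rule boundaries", {
  bres <- bace1_residues()
  # minimum passing profile: 4 H-bonds (2 catalytic), 8 contacts
  hb <- rep(0L, nrow(bres))
  hb[bres$role == "catalytic"] <- 1L
  hb[match(c("GLY", "THR"), bres$resid)] <- 1L
  ct <- rep(FALSE, nrow(bres)); ct[bres$role == "vdw"][1:4] <- TRUE
  fx <- make_pose_fixture(bres, hb, ct, seed = 2)
  pr <- profile_pose(fx$pose, fx$receptor, bres, crit_b)
  expect_equal(pr$n_hbonds, 4)
  expect_equal(pr$n_catalytic_hbonds, 2)
  expect_equal(pr$n_contacts, 8)
  expect_true(classify_pose(pr, crit_b, bres))
  # catalytic clause: 4 H-bonds but only 1 catalytic fails despite contacts
  hb1 <- rep(0L, nrow(bres))
  hb1[which(bres$role == "catalytic")[1]] <- 1L
  hb1[match(c("GLY", "THR", "GLN"), bres$resid)] <- 1L
  ct1 <- rep(FALSE, nrow(bres)); ct1[bres$role == "vdw"] <- TRUE
  fx1 <- make_pose_fixture(bres, hb1, ct1, seed = 3)
  pr1 <- profile_pose(fx1$pose, fx1$receptor, bres, crit_b)
  expect_equal(pr1$n_hbonds, 4)
  expect_equal(pr1$n_catalytic_hbonds, 1)
  expect_gte(pr1$n_contacts, 8)
  expect_false(classify_pose(pr1, crit_b, bres))
  # contacts clause: plenty of H-bonds, too few contacts
  hb2 <- rep(0L, nrow(bres)); hb2[bres$role %in% c("catalytic", "hbond")][1:5] <- 1L
  fx2 <- make_pose_fixture(bres, hb2, rep(FALSE, nrow(bres)), seed = 4)
  pr2 <- profile_pose(fx2$pose, fx2$receptor, bres, crit_b)
  expect_lt(pr2$n_contacts, 8)
  expect_false(classify_pose(pr2, crit_b, bres))

  ares <- ache_residues()
  fx_all <- make_pose_fixture(ares, contacts = rep(TRUE, 9), seed = 5)
  pr_all <- profile_pose(fx_all$pose, fx_all$receptor, ares, crit_a)
  expect_true(classify_pose(pr_all, crit_a, ares))
  # eight of nine residues is not positively docked
  fx8 <- make_pose_fixture(ares, contacts = c(rep(TRUE, 8), FALSE), seed = 6)
  pr8 <- profile_pose(fx8$pose, fx8$receptor, ares, crit_a)
  expect_equal(pr8$n_contacts, 8)
  expect_false(classify_pose(pr8, crit_a, ares))
})

test_that("classification is monotone in interactions", {
  bres <- bace1_residues()
  base_hb <- rep(0L, nrow(bres)); base_hb[bres$role == "catalytic"] <- 1L
  base_hb[match(c("GLY", "THR"), bres$resid)] <- 1L
  base_ct <- rep(FALSE, nrow(bres)); base_ct[bres$role == "vdw"][1:4] <- TRUE
  fx <- make_pose_fixture(bres, base_hb, base_ct, seed = 12)
  base <- classify_pose(profile_pose(fx$pose, fx$receptor, bres, crit_b),
                        crit_b, bres)
  expect_true(base)
  # adding an H-bond or a contact never flips docked -> not docked
  more_hb <- base_hb; more_hb[match("GLN", bres$resid)] <- 1L
  fx2 <- make_pose_fixture(bres, more_hb, base_ct, seed = 12)
  expect_true(classify_pose(profile_pose(fx2$pose, fx2$receptor, bres,
                                         crit_b), crit_b, bres))
  more_ct <- base_ct; more_ct[bres$role == "vdw"] <- TRUE
  fx3 <- make_pose_fixture(bres, base_hb, more_ct, seed = 12)
  expect_true(classify_pose(profile_pose(fx3$pose, fx3$receptor, bres,
                                         crit_b), crit_b, bres))
})

test_that("counts are invariant under rigid rotation and translation", {
  bres <- bace1_residues()
  hb <- rep(0L, nrow(bres)); hb[bres$role %in% c("catalytic", "hbond")][1:4] <- 1L
  ct <- rep(FALSE, nrow(bres)); ct[bres$role == "vdw"][1:5] <- TRUE
  fx <- make_pose_fixture(bres, hb, ct, seed = 31)
  p0 <- profile_pose(fx$pose, fx$receptor, bres, crit_b)
  for (s in 1:3) {
    R <- random_rotation(s)
    t_vec <- c(5.5, -3.1, 12) * s
    rec <- fx$receptor
    xyz <- as.matrix(rec[, c("x", "y", "z")]) %*% t(R)
    rec$x <- xyz[, 1] + t_vec[1]; rec$y <- xyz[, 2] + t_vec[2]
    rec$z <- xyz[, 3] + t_vec[3]
    pose <- fx$pose
    pc <- pose$coords %*% t(R)
    pose$coords <- sweep(pc, 2, t_vec, `+`)
    p1 <- profile_pose(pose, rec, bres, crit_b)
    expect_equal(p1$n_hbonds, p0$n_hbonds)
    expect_equal(p1$n_catalytic_hbonds, p0$n_catalytic_hbonds)
    expect_equal(sort(paste(p1$contacts$resid, p1$contacts$resno)),
                 sort(paste(p0$contacts$resid, p0$contacts$resno)))
  }
})

test_that("numbering maps translate canonical residue numbers", {
  bres <- bace1_residues()
  hb <- rep(0L, nrow(bres)); hb[bres$role == "catalytic"] <- 1L
  hb[match(c("GLY", "THR"), bres$resid)] <- 1L
  ct <- rep(FALSE, nrow(bres)); ct[bres$role == "vdw"] <- TRUE
  # structure written in the +61 numbering (Asp93 / Asp289 convention)
  fx <- make_pose_fixture(bres, hb, ct, seed = 9, resno_offset = 61L)
  m_off <- numbering_map(offset = 61L)
  pr <- profile_pose(fx$pose, fx$receptor, bres, crit_b, map = m_off)
  expect_equal(pr$n_hbonds, 4)
  expect_equal(pr$n_catalytic_hbonds, 2)
  # reported numbering stays canonical
  expect_true(all(pr$hbonds$resno %in% bres$resno))
  # explicit pair map behaves identically
  m_pairs <- numbering_map(bres$resno, bres$resno + 61L)
  pr2 <- profile_pose(fx$pose, fx$receptor, bres, crit_b, map = m_pairs)
  expect_equal(pr2$n_hbonds, pr$n_hbonds)
  # without the map the listed residues are missing
  expect_error(profile_pose(fx$pose, fx$receptor, bres, crit_b), "absent")
  # non-bijective map rejected
  expect_error(numbering_map(c(1, 2), c(5, 5)), "bijective")
})

test_that("per-molecule outcomes aggregate across structures", {
  bres <- bace1_residues()
  good_hb <- rep(0L, nrow(bres)); good_hb[bres$role == "catalytic"] <- 1L
  good_hb[match(c("GLY", "THR"), bres$resid)] <- 1L
  good_ct <- rep(FALSE, nrow(bres)); good_ct[bres$role == "vdw"] <- TRUE
  make_pose_n <- function(ok, seed) {
    if (ok) make_pose_fixture(bres, good_hb, good_ct, seed = seed, dir = NULL)
    else make_pose_fixture(bres, n_decoy = 4, seed = seed, dir = NULL)
  }
  # planted per-structure pass counts (2, 0, 3)
  s1 <- lapply(1:2, function(i) make_pose_n(TRUE, 40 + i))
  s2 <- lapply(1:2, function(i) make_pose_n(FALSE, 50 + i))
  s3 <- lapply(1:3, function(i) make_pose_n(TRUE, 60 + i))
  rec <- s1[[1]]$receptor  # identical deterministic receptor geometry
  out <- profile_molecule(
    list(a = lapply(s1, `[[`, "pose"), b = lapply(s2, `[[`, "pose"),
         c = lapply(s3, `[[`, "pose")),
    list(a = rec, b = rec, c = rec), bres, crit_b)
  expect_equal(unname(out$poses_by_structure), c(2L, 0L, 3L))
  expect_equal(unname(out$docked_by_structure), c(TRUE, FALSE, TRUE))
  expect_true(out$docked)
  expect_equal(out$total_poses, 5L)
  # no passing pose anywhere
  none <- profile_molecule(list(a = lapply(s2, `[[`, "pose")), list(a = rec),
                           bres, crit_b)
  expect_false(none$docked)
  expect_equal(none$total_poses, 0L)
  # one passing pose in one of three structures
  one <- profile_molecule(
    list(a = list(s1[[1]]$pose), b = list(s2[[1]]$pose),
         c = list(s2[[2]]$pose)),
    list(a = rec, b = rec, c = rec), bres, crit_b)
  expect_true(one$docked)
  expect_equal(one$total_poses, 1L)
  # more than 10 poses per structure are truncated with a warning
  many <- c(lapply(s1, `[[`, "pose"), lapply(s3, `[[`, "pose"))
  many <- rep(many, 3)[1:11]
  expect_warning(profile_molecule(list(a = many), list(a = rec), bres,
                                  crit_b), "10")
})

test_that("receptor and pose files round-trip through standard readers", {
  bres <- bace1_residues()
  hb <- rep(0L, nrow(bres)); hb[1] <- 2L
  fx <- make_pose_fixture(bres, hb, seed = 77)
  rec <- read_receptor(fx$receptor_file)
  expect_s3_class(rec, "receptor")
  # coordinates identical to 1e-3 A after the PDB round trip
  expect_equal(rec$x, fx$receptor$x, tolerance = 1e-3)
  expect_equal(rec$resno, fx$receptor$resno)
  poses <- read_poses(fx$pose_file)
  expect_length(poses, 1)
  expect_equal(poses[[1]]$coords, fx$pose$coords, tolerance = 1e-3)
  expect_equal(poses[[1]]$element, fx$pose$element)
  expect_equal(poses[[1]]$mol_id, "synthmol")
  # profile computed from files matches the in-memory profile
  pr_mem <- profile_pose(fx$pose, fx$receptor, bres, crit_b)
  pr_file <- profile_pose(poses[[1]], rec, bres, crit_b)
  expect_equal(pr_file$n_hbonds, pr_mem$n_hbonds)
  expect_equal(pr_file$n_contacts, pr_mem$n_contacts)
  # waters and hetero records are stripped on load
  tf <- tempfile(fileext = ".pdb")
  lines <- readLines(fx$receptor_file)
  water <- "HETATM 9999  O   HOH A 900      99.000  99.000  99.000  1.00  0.00           O"
  writeLines(append(lines, water, after = length(lines) - 1), tf)
  rec2 <- read_receptor(tf)
  expect_false(any(rec2$resid == "HOH"))
})
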