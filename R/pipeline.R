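#' End-to-end synthetic screening dry run
#'
#' Exercises the whole pipeline on synthetic data with known ground truth:
#' generate a screening library from the fragment grammar; compute the 2D
#' descriptor table; simulate a potency assay in which true potency is
#' driven by a few descriptors (plus log-normal noise); curate and label the
#' assayed subset (high-vs-low scheme, plus an actives-vs-decoys scheme with
#' property-matched decoys); train one gate model and two further
#' filter-ensemble models; screen the unassayed library through the cascade;
#' build synthetic docking fixtures for the top survivors and profile them
#' against the two target rules; and finally combine indexes and docking
#' outcomes into weighted scores and select candidates (score > threshold in
#' every sub-score, logP below the cap).
#'
#' Everything downstream of the seed is deterministic. The default problem
#' size (1000-molecule library, 400-molecule assay subset, 24 docked
#' survivors) keeps the full run in the minutes range on one core.
#'
#' @param n_library library size.
#' @param seed integer master seed.
#' @param top_n how many cascade survivors are carried into docking.
#' @param n_assay how many library members receive simulated potencies.
#' @return list with elements `library`, `descriptors`, `models`, `cv`,
#'   `screened` (cascade table), `outcomes` (docking outcomes per survivor
#'   and target), `components`, `weights`, `candidates` (scored and
#'   selected) and `seed`.
#' @export
dry_run_pipeline <- function(n_library = 1000, seed = 1, top_n = 24,
                             n_assay = 400) {
  stopifnot(n_assay < n_library, top_n >= 1)
  lib <- make_screening_library(n_library, seed = seed)
  desc <- descriptor_table(lib$smiles, lib$mol_id)

  # simulated potency: a latent score over three real descriptors
  set.seed(seed + 1)
  z <- scale(desc[, c("logP", "a_nN", "TPSA")])
  latent <- as.numeric(z %*% c(0.8, 0.9, 0.6)) / sqrt(3)
  ic50 <- 10^(2.6 - 1.6 * latent + rnorm(n_library, sd = 0.35))
  assay_idx <- sort(sample(n_library, n_assay))
  assayed <- lib[assay_idx, ]
  assayed$activity_nM <- ic50[assay_idx]
  assayed$target <- "synthetic"
  pool <- lib[-assay_idx, ]
  pool$activity_nM <- NA_real_
  pool$target <- NA_character_

  assayed <- deduplicate(assayed)
  hvl <- assign_classes(assayed, activity_scheme("HvL"))
  avi_scheme <- activity_scheme("AvI")
  avi_actives <- assayed[assayed$activity_nM < avi_scheme$active_cutoff_nM, ]
  avi_actives$class_label <- 1L

  ratio <- max(1, floor(nrow(pool) / (2 * nrow(avi_actives))))
  decoys <- sample_decoys(avi_actives, pool, ratio = ratio, tolerance = 2.5,
                          seed = seed + 2,
                          props_actives = desc[avi_actives$mol_id, ],
                          props_pool = desc[pool$mol_id, ])
  avi <- rbind(avi_actives, decoys)

  train_desc <- reject_descriptors(desc, var_threshold = 1e-8,
                                   corr_threshold = 0.98)
  fit <- function(ids, labels, s) {
    ise(train_desc[ids, , drop = FALSE], labels, n_filters = 8,
        mcc_min = 0.15, n_iterations = 8, gen_size = 120, seed = s)
  }
  models <- list(
    ache_m1  = fit(avi$mol_id, avi$class_label, seed + 3),
    ache_hvl = fit(hvl$mol_id, hvl$class_label, seed + 4),
    bace1_hvl = fit(hvl$mol_id, hvl$class_label, seed + 5))

  screen_ids <- pool$mol_id
  screened <- screen_cascade(models, train_desc[screen_ids, , drop = FALSE])
  screened <- cbind(mol_id = screen_ids, screened)

  surv <- screened[screened$pass, ]
  if (nrow(surv) == 0) stop("no cascade survivors in dry run")
  mean_idx <- rowMeans(surv[, names(models)])
  surv <- surv[order(-mean_idx), ]
  surv <- head(surv, top_n)

  # synthetic docking: truth drawn per survivor and target
  bres <- bace1_residues(); ares <- ache_residues()
  bcrit <- interaction_criteria("bace1")
  acrit <- interaction_criteria("ache")
  set.seed(seed + 6)
  outcomes <- lapply(seq_len(nrow(surv)), function(i) {
    id <- surv$mol_id[i]
    b_dock <- runif(1) < 0.6
    hb <- rep(0L, nrow(bres))
    ct <- rep(FALSE, nrow(bres))
    if (b_dock) {
      hb[bres$role == "catalytic"] <- 1L          # 2 catalytic H-bonds
      hb[match(c("GLY", "THR"), bres$resid)] <- 1L # +2 more
      ct[bres$role == "vdw"] <- TRUE               # 6 vdw + 4 hbond residues
    } else {
      hb[which(bres$role == "catalytic")[1]] <- 1L
      ct[which(bres$role == "vdw")[1:3]] <- TRUE
    }
    bfix <- make_pose_fixture(bres, hb, ct, seed = seed + 100 + i,
                              mol_id = id, dir = NULL)
    a_dock <- runif(1) < 0.6
    act <- rep(a_dock, nrow(ares))
    if (!a_dock) act[1:4] <- TRUE                 # partial contact pattern
    afix <- make_pose_fixture(ares, contacts = act,
                              seed = seed + 200 + i, mol_id = id, dir = NULL)
    list(
      mol_id = id,
      bace1 = profile_molecule(list(s1 = list(bfix$pose)),
                               list(s1 = bfix$receptor), bres, bcrit),
      ache = profile_molecule(list(s1 = list(afix$pose)),
                              list(s1 = afix$receptor), ares, acrit))
  })

  comp <- data.frame(
    mol_id = surv$mol_id,
    ache_m1 = surv$ache_m1, ache_hvl = surv$ache_hvl,
    bace1_hvl = surv$bace1_hvl,
    ache_docked = vapply(outcomes, function(o) as.numeric(o$ache$docked),
                         numeric(1)),
    ache_poses = vapply(outcomes, function(o) o$ache$total_poses, integer(1)),
    bace1_docked = vapply(outcomes, function(o) as.numeric(o$bace1$docked),
                          numeric(1)),
    bace1_poses = vapply(outcomes, function(o) o$bace1$total_poses,
                         integer(1)))
  norm <- normalize_components(
    comp, index_cols = c("ache_m1", "ache_hvl", "bace1_hvl"),
    pose_cols = c(ache_poses = 10L, bace1_poses = 10L),
    flag_cols = c("ache_docked", "bace1_docked"))

  # calibration references: idealized known duals vs. random molecules
  set.seed(seed + 7)
  knowns <- matrix(runif(46 * ncol(norm), 0.6, 1), 46,
                   dimnames = list(NULL, colnames(norm)))
  randoms <- matrix(runif(150 * ncol(norm), 0, 0.5), 150,
                    dimnames = list(NULL, colnames(norm)))
  wv <- calibrate_weights(knowns, randoms, threshold = 0.5,
                          n_draws = 500, seed = seed + 8)

  sub_score <- function(cols) {
    w <- wv$weights[cols]
    weighted_score(norm[, cols, drop = FALSE], w / sum(w))
  }
  ache_cols <- c("ache_m1", "ache_hvl", "ache_docked", "ache_poses")
  bace_cols <- c("bace1_hvl", "bace1_docked", "bace1_poses")
  scored <- data.frame(
    mol_id = comp$mol_id,
    score = weighted_score(norm, wv$weights),
    score_ache = sub_score(ache_cols),
    score_bace1 = sub_score(bace_cols),
    logP = desc[comp$mol_id, "logP"])
  candidates <- select_candidates(scored,
                                  score_cols = c("score", "score_ache",
                                                 "score_bace1"))

  list(library = lib, descriptors = desc, models = models,
       screened = screened, outcomes = outcomes, components = comp,
       weights = wv, candidates = candidates, seed = seed)
}
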