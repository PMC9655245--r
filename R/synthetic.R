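#' Synthetic two-class descriptor dataset
#'
#' Class-conditional Gaussian descriptor table with a known informative
#' subset: informative descriptors are separated between classes by
#' `effect` standard deviations, noise descriptors share one distribution.
#' Used to test model training against generator ground truth.
#'
#' @param n_active,n_inactive class sizes.
#' @param n_descriptors total number of descriptors.
#' @param n_informative how many are informative.
#' @param effect class-mean separation of informative descriptors, in sd
#'   units.
#' @param seed integer seed (the table is deterministic under it).
#' @return list with `x` (data.frame, rows syn0001...), `y` (0/1 labels) and
#'   `informative` (descriptor names carrying signal).
#' @export
make_classification_dataset <- function(n_active = 200, n_inactive = 200,
                                        n_descriptors = 20,
                                        n_informative = 3, effect = 3,
                                        seed = 1) {
  stopifnot(n_informative <= n_descriptors, effect >= 0,
            n_active >= 1, n_inactive >= 1)
  set.seed(seed)
  n <- n_active + n_inactive
  y <- c(rep(1L, n_active), rep(0L, n_inactive))
  cn <- sprintf("D%02d", seq_len(n_descriptors))
  inf <- sort(sample(cn, n_informative))
  x <- matrix(rnorm(n * n_descriptors), n, n_descriptors,
              dimnames = list(sprintf("syn%04d", seq_len(n)), cn))
  x[y == 1, inf] <- x[y == 1, inf] + effect
  list(x = as.data.frame(x), y = y, informative = inf)
}

# one synthetic residue: backbone N, CA, C, O around a centre
.synth_residue <- function(resid, resno, centre) {
  off <- rbind(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0),
               C = c(1.2, 0.8, 0), O = c(1.8, 1.9, 0))
  data.frame(resid = resid, resno = resno, chain = "A",
             elety = rownames(off),
             elesy = c("N", "C", "C", "O"),
             x = centre[1] + off[, 1], y = centre[2] + off[, 2],
             z = centre[3] + off[, 3], stringsAsFactors = FALSE)
}

# rejection-sample a point at distance in [dmin, dmax] from `target` subject
# to exclusion constraints; each row of `avoid` is (x, y, z, min_dist)
.place_atom <- function(target, dmin, dmax, avoid, max_try = 500) {
  for (i in seq_len(max_try)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- target + u * runif(1, dmin, dmax)
    if (nrow(avoid) == 0) return(p)
    d <- sqrt(rowSums((avoid[, 1:3, drop = FALSE] -
                         matrix(p, nrow(avoid), 3, byrow = TRUE))^2))
    if (all(d > avoid[, 4])) return(p)
  }
  stop("infeasible packing: could not place a ligand atom")
}

#' Synthetic receptor / pose fixture with exact ground truth
#'
#' Builds a toy receptor (one four-atom residue per entry of `residues`,
#' centres 14 Angstrom apart) and a ligand pose whose interactions are known
#' exactly: `hbonds[i]` ligand polar atoms are placed 2.8-3.4 Angstrom from
#' residue i's backbone O (and kept > 3.6 Angstrom from every other receptor
#' polar atom), contact atoms (carbon) are placed 3.8-4.9 Angstrom from the
#' residue's CA, and decoy atoms at least 5.5 Angstrom from every receptor
#' atom. No bond-chemistry realism is attempted: the interaction profiler is
#' distance/element based, so valid elements and coordinates suffice.
#'
#' @param residues residue list (see [bace1_residues()]); hydrogen bonds may
#'   only be planted on residues with role "hbond"/"catalytic".
#' @param hbonds integer vector, planted hydrogen-bond count per residue row.
#' @param contacts logical vector, whether a contact atom is planted for the
#'   residue. Residues with planted hydrogen bonds are contacted implicitly.
#' @param n_decoy number of far-away decoy ligand atoms.
#' @param seed integer seed.
#' @param mol_id,pose_id identifiers written into the SDF record.
#' @param resno_offset offset added to residue numbers in the written
#'   receptor (to exercise numbering maps).
#' @param dir directory the PDB/SDF files are written into (set `NULL` to
#'   skip writing).
#' @return list with `receptor` (data.frame usable directly), `pose`,
#'   `receptor_file`, `pose_file`, and `expected`: per-residue hydrogen-bond
#'   counts and the contacted residue keys ("RESID resno", canonical
#'   numbering).
#' @export
make_pose_fixture <- function(residues, hbonds = rep(0L, nrow(residues)),
                              contacts = rep(FALSE, nrow(residues)),
                              n_decoy = 5, seed = 1, mol_id = "synthmol",
                              pose_id = 1, resno_offset = 0L,
                              dir = tempdir()) {
  stopifnot(length(hbonds) == nrow(residues),
            length(contacts) == nrow(residues), all(hbonds >= 0))
  can_hb <- residues$role %in% c("hbond", "catalytic")
  if (any(hbonds > 0 & !can_hb))
    stop("hydrogen bonds may only be planted on hbond/catalytic residues")
  set.seed(seed)
  centres <- cbind(14 * (seq_len(nrow(residues)) - 1), 0, 0)
  rec <- do.call(rbind, lapply(seq_len(nrow(residues)), function(i)
    .synth_residue(residues$resid[i], residues$resno[i] + resno_offset,
                   centres[i, ])))
  rownames(rec) <- NULL
  class(rec) <- c("receptor", "data.frame")

  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  polar <- rec$elesy %in% c("N", "O", "S")
  lig_xyz <- matrix(numeric(0), 0, 3)
  lig_el <- character(0)
  add_atom <- function(p, el) {
    lig_xyz <<- rbind(lig_xyz, p)
    lig_el <<- c(lig_el, el)
  }
  for (i in seq_len(nrow(residues))) {
    ri <- which(rec$resno == residues$resno[i] + resno_offset)
    o_at <- rec_xyz[ri[rec$elety[ri] == "O"], ]
    ca_at <- rec_xyz[ri[rec$elety[ri] == "CA"], ]
    if (hbonds[i] > 0) {
      for (k in seq_len(hbonds[i])) {
        # stay clear of every other receptor polar atom and other residues
        other_polar <- setdiff(which(polar), ri[rec$elety[ri] == "O"])
        avoid <- rbind(
          cbind(rec_xyz[other_polar, , drop = FALSE], 3.6),
          cbind(rec_xyz[-ri, , drop = FALSE], 5.5),
          if (nrow(lig_xyz)) cbind(lig_xyz, 1.5))
        p <- .place_atom(o_at, 2.8, 3.4, avoid)
        add_atom(p, if (k %% 2 == 1) "N" else "O")
      }
    }
    if (contacts[i] && hbonds[i] == 0) {
      avoid <- rbind(cbind(rec_xyz[-ri, , drop = FALSE], 5.5),
                     if (nrow(lig_xyz)) cbind(lig_xyz, 1.5))
      p <- .place_atom(ca_at, 3.8, 4.9, avoid)
      add_atom(p, "C")
    }
  }
  for (j in seq_len(n_decoy)) {
    add_atom(c(14 * runif(1, 0, nrow(residues) - 1), runif(1, -3, 3),
               25 + 2 * j), "C")
  }
  pose <- list(mol_id = mol_id, pose_id = pose_id, element = lig_el,
               coords = unname(lig_xyz))
  contacted <- contacts | hbonds > 0
  expected <- list(
    hbonds_per_residue = setNames(as.integer(hbonds),
                                  paste(residues$resid, residues$resno)),
    contacts = paste(residues$resid, residues$resno)[contacted])

  receptor_file <- pose_file <- NULL
  if (!is.null(dir)) {
    receptor_file <- file.path(dir, sprintf("%s_receptor.pdb", mol_id))
    pose_file <- file.path(dir, sprintf("%s_pose%d.sdf", mol_id, pose_id))
    bio3d::write.pdb(file = receptor_file,
                     xyz = as.numeric(t(rec_xyz)),
                     type = rep("ATOM", nrow(rec)),
                     resno = rec$resno, resid = rec$resid,
                     elety = rec$elety, chain = rec$chain, elesy = rec$elesy)
    write_pose_sdf(list(pose), pose_file)
  }
  list(receptor = rec, pose = pose, receptor_file = receptor_file,
       pose_file = pose_file, expected = expected)
}

#' Write poses to a multi-record SDF file
#'
#' @param poses list of poses (`mol_id`, `pose_id`, `element`, `coords`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pose_sdf <- function(poses, path) {
  sdfs <- lapply(poses, function(p) {
    n <- nrow(p$coords)
    ab <- cbind(p$coords, matrix(0, n, 13))
    rownames(ab) <- paste(p$element, seq_len(n), sep = "_")
    colnames(ab) <- paste0("C", 1:16)
    nb <- max(n - 1, 1)
    bb <- cbind(pmin(seq_len(nb), n), pmin(seq_len(nb) + 1, n), 1,
                matrix(0, nb, 4))
    rownames(bb) <- seq_len(nb)
    colnames(bb) <- paste0("C", 1:7)
    methods::new("SDF",
      header = c(Molecule_Name = p$mol_id, Source = "dualscreen-synthetic",
                 Comment = "",
                 Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                       n, nb)),
      atomblock = ab, bondblock = bb,
      datablock = c(mol_id = p$mol_id, pose_id = as.character(p$pose_id)))
  })
  set <- methods::new("SDFset", SDF = sdfs,
                      ID = vapply(poses, `[[`, character(1), "mol_id"))
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

#' Synthetic screening library from a fragment grammar
#'
#' Samples valid SMILES from a small parametric grammar (substituent + ring
#' core + optional linker and second core + substituent), canonicalizes them
#' and keeps `n` unique canonical structures. Deterministic under `seed`.
#'
#' @param n library size.
#' @param seed integer seed.
#' @param max_rounds resampling rounds allowed to reach `n` unique
#'   structures.
#' @return data.frame with `mol_id` and canonical `smiles`.
#' @export
make_screening_library <- function(n, seed = 1, max_rounds = 8) {
  stopifnot(n >= 1)
  cores <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCNCC1",
             "C1CCCCC1", "c1ccsc1", "c1ccoc1", "c1cnc2ccccc2c1")
  subs <- c("", "C", "CC", "CCC", "CCCC", "O", "OC", "OCC", "N", "NC",
            "N(C)C", "Cl", "F", "Br", "C(=O)OC", "C(=O)N", "C(=O)O",
            "CN", "CCN", "COC", "OCCN", "C(C)C", "CO", "CCO")
  linkers <- c("", "C", "CC", "O", "OC", "N", "CN")
  set.seed(seed)
  draw <- function(m) {
    two <- runif(m) < 0.5
    s <- paste0(sample(subs, m, TRUE), sample(cores, m, TRUE),
                ifelse(two, paste0(sample(linkers, m, TRUE),
                                   sample(cores, m, TRUE)), ""),
                sample(subs, m, TRUE))
    s
  }
  can <- character(0)
  for (round in seq_len(max_rounds)) {
    need <- n - length(can)
    if (need <= 0) break
    raw <- unique(draw(max(2 * need, 50)))
    new_can <- unique(suppressWarnings(
      unname(canonical_smiles(raw, paste0("tmp", seq_along(raw))))))
    can <- unique(c(can, new_can))
  }
  if (length(can) < n)
    stop(sprintf("grammar exhausted: only %d unique structures", length(can)))
  can <- can[seq_len(n)]
  data.frame(mol_id = sprintf("lib%05d", seq_len(n)), smiles = can,
             stringsAsFactors = FALSE)
}
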