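#' Residue interaction lists
#'
#' Pre-determined binding-site residues whose interactions with a docked
#' pose are counted. `bace1_residues()` returns the beta-secretase list:
#' hydrogen-bonding residues Asp32 (catalytic), Gly34, Thr72, Gln73, Asp228
#' (catalytic), Gly230 and Thr232, plus van der Waals contact residues
#' Gly11, Leu30, Ser35, Tyr71, Phe108 and Thr231. `ache_residues()` returns
#' the nine acetylcholinesterase gorge/peripheral-site contact residues
#' (human numbering): Tyr72, Trp86, Gly121, Tyr124, Glu202, Trp286, Tyr337,
#' Tyr341 and His447.
#'
#' @param chain chain identifier the residues live on.
#' @return data.frame with columns resid (3-letter), resno (canonical
#'   numbering), chain and role ("hbond", "vdw" or "catalytic"; catalytic
#'   residues also count as hydrogen-bonding).
#' @export
bace1_residues <- function(chain = "A") {
  data.frame(
    resid = c("ASP", "GLY", "THR", "GLN", "ASP", "GLY", "THR",
              "GLY", "LEU", "SER", "TYR", "PHE", "THR"),
    resno = c(32L, 34L, 72L, 73L, 228L, 230L, 232L,
              11L, 30L, 35L, 71L, 108L, 231L),
    chain = chain,
    role = c("catalytic", "hbond", "hbond", "hbond", "catalytic", "hbond",
             "hbond", rep("vdw", 6)),
    stringsAsFactors = FALSE)
}

#' @rdname bace1_residues
#' @export
ache_residues <- function(chain = "A") {
  data.frame(
    resid = c("TYR", "TRP", "GLY", "TYR", "GLU", "TRP", "TYR", "TYR", "HIS"),
    resno = c(72L, 86L, 121L, 124L, 202L, 286L, 337L, 341L, 447L),
    chain = chain,
    role = "vdw",
    stringsAsFactors = FALSE)
}

#' Residue numbering map
#'
#' Maps canonical residue numbers (the numbering of the residue lists) to
#' the numbering used in a particular structure file — e.g. the +61 offset
#' under which the catalytic Asp32/Asp228 pair appears as Asp93/Asp289.
#' Maps are configuration, never inferred from the structure.
#'
#' @param canonical,actual integer vectors of equal length (bijective on the
#'   listed residues), or leave both empty and give `offset`.
#' @param offset constant offset applied to every canonical number (ignored
#'   when explicit pairs are given).
#' @return function mapping canonical numbers to structure-file numbers.
#' @export
numbering_map <- function(canonical = integer(), actual = integer(),
                          offset = 0L) {
  stopifnot(length(canonical) == length(actual))
  if (length(canonical)) {
    if (anyDuplicated(canonical) || anyDuplicated(actual))
      stop("numbering map must be bijective")
    lut <- setNames(as.integer(actual), as.character(canonical))
    function(x) {
      out <- lut[as.character(x)]
      out[is.na(out)] <- as.integer(x[is.na(out)])
      unname(out)
    }
  } else {
    function(x) as.integer(x) + as.integer(offset)
  }
}

#' Interaction criteria for pose classification
#'
#' Distance cutoffs and the target-specific "positively docked" rule:
#' beta-secretase poses need at least `min_hbonds` hydrogen bonds of which
#' at least `min_catalytic_hbonds` are to the catalytic Asp pair, and at
#' least `min_contacts` contacted residues; acetylcholinesterase poses must
#' contact every residue of the nine-residue list.
#'
#' @param target "bace1" or "ache".
#' @param hbond_max_dist heavy-atom hydrogen-bond cutoff (Angstrom).
#' @param vdw_max_dist van der Waals contact cutoff (Angstrom).
#' @param min_hbonds,min_catalytic_hbonds,min_contacts bace1 rule fields.
#' @param any_residue when TRUE, contacts are counted against any protein
#'   residue rather than the configured list (bace1 only).
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(target = c("bace1", "ache"),
                                 hbond_max_dist = 3.5, vdw_max_dist = 5.0,
                                 min_hbonds = 4L, min_catalytic_hbonds = 2L,
                                 min_contacts = 8L, any_residue = FALSE) {
  target <- match.arg(target)
  stopifnot(hbond_max_dist > 0, vdw_max_dist > 0)
  structure(list(target = target, hbond_max_dist = hbond_max_dist,
                 vdw_max_dist = vdw_max_dist, min_hbonds = min_hbonds,
                 min_catalytic_hbonds = min_catalytic_hbonds,
                 min_contacts = min_contacts, any_residue = any_residue),
            class = "interaction_criteria")
}

#' Read a receptor structure
#'
#' Loads a PDB file and strips waters, ions and bound ligands (HETATM
#' records), keeping protein atoms with their element symbols. Coordinates
#' are used as-is (Angstrom, no symmetry expansion).
#'
#' @param path PDB file.
#' @return data.frame of class `receptor` with columns resid, resno, chain,
#'   elety (atom name), elesy (element) and x, y, z.
#' @export
read_receptor <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" &
             !(at$resid %in% c("HOH", "WAT", "DOD", "NA", "CL", "MG", "ZN",
                               "SO4", "PO4")), , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms in ", path)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- sub("^[0-9]*", "", at$elety)
    el <- substr(el, 1, 1)
  }
  out <- data.frame(resid = at$resid, resno = at$resno, chain = at$chain,
                    elety = at$elety, elesy = trimws(el),
                    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  class(out) <- c("receptor", "data.frame")
  out
}

#' Read docked poses from an SDF file
#'
#' Multi-record SDF; pose order is preserved. Poses are grouped into
#' molecules by the record title (default) or by a data field.
#'
#' @param path SDF file.
#' @param group_by "title" or "field".
#' @param field data-field name when `group_by = "field"`.
#' @return list of poses; each pose is a list with `mol_id`, `pose_id`
#'   (running number within its molecule), `element` and `coords`
#'   (n x 3 matrix).
#' @export
read_poses <- function(path, group_by = c("title", "field"), field = NULL) {
  group_by <- match.arg(group_by)
  sdf <- ChemmineR::read.SDFset(path)
  ids <- vapply(seq_along(sdf), function(i) {
    if (group_by == "title") {
      unname(ChemmineR::header(sdf[[i]])[["Molecule_Name"]])
    } else {
      db <- ChemmineR::datablock(sdf[[i]])
      if (is.null(db[[field]])) stop("pose record lacks field ", field)
      as.character(db[[field]])
    }
  }, character(1))
  counter <- list()
  poses <- vector("list", length(sdf))
  for (i in seq_along(sdf)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    id <- ids[i]
    counter[[id]] <- (counter[[id]] %||% 0L) + 1L
    poses[[i]] <- list(
      mol_id = id, pose_id = counter[[id]],
      element = sub("_.*", "", rownames(ab)),
      coords = unname(ab[, 1:3, drop = FALSE]))
  }
  poses
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atoms of one listed residue in a receptor (after numbering mapping)
.residue_atoms <- function(receptor, resno, chain) {
  receptor[receptor$resno == resno &
             (is.na(chain) | receptor$chain == chain), , drop = FALSE]
}

.pairwise_dist <- function(a, b) {
  # a: n x 3, b: m x 3
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Count hydrogen bonds between a pose and listed residues
#'
#' Heavy-atom hydrogen-bond detection: a bond is a (receptor polar atom,
#' ligand polar atom) pair at distance <= the cutoff, with donor/acceptor
#' capable elements — N and O in either role, S as acceptor only, so a
#' qualifying pair has both atoms in \{N, O, S\} and at least one in
#' \{N, O\}. No angle term is applied (poses may lack hydrogens). Multiple
#' pairs to the same residue count separately. Only residues with role
#' "hbond" or "catalytic" are scanned.
#'
#' @param pose a pose (list with `element`, `coords`) from [read_poses()].
#' @param receptor a [read_receptor()] table.
#' @param residues residue list, e.g. [bace1_residues()].
#' @param criteria an [interaction_criteria()].
#' @param map optional [numbering_map()].
#' @return data.frame with one row per hydrogen bond: resid, resno
#'   (canonical), receptor_atom, ligand_atom (index), distance.
#' @export
count_hbonds <- function(pose, receptor, residues, criteria, map = NULL) {
  hb <- residues[residues$role %in% c("hbond", "catalytic"), , drop = FALSE]
  if (nrow(hb) == 0)
    return(data.frame(resid = character(), resno = integer(),
                      receptor_atom = character(), ligand_atom = integer(),
                      distance = numeric()))
  lig_polar <- which(pose$element %in% c("N", "O", "S"))
  out <- list()
  for (i in seq_len(nrow(hb))) {
    rn <- if (is.null(map)) hb$resno[i] else map(hb$resno[i])
    at <- .residue_atoms(receptor, rn, hb$chain[i])
    if (nrow(at) == 0)
      stop(sprintf("listed residue %s%d (structure numbering %d) absent from structure",
                   hb$resid[i], hb$resno[i], rn))
    pol <- at[at$elesy %in% c("N", "O", "S"), , drop = FALSE]
    if (nrow(pol) == 0 || length(lig_polar) == 0) next
    d <- .pairwise_dist(as.matrix(pol[, c("x", "y", "z")]),
                        pose$coords[lig_polar, , drop = FALSE])
    valid <- outer(pol$elesy, pose$element[lig_polar],
                   function(a, b) a %in% c("N", "O") | b %in% c("N", "O"))
    hit <- which(d <= criteria$hbond_max_dist & valid, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        resid = hb$resid[i], resno = hb$resno[i],
        receptor_atom = pol$elety[hit[, 1]],
        ligand_atom = lig_polar[hit[, 2]],
        distance = d[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(resid = character(), resno = integer(),
                      receptor_atom = character(), ligand_atom = integer(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contacted residues within the van der Waals cutoff
#'
#' A listed residue is contacted iff any of its heavy atoms lies within the
#' contact cutoff of any ligand heavy atom. With `criteria$any_residue` the
#' scan runs over every residue in the structure instead of the list.
#'
#' @inheritParams count_hbonds
#' @return data.frame of contacted residues (resid, resno canonical where
#'   listed, min_dist).
#' @export
count_vdw_contacts <- function(pose, receptor, residues, criteria,
                               map = NULL) {
  heavy <- which(pose$element != "H")
  lig <- pose$coords[heavy, , drop = FALSE]
  if (criteria$any_residue) {
    rk <- unique(receptor[, c("resid", "resno", "chain")])
    scan <- data.frame(resid = rk$resid, resno = rk$resno, chain = rk$chain,
                       stringsAsFactors = FALSE)
    rn_actual <- scan$resno
  } else {
    scan <- residues
    rn_actual <- if (is.null(map)) scan$resno else map(scan$resno)
  }
  hit <- logical(nrow(scan))
  mind <- rep(NA_real_, nrow(scan))
  for (i in seq_len(nrow(scan))) {
    at <- .residue_atoms(receptor, rn_actual[i], scan$chain[i])
    if (nrow(at) == 0) {
      if (!criteria$any_residue)
        stop(sprintf("listed residue %s%d (structure numbering %d) absent from structure",
                     scan$resid[i], scan$resno[i], rn_actual[i]))
      next
    }
    at <- at[at$elesy != "H", , drop = FALSE]
    d <- .pairwise_dist(as.matrix(at[, c("x", "y", "z")]), lig)
    mind[i] <- min(d)
    hit[i] <- mind[i] <= criteria$vdw_max_dist
  }
  out <- data.frame(resid = scan$resid, resno = scan$resno,
                    min_dist = mind, stringsAsFactors = FALSE)[hit, ,
                                                               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile one pose against a receptor
#'
#' @inheritParams count_hbonds
#' @return list of class `pose_profile`: `hbonds` (data.frame), `contacts`
#'   (data.frame of contacted residues), counts and the pose/molecule ids.
#' @export
profile_pose <- function(pose, receptor, residues, criteria, map = NULL) {
  hb <- count_hbonds(pose, receptor, residues, criteria, map)
  ct <- count_vdw_contacts(pose, receptor, residues, criteria, map)
  cat_res <- residues[residues$role == "catalytic", , drop = FALSE]
  n_cat <- sum(hb$resno %in% cat_res$resno & hb$resid %in% cat_res$resid)
  structure(list(mol_id = pose$mol_id, pose_id = pose$pose_id,
                 hbonds = hb, contacts = ct,
                 n_hbonds = nrow(hb), n_catalytic_hbonds = n_cat,
                 n_contacts = nrow(ct)),
            class = "pose_profile")
}

#' Classify a pose as positively docked
#'
#' Applies the target rule of the criteria: for beta-secretase, at least
#' four hydrogen bonds of which at least two to the catalytic Asp pair
#' (counted over both) and at least eight contacted residues; for
#' acetylcholinesterase, contacts with the full nine-residue list.
#'
#' @param profile a [profile_pose()] result.
#' @param criteria the same [interaction_criteria()] used to compute it.
#' @param residues the residue list used to compute the profile (needed for
#'   the all-residue rule).
#' @return logical: positively docked or not.
#' @export
classify_pose <- function(profile, criteria, residues) {
  stopifnot(inherits(profile, "pose_profile"))
  if (criteria$target == "bace1") {
    profile$n_hbonds >= criteria$min_hbonds &&
      profile$n_catalytic_hbonds >= criteria$min_catalytic_hbonds &&
      profile$n_contacts >= criteria$min_contacts
  } else {
    req <- paste(residues$resid, residues$resno)
    got <- paste(profile$contacts$resid, profile$contacts$resno)
    all(req %in% got)
  }
}

#' Per-molecule docking outcome over one or more structures
#'
#' A molecule is docked in a structure when any of its (at most ten) poses
#' classifies as positively docked; it is docked overall when it is docked
#' in at least one structure. The reported total pose count is the sum of
#' positively-docked pose counts across structures (so at most 10 per
#' structure, e.g. 30 over three structures).
#'
#' @param poses_by_structure named list: structure id -> list of poses of
#'   one molecule (each as from [read_poses()]).
#' @param receptors named list of [read_receptor()] tables (same names).
#' @param residues residue list.
#' @param criteria an [interaction_criteria()].
#' @param maps optional named list of [numbering_map()]s per structure.
#' @return list of class `docking_outcome`: mol_id, per-structure docked
#'   flags and pose counts, aggregate `docked` and `total_poses`.
#' @export
profile_molecule <- function(poses_by_structure, receptors, residues,
                             criteria, maps = NULL) {
  sn <- names(poses_by_structure)
  stopifnot(!is.null(sn), all(sn %in% names(receptors)))
  docked <- setNames(logical(length(sn)), sn)
  counts <- setNames(integer(length(sn)), sn)
  mol_id <- NA_character_
  for (s in sn) {
    poses <- poses_by_structure[[s]]
    if (length(poses) > 10) {
      warning("more than 10 poses for one structure; keeping the first 10")
      poses <- poses[seq_len(10)]
    }
    map <- if (is.null(maps)) NULL else maps[[s]]
    ok <- vapply(poses, function(p) {
      classify_pose(profile_pose(p, receptors[[s]], residues, criteria, map),
                    criteria, residues)
    }, logical(1))
    counts[s] <- sum(ok)
    docked[s] <- any(ok)
    if (length(poses)) mol_id <- poses[[1]]$mol_id
  }
  structure(list(mol_id = mol_id, structures = sn,
                 docked_by_structure = docked, poses_by_structure = counts,
                 docked = any(docked), total_poses = sum(counts)),
            class = "docking_outcome")
}

#' @export
print.docking_outcome <- function(x, ...) {
  cat(sprintf("Molecule %s: %s (poses: %s; total %d)\n", x$mol_id,
              if (x$docked) "docked" else "not docked",
              paste(sprintf("%s=%d", x$structures, x$poses_by_structure),
                    collapse = ", "),
              x$total_poses))
  invisible(x)
}
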