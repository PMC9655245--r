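# Shared tiny fixtures. Everything chemical is generated in code; OpenBabel
# calls are kept small because each SMILES batch costs real time.

smiles_small <- c(
  eth = "CCO", eth2 = "OCC",            # same structure, different writing
  phe = "c1ccccc1O", tol = "Cc1ccccc1",
  apap = "CC(=O)Nc1ccc(O)cc1", dea = "CCN(CC)CC",
  pyr = "c1ccncc1", nap = "c1ccc2ccccc2c1",
  ala = "C[C@H](N)C(=O)O", ben = "c1ccccc1"
)

# a manually laid-out receptor with two residues far apart
manual_receptor <- function() {
  rec <- rbind(
    data.frame(resid = "ASP", resno = 32L, chain = "A",
               elety = c("N", "CA", "C", "O", "OD1"),
               elesy = c("N", "C", "C", "O", "O"),
               x = c(-1.2, 0, 1.2, 1.8, 0.5), y = c(0.8, 0, 0.8, 1.9, -1.4),
               z = 0),
    data.frame(resid = "GLY", resno = 34L, chain = "A",
               elety = c("N", "CA", "C", "O"),
               elesy = c("N", "C", "C", "O"),
               x = 20 + c(-1.2, 0, 1.2, 1.8), y = c(0.8, 0, 0.8, 1.9),
               z = 0))
  class(rec) <- c("receptor", "data.frame")
  rec
}

manual_pose <- function(element, coords, mol_id = "m1", pose_id = 1) {
  list(mol_id = mol_id, pose_id = pose_id, element = element,
       coords = matrix(coords, ncol = 3, byrow = TRUE))
}

# build an ise model object directly from filters + performances (bypasses
# the search; used to test the index arithmetic in isolation)
manual_ise <- function(filters, perf, cap = 1, eps = 0.5) {
  structure(list(filters = filters, performance = perf, n = length(filters),
                 cap = cap, eps = eps,
                 descriptors = unique(unlist(lapply(filters,
                                                    `[[`, "descriptor"))),
                 seed = NA_integer_, call = NULL),
            class = "ise")
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(m))
}
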