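#' @importFrom methods new is
#' @importFrom stats quantile sd cor predict coef rexp rnorm runif setNames
#' @importFrom utils head read.csv write.csv
NULL

# Parse SMILES through OpenBabel. Invalid strings are dropped with a warning
# rather than aborting the batch; returns the SDFset plus the ids that survived.
.parse_smiles <- function(smiles, ids = names(smiles)) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  names(smiles) <- ids
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  ok <- ids
  if (is.null(sdf) || length(sdf) != length(smiles)) {
    # batch conversion failed or silently dropped records: go one by one
    pieces <- vector("list", length(smiles))
    keep <- logical(length(smiles))
    for (i in seq_along(smiles)) {
      s <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
        error = function(e) NULL
      )
      if (!is.null(s) && length(s) == 1 &&
          nrow(ChemmineR::atomblock(s[[1]])) > 0) {
        pieces[[i]] <- s[[1]]
        keep[i] <- TRUE
      }
    }
    if (!any(keep)) stop("no SMILES string could be parsed")
    if (any(!keep))
      warning(sprintf("rejected %d unparseable SMILES: %s",
                      sum(!keep), paste(ids[!keep], collapse = ", ")))
    sdf <- new("SDFset", SDF = pieces[keep], ID = ids[keep])
    ok <- ids[keep]
  } else {
    ChemmineR::cid(sdf) <- ids
  }
  list(sdf = sdf, ids = ok)
}

#' Canonicalize SMILES strings
#'
#' Round-trips SMILES through OpenBabel and returns the canonical form.
#' Unparseable strings are dropped with a warning.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional molecule identifiers (defaults to names of `smiles`).
#' @return named character vector of canonical SMILES (names are ids of the
#'   molecules that parsed).
#' @export
canonical_smiles <- function(smiles, ids = names(smiles)) {
  p <- .parse_smiles(smiles, ids)
  pr <- ChemmineR::propOB(p$sdf)
  setNames(as.character(pr$cansmi), p$ids)
}

# formal charge summed over bracket atoms of a canonical SMILES
.smiles_fcharge <- function(smi) {
  vapply(smi, function(s) {
    br <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (length(br) == 0) return(0)
    sum(vapply(br, function(b) {
      plus <- regmatches(b, regexpr("\\+[0-9]*", b))
      minus <- regmatches(b, regexpr("-[0-9]*", b))
      q <- 0
      if (length(plus) && nchar(plus)) {
        q <- q + if (nchar(plus) > 1) as.integer(substring(plus, 2)) else
          lengths(regmatches(b, gregexpr("\\+", b)))
      }
      if (length(minus) && nchar(minus)) {
        q <- q - if (nchar(minus) > 1) as.integer(substring(minus, 2)) else
          lengths(regmatches(b, gregexpr("-", b)))
      }
      q
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# stereocentre annotations in a canonical SMILES ("@" or "@@" per atom)
.smiles_chiral <- function(smi) {
  vapply(smi, function(s) {
    br <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (length(br) == 0) return(0L)
    sum(grepl("@", br, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute the 2D descriptor table
#'
#' An open 2D physico-chemical descriptor set computed with OpenBabel plus
#' heavy-atom element counts. Column names follow the conventional
#' cheminformatics abbreviations: `weight` (molecular weight), `logP`
#' (calculated octanol/water partition), `TPSA`, `HBD`/`HBA` (hydrogen-bond
#' donor/acceptor counts), `MR` (molar refractivity), `a_hyd` (number of
#' non-polar atoms: carbon plus halogens), `a_nN`, `a_nO`, `a_nS`, `a_nI`,
#' etc. (element counts), `a_heavy` (heavy-atom count), `FCharge` (sum of
#' formal charges, derived from the canonical SMILES) and `chiral` (number of
#' annotated stereocentres in the canonical SMILES).
#'
#' @param smiles character vector of SMILES.
#' @param ids molecule identifiers; row names of the result.
#' @return data.frame of numeric descriptors, one row per molecule that
#'   parsed, row names = ids.
#' @export
descriptor_table <- function(smiles, ids = names(smiles)) {
  p <- .parse_smiles(smiles, ids)
  pr <- ChemmineR::propOB(p$sdf)
  counts <- lapply(seq_along(p$sdf), function(i) {
    el <- sub("_.*", "", rownames(ChemmineR::atomblock(p$sdf[[i]])))
    table(factor(el, levels = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")))
  })
  cm <- do.call(rbind, counts)
  halo <- cm[, "F"] + cm[, "Cl"] + cm[, "Br"] + cm[, "I"]
  out <- data.frame(
    weight  = pr$MW,
    logP    = pr$logP,
    TPSA    = pr$TPSA,
    HBD     = pr$HBD,
    HBA     = pr$HBA2,
    MR      = pr$MR,
    a_nC    = as.numeric(cm[, "C"]),
    a_nN    = as.numeric(cm[, "N"]),
    a_nO    = as.numeric(cm[, "O"]),
    a_nS    = as.numeric(cm[, "S"]),
    a_nP    = as.numeric(cm[, "P"]),
    a_nF    = as.numeric(cm[, "F"]),
    a_nCl   = as.numeric(cm[, "Cl"]),
    a_nBr   = as.numeric(cm[, "Br"]),
    a_nI    = as.numeric(cm[, "I"]),
    a_halo  = as.numeric(halo),
    a_heavy = as.numeric(rowSums(cm)),
    a_hyd   = as.numeric(cm[, "C"] + halo),
    a_pol   = as.numeric(cm[, "N"] + cm[, "O"] + cm[, "S"] + cm[, "P"]),
    FCharge = .smiles_fcharge(as.character(pr$cansmi)),
    chiral  = as.numeric(.smiles_chiral(as.character(pr$cansmi))),
    row.names = p$ids
  )
  stopifnot(!anyNA(out))
  out
}

#' Compute FP2 path fingerprints
#'
#' 1024-bit linear-path fingerprints (paths up to 7 bonds, OpenBabel FP2
#' dialect). The dialect is recorded in the `"dialect"` attribute because
#' Tanimoto values depend on it.
#'
#' @inheritParams descriptor_table
#' @return 0/1 integer matrix, one row per parsed molecule (row names = ids),
#'   1024 columns, with attribute `dialect = "FP2/1024"`.
#' @export
fingerprint_matrix <- function(smiles, ids = names(smiles)) {
  p <- .parse_smiles(smiles, ids)
  fp <- ChemmineR::fingerprintOB(p$sdf, "FP2")
  m <- fp@fpma
  rownames(m) <- p$ids
  storage.mode(m) <- "integer"
  attr(m, "dialect") <- "FP2/1024"
  m
}

#' Count SMARTS pattern matches
#'
#' Thin wrapper around OpenBabel SMARTS matching, used for structural
#' exclusion lists (e.g. phosphorus-containing, carbamate or ester motifs
#' typical of covalent cholinesterase inhibitors).
#'
#' @inheritParams descriptor_table
#' @param smarts character vector of SMARTS patterns.
#' @return integer matrix of match counts, molecules x patterns.
#' @export
smarts_hits <- function(smiles, smarts, ids = names(smiles)) {
  p <- .parse_smiles(smiles, ids)
  hits <- vapply(smarts, function(pat) {
    as.integer(ChemmineR::smartsSearchOB(p$sdf, pat, uniqueMatches = FALSE))
  }, integer(length(p$sdf)))
  hits <- matrix(hits, nrow = length(p$sdf),
                 dimnames = list(p$ids, smarts))
  hits
}
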