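# Cheminformatics layer: SMILES parsing, Bemis-Murcko scaffolds, ECFP.
# Parsing, fingerprint hashing and canonicalisation are delegated to
# OpenBabel through ChemmineR/ChemmineOB; the scaffold pruning itself is
# implemented here (terminal-atom removal plus exocyclic multiple-bond
# add-back, the standard Bemis-Murcko convention).

# Parse a vector of SMILES one molecule at a time. Returns list(valid =
# logical, sdf = list of single-molecule SDFset or NULL).
.parse_smiles <- function(smiles) {
  n <- length(smiles)
  valid <- logical(n)
  sdfs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    nm <- s
    names(nm) <- paste0("m", i)
    res <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(nm)),
                    error = function(e) NULL)
    if (!is.null(res) && length(res) == 1 &&
        nrow(ChemmineR::atomblock(res[[1]])) > 0) {
      valid[i] <- TRUE
      sdfs[[i]] <- res
    }
  }
  list(valid = valid, sdf = sdfs)
}

# Scaffold atoms of one SDF molecule: iteratively prune degree-1 atoms,
# drop isolated atoms, then add back atoms attached to the retained core by
# a double/triple bond. Returns "" for acyclic molecules.
.murcko_one <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0) return("")
  b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2])
  bo <- as.integer(bb[, 3])
  keep <- rep(TRUE, n)
  degree <- function() {
    d <- integer(n)
    on <- keep[b1] & keep[b2]
    for (k in which(on)) {
      d[b1[k]] <- d[b1[k]] + 1L
      d[b2[k]] <- d[b2[k]] + 1L
    }
    d
  }
  repeat {
    term <- keep & (degree() == 1L)
    if (!any(term)) break
    keep[term] <- FALSE
  }
  keep[keep & degree() == 0L] <- FALSE
  if (!any(keep)) return("")
  addback <- rep(FALSE, n)
  multi <- bo >= 2L
  addback[b2[multi & keep[b1] & !keep[b2]]] <- TRUE
  addback[b1[multi & keep[b2] & !keep[b1]]] <- TRUE
  keep <- keep | addback

  idx <- which(keep)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  bsel <- which(keep[b1] & keep[b2])
  elem <- gsub("_.*", "", rownames(ab)[idx])
  xyz <- cbind(ab[idx, 1], ab[idx, 2],
               if (ncol(ab) >= 3) ab[idx, 3] else 0)
  mol <- c("", " molal scaffold", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(idx), length(bsel)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], elem),
           if (length(bsel))
             sprintf("%3d%3d%3d  0  0  0  0", remap[b1[bsel]], remap[b2[bsel]],
                     bo[bsel]),
           "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste(mol, collapse = "\n"))
  can <- strsplit(trimws(out), "[\t\n ]")[[1]][1]
  if (is.na(can)) "" else can
}

#' Bemis-Murcko scaffolds of a set of molecules
#'
#' Computes the canonical SMILES of each molecule's Bemis-Murcko scaffold
#' (ring systems plus connecting linkers; atoms double- or triple-bonded to
#' the core are retained). Acyclic molecules yield the empty string and are
#' treated as one shared scaffold group by [scaffoldSplit()].
#'
#' @param x A [MoleculeTable-class] or a character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` = acyclic).
#' @examples
#' murckoScaffolds(c("CC(=O)Oc1ccccc1C(=O)O", "CCCC"))
#' @export
murckoScaffolds <- function(x) {
  smiles <- if (is(x, "MoleculeTable")) smilesOf(x) else as.character(x)
  parsed <- .parse_smiles(smiles)
  if (!all(parsed$valid))
    .input_error(sprintf("unparseable SMILES at position(s): %s",
                         paste(which(!parsed$valid), collapse = ", ")))
  vapply(parsed$sdf, function(s) .murcko_one(s[[1]]), character(1))
}

# OpenBabel circular fingerprints for a SMILES vector (all parseable),
# folded down to n_bits by OR-ing bit i into position i mod n_bits.
# radius r maps to the diameter-2r ECFP variant.
.ecfp_matrix <- function(smiles, radius, n_bits) {
  if (!radius %in% 1:5)
    .config_error("radius must be an integer in 1..5 (ECFP2..ECFP10)")
  nm <- smiles
  names(nm) <- paste0("m", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(nm))
  fp <- ChemmineR::as.matrix(
    ChemmineR::fingerprintOB(sdf, paste0("ECFP", 2L * as.integer(radius))))
  storage.mode(fp) <- "numeric"
  if (ncol(fp) <= n_bits) {
    out <- matrix(0, nrow(fp), n_bits)
    out[, seq_len(ncol(fp))] <- fp
  } else {
    out <- matrix(0, nrow(fp), n_bits)
    grp <- (seq_len(ncol(fp)) - 1L) %% n_bits + 1L
    for (j in seq_len(n_bits)) {
      cols <- which(grp == j)
      out[, j] <- as.numeric(rowSums(fp[, cols, drop = FALSE]) > 0)
    }
  }
  rownames(out) <- NULL
  out
}
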