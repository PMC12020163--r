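# Feature construction (ECFP fingerprints, precomputed embeddings) and
# feature-space separability diagnostics.

#' Extended-connectivity fingerprints
#'
#' Hashed circular-substructure (Morgan-type) fingerprints: substructures
#' up to `radius` bonds around each atom are enumerated and hashed into a
#' fixed-length binary vector. The default (radius 2, 1024 bits) is the
#' common ECFP4 setting. Deterministic: identical molecules -- under any
#' SMILES spelling -- give identical fingerprints.
#'
#' @param table A [MoleculeTable-class] (all SMILES must parse) or a
#'   character vector of SMILES.
#' @param radius Circular-substructure radius in bonds (1..5).
#' @param nBits Fingerprint length; hashed bits are folded modulo `nBits`.
#' @return A [FeatureMatrix-class] of kind `"ecfp"`.
#' @examples
#' fp <- featurizeEcfp(c("CCO", "OCC"))
#' identical(featureValues(fp)[1, ], featureValues(fp)[2, ])
#' @export
featurizeEcfp <- function(table, radius = 2L, nBits = 1024L) {
  smiles <- if (is(table, "MoleculeTable")) smilesOf(table) else
    as.character(table)
  if (nBits < 64) .config_error("nBits must be at least 64")
  if (radius < 1) .config_error("radius must be at least 1")
  parsed <- .parse_smiles(smiles)
  if (!all(parsed$valid))
    .input_error(sprintf("unparseable SMILES at row(s): %s",
                         paste(which(!parsed$valid), collapse = ", ")))
  vals <- .ecfp_matrix(smiles, radius, as.integer(nBits))
  new("FeatureMatrix", values = vals, kind = "ecfp")
}

# Minimal reader for 2-D little-endian .npy arrays (v1/v2 headers,
# float32/float64/int32/int64, C or Fortran order). No R package in the
# dependency set reads the format.
.read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic), c(0x93L, 0x4eL, 0x55L, 0x4dL, 0x50L, 0x59L)))
    .input_error(sprintf("%s is not an .npy file", path))
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else
    readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([^']+)'$", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shape_s), ",")[[1]])
  if (length(shape) != 2)
    .input_error("only 2-D .npy arrays are supported")
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4, endian = "little")),
    "<i8" = readBin(con, "double", n, size = 8, endian = "little"),
    .input_error(sprintf("unsupported .npy dtype '%s'", descr)))
  if (fortran) matrix(vals, nrow = shape[1], ncol = shape[2])
  else t(matrix(vals, nrow = shape[2], ncol = shape[1]))
}

#' Load a precomputed embedding matrix
#'
#' Reads per-molecule embeddings (e.g. pooled transformer output) from a
#' 2-D `.npy` array or a headerless CSV matrix, aligned row-for-row with
#' the molecule table. Any embedding dimension is accepted and recorded;
#' the encoder that produced the embeddings is out of scope.
#'
#' @param path `.npy` or CSV file.
#' @param expectedRows Number of molecules the embeddings must align to.
#' @return A [FeatureMatrix-class] of kind `"embedding"`.
#' @export
loadEmbeddings <- function(path, expectedRows) {
  if (!file.exists(path)) .input_error(sprintf("file not found: %s", path))
  vals <- if (grepl("\\.npy$", path, ignore.case = TRUE)) .read_npy(path)
  else as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  if (nrow(vals) != expectedRows)
    .input_error(sprintf(
      "embedding rows (%d) do not align with the molecule table (%d)",
      nrow(vals), expectedRows))
  if (any(!is.finite(vals)))
    .input_error("embeddings contain non-finite entries")
  new("FeatureMatrix", values = vals, kind = "embedding")
}

#' Write a feature matrix to CSV
#'
#' @param features A [FeatureMatrix-class].
#' @param path Output path (headerless CSV).
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(features, path) {
  stopifnot(is(features, "FeatureMatrix"))
  utils::write.table(features@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# k nearest neighbours by squared Euclidean distance, computed in row
# blocks to bound memory; returns mean same-label fraction.
.knn_purity <- function(x, labels, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  block <- max(1L, min(n, as.integer(2e6 / n)))
  agree <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d <- d2[r, ]
      d[i] <- Inf
      nb <- order(d)[seq_len(k)]
      agree[i] <- mean(labels[nb] == labels[i])
    }
  }
  mean(agree)
}

#' Class-separability metrics of a feature space
#'
#' Quantifies how well the two classes separate in feature space using
#' three complementary metrics: Fisher's ratio (squared distance between
#' the class means over the summed traces of the per-class sample
#' covariance matrices), the two-cluster Davies-Bouldin index (classes as
#' clusters, centroid = class mean, scatter = mean Euclidean distance to
#' the centroid), and class purity (mean fraction of each point's
#' `kNeighbors` nearest neighbours, excluding itself, sharing its label).
#' Structured feature spaces score a higher Fisher ratio and purity and a
#' lower Davies-Bouldin index than scattered, overlapping ones.
#'
#' @param features A [FeatureMatrix-class] or numeric matrix.
#' @param labels Binary vector (both classes present).
#' @param kNeighbors Neighbourhood size for the purity (`< n`).
#' @return A [SeparabilityReport-class].
#' @export
separability <- function(features, labels, kNeighbors = 10L) {
  x <- if (is(features, "FeatureMatrix")) features@values else
    as.matrix(features)
  labels <- as.numeric(labels)
  if (length(labels) != nrow(x))
    .input_error("labels must have one entry per feature row")
  if (length(unique(labels)) < 2)
    .input_error("both classes must be present")
  if (kNeighbors >= nrow(x))
    .config_error("kNeighbors must be smaller than the number of points")
  xp <- x[labels == 1, , drop = FALSE]
  xn <- x[labels == 0, , drop = FALSE]
  mu_p <- colMeans(xp)
  mu_n <- colMeans(xn)
  tr_p <- sum(apply(xp, 2, stats::var))
  tr_n <- sum(apply(xn, 2, stats::var))
  fisher <- sum((mu_p - mu_n)^2) / (tr_p + tr_n)
  s_p <- mean(sqrt(rowSums((xp - rep(mu_p, each = nrow(xp)))^2)))
  s_n <- mean(sqrt(rowSums((xn - rep(mu_n, each = nrow(xn)))^2)))
  m <- sqrt(sum((mu_p - mu_n)^2))
  db <- (s_p + s_n) / m
  purity <- .knn_purity(x, labels, as.integer(kNeighbors))
  new("SeparabilityReport", fisherRatio = fisher, daviesBouldin = db,
      classPurity = purity, kNeighbors = as.integer(kNeighbors))
}
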