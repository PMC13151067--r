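#' @include AllClasses.R genetic-code.R
NULL

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# EMBOSS-style side-chain pKa values and charge signs
PKA_SIDECHAIN <- data.frame(
  token = c("C", "D", "E", "H", "K", "R", "Y"),
  pKa = c(8.5, 3.9, 4.1, 6.5, 10.8, 12.5, 10.1),
  sign = c(-1, -1, -1, +1, +1, +1, -1),
  stringsAsFactors = FALSE
)
PKA_NTERM <- 8.6
PKA_CTERM <- 3.6

ALIPHATIC_WEIGHTS <- c(A = 1.0, V = 2.9, I = 3.9, L = 3.9)

#' Default physicochemical scale set
#'
#' Kyte-Doolittle hydropathy, an EMBOSS-style ionizable-group pKa table
#' (side chains C, D, E, H, K, R, Y plus the termini), and Ikai aliphatic
#' weights (A 1.0, V 2.9, I 3.9, L 3.9). Non-canonical residue tokens get an
#' override row each; the built-in `AcrK` override is lysine-like hydropathy
#' (-3.9) with no ionizable side chain (the epsilon-amine is acylated) and
#' aliphatic weight 0.
#'
#' @param ncaa named list of overrides: token -> `list(hydropathy =, pKa =
#'   (NA for none), sign =, aliphatic =)`.
#' @return a `ScaleSet` (classed list).
#' @export
defaultScaleSet <- function(ncaa = list(
    AcrK = list(hydropathy = -3.9, pKa = NA_real_, sign = 0, aliphatic = 0))) {
  hydro <- KYTE_DOOLITTLE
  pka <- PKA_SIDECHAIN
  ali <- ALIPHATIC_WEIGHTS
  for (tok in names(ncaa)) {
    ov <- ncaa[[tok]]
    hydro[tok] <- ov$hydropathy
    if (!is.na(ov$pKa)) {
      pka <- rbind(pka, data.frame(token = tok, pKa = ov$pKa, sign = ov$sign))
    }
    if (!is.null(ov$aliphatic) && ov$aliphatic != 0) ali[tok] <- ov$aliphatic
  }
  structure(list(hydropathy = hydro, pKa = pka, aliphatic = ali,
                 pKaNterm = PKA_NTERM, pKaCterm = PKA_CTERM),
            class = "ScaleSet")
}

.tokensOf <- function(peptide) {
  if (length(peptide) == 1L) parsePeptide(peptide) else peptide
}

.checkCoverage <- function(tokens, covered, what) {
  missing <- setdiff(unique(tokens), covered)
  if (length(missing)) {
    stop("no ", what, " value for token(s): ", paste(missing, collapse = ", "))
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy over the peptide.
#'
#' @param peptide serialized peptide string or token vector.
#' @param scales a [defaultScaleSet()].
#' @return mean hydropathy (dimensionless).
#' @examples
#' gravy("II")  # 4.5
#' @export
gravy <- function(peptide, scales = defaultScaleSet()) {
  tokens <- .tokensOf(peptide)
  if (!length(tokens)) stop("peptide must be nonempty")
  .checkCoverage(tokens, names(scales$hydropathy), "hydropathy")
  mean(scales$hydropathy[tokens])
}

#' Net charge at a given pH (Henderson-Hasselbalch)
#'
#' Each basic group contributes `+1 / (1 + 10^(pH - pKa))`, each acidic group
#' `-1 / (1 + 10^(pKa - pH))`; the free termini are included only when
#' `includeTermini` (macrocyclization typically removes or blocks them).
#'
#' @param peptide serialized peptide string or token vector.
#' @param pH solution pH, in (0, 14).
#' @param scales a [defaultScaleSet()].
#' @param includeTermini include the N/C terminal groups.
#' @return signed net charge (elementary charges).
#' @examples
#' netCharge("DD", pH = 7)  # ~ -2
#' @export
netCharge <- function(peptide, pH = 7.4, scales = defaultScaleSet(),
                      includeTermini = FALSE) {
  stopifnot(pH > 0, pH < 14)
  tokens <- .tokensOf(peptide)
  if (!length(tokens)) stop("peptide must be nonempty")
  .checkCoverage(tokens, names(scales$hydropathy), "scale")
  q <- 0
  for (i in seq_len(nrow(scales$pKa))) {
    n <- sum(tokens == scales$pKa$token[i])
    if (!n) next
    pKa <- scales$pKa$pKa[i]
    q <- q + n * if (scales$pKa$sign[i] > 0) {
      1 / (1 + 10^(pH - pKa))
    } else {
      -1 / (1 + 10^(pKa - pH))
    }
  }
  if (includeTermini) {
    q <- q + 1 / (1 + 10^(pH - scales$pKaNterm)) -
      1 / (1 + 10^(scales$pKaCterm - pH))
  }
  q
}

#' Aliphatic index (Ikai)
#'
#' `100 * (fA * 1.0 + fV * 2.9 + (fI + fL) * 3.9)` over mole fractions;
#' non-canonical tokens use override weights (default 0).
#'
#' @param peptide serialized peptide string or token vector.
#' @param scales a [defaultScaleSet()].
#' @return the index (0 for peptides without A/V/I/L).
#' @examples
#' aliphaticIndex("AAAA")  # 100
#' @export
aliphaticIndex <- function(peptide, scales = defaultScaleSet()) {
  tokens <- .tokensOf(peptide)
  if (!length(tokens)) stop("peptide must be nonempty")
  w <- scales$aliphatic[tokens]
  w[is.na(w)] <- 0
  100 * sum(w) / length(tokens)
}

#' Physicochemical descriptor table
#'
#' Per peptide: GRAVY, net charge at `pH`, aliphatic index, length, and the
#' monomer-frequency vector over the union alphabet (canonical residues plus
#' any ncAA tokens present). Monomer frequencies realize the "sequence
#' composition" feature; they sum to 1 per peptide.
#'
#' @param peptides character vector of serialized peptide strings.
#' @param scales a [defaultScaleSet()].
#' @param pH pH for the charge descriptor.
#' @param includeTermini passed to [netCharge()].
#' @return data.frame with `peptide`, `gravy`, `charge`, `aliphatic`,
#'   `length`, and one `f_<token>` column per alphabet token.
#' @export
descriptorTable <- function(peptides, scales = defaultScaleSet(), pH = 7.4,
                            includeTermini = FALSE) {
  toks <- lapply(peptides, parsePeptide)
  alphabet <- sort(unique(c(CANONICAL_RESIDUES, unlist(toks))))
  comp <- t(vapply(toks, function(tk) {
    tabulate(factor(tk, levels = alphabet), nbins = length(alphabet)) /
      length(tk)
  }, numeric(length(alphabet))))
  colnames(comp) <- paste0("f_", alphabet)
  # pad 1-token peptides so they are not re-parsed as serialized strings
  safe <- function(tk) if (length(tk) == 1L) formatPeptide(tk) else tk
  df <- data.frame(
    peptide = peptides,
    gravy = vapply(toks, function(tk) gravy(safe(tk), scales), numeric(1)),
    charge = vapply(toks, function(tk) {
      netCharge(safe(tk), pH = pH, scales = scales,
                includeTermini = includeTermini)
    }, numeric(1)),
    aliphatic = vapply(toks, function(tk) aliphaticIndex(safe(tk), scales),
                       numeric(1)),
    length = lengths(toks),
    stringsAsFactors = FALSE
  )
  cbind(df, comp)
}

# classic DBSCAN on a coordinate matrix (no installed package provides it)
.dbscan <- function(coords, eps, minPts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neigh) >= minPts
  labels <- rep(0L, n)  # 0 = unvisited; -1 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cl       # border point
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- union(queue, setdiff(neigh[[j]], j))
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Embed descriptor vectors in 2-D and density-cluster them
#'
#' Features are z-score standardized (zero-variance columns dropped and
#' recorded), embedded in 2-D by UMAP (default; deterministic given `seed`
#' and single-threaded optimization) or by principal-component projection
#' (`method = "pca"`, fully deterministic with no stochastic stage), then
#' clustered by DBSCAN on the embedded coordinates. All parameters used are
#' echoed into the result.
#'
#' @param descriptors a [descriptorTable()] (or any data.frame with a
#'   `peptide` column and numeric feature columns).
#' @param method `"umap"` or `"pca"`.
#' @param nNeighbors,minDist UMAP hyperparameters.
#' @param eps,minPts DBSCAN parameters on embedded coordinates (eps in embedded
#'   units; the default suits the coordinate scale of the UMAP backend).
#' @param seed RNG seed for the stochastic embedding stage.
#' @return list with `coords` (data.frame: `peptide`, `dim1`, `dim2`,
#'   `cluster`; cluster `-1` = noise), `droppedColumns`, `center`, `scale`
#'   and `params`.
#' @export
embedAndCluster <- function(descriptors, method = c("umap", "pca"),
                            nNeighbors = 15, minDist = 0.1,
                            eps = 1.5, minPts = 5, seed = 42L) {
  method <- match.arg(method)
  if (nrow(descriptors) < 5L) stop("need at least 5 peptides to embed")
  num <- descriptors[vapply(descriptors, is.numeric, logical(1))]
  bad <- !vapply(num, function(v) all(is.finite(v)), logical(1))
  if (any(bad)) {
    nf <- which(!is.finite(as.matrix(num)), arr.ind = TRUE)
    stop("non-finite feature value for peptide '",
         descriptors$peptide[nf[1, 1]], "'")
  }
  X <- as.matrix(num)
  sds <- apply(X, 2L, stats::sd)
  droppedCols <- colnames(X)[sds == 0]
  keep <- sds > 0
  degenerate <- !any(keep)
  if (degenerate) {
    # all features identical across peptides: embedding collapses to a point
    emb <- matrix(0, nrow = nrow(X), ncol = 2L)
    ctr <- colMeans(X); scl <- rep(1, ncol(X))
  } else {
    ctr <- colMeans(X[, keep, drop = FALSE])
    scl <- sds[keep]
    Z <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)
    if (method == "pca" || ncol(Z) < 2L) {
      pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
      emb <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
      if (ncol(emb) < 2L) emb <- cbind(emb, 0)
    } else {
      set.seed(seed)
      nn <- min(nNeighbors, nrow(Z) - 1L)
      emb <- uwot::umap(Z, n_neighbors = nn, min_dist = minDist,
                        n_threads = 1, n_sgd_threads = 1, verbose = FALSE)
    }
  }
  cluster <- if (degenerate) rep(1L, nrow(X)) else .dbscan(emb, eps, minPts)
  list(
    coords = data.frame(peptide = descriptors$peptide, dim1 = emb[, 1L],
                        dim2 = emb[, 2L], cluster = cluster,
                        stringsAsFactors = FALSE),
    droppedColumns = droppedCols,
    center = ctr, scale = scl,
    params = list(method = method, nNeighbors = nNeighbors, minDist = minDist,
                  eps = eps, minPts = minPts, seed = seed)
  )
}
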