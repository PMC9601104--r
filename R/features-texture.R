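# Texture-matrix feature families. All matrices are built in C++ over the
# 3D ROI (26-neighbourhood / 13 unique directions, distance 1) and the
# statistics are computed here. `disc` is the output of discretize():
# integer gray levels 1..n_bins inside the ROI, 0 outside. Each family
# function can rebuild its matrix from `disc` alone, or reuse a matrix
# precomputed by texture_matrices() (the extractor's fast path).

texture_eps <- 2.2e-16

# index structures shared by every GLCM evaluation with the same bin count
glcm_index <- local({
  cache <- new.env(parent = emptyenv())
  function(ng) {
    key <- as.character(ng)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- matrix(rep(seq_len(ng), ng), ng)
    j <- t(i)
    cache[[key]] <- list(
      i = i, j = j, d = i - j, absd = abs(i - j),
      sum_group = as.vector(i + j), diff_group = as.vector(abs(i - j)))
    cache[[key]]
  }
})

# build all texture matrices for one discretized ROI in one fused C++ pass
texture_matrices <- function(disc, alpha = 0) {
  .cpp_texture_neighbors(as.integer(disc$levels),
                         as.integer(dim(disc$levels)),
                         disc$n_bins, as.integer(alpha))
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence at distance 1 over the 13 unique 3D directions;
#' per-direction matrices are normalized and averaged, and the 24-feature
#' family is computed from the averaged matrix.
#'
#' @param disc output of [discretize()].
#' @param counts optional precomputed per-direction count array.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(disc, counts = NULL) {
  ng <- disc$n_bins
  if (is.null(counts))
    counts <- .cpp_glcm(as.integer(disc$levels),
                        as.integer(dim(disc$levels)), ng)
  dim(counts) <- c(ng * ng, 13)
  tot <- colSums(counts)
  keep <- which(tot > 0)
  if (length(keep) == 0) stop("no valid voxel pair for the GLCM")
  P <- matrix(counts[, keep, drop = FALSE] %*% (1 / tot[keep]), ng, ng) /
    length(keep)

  ix <- glcm_index(ng)
  i <- ix$i; j <- ix$j
  px <- rowSums(P)  # == colSums(P) by symmetry
  mu_x <- sum(i * P); mu_y <- mu_x
  var_x <- sum((i - mu_x)^2 * P)
  k_sum <- 2:(2 * ng)
  p_sum <- drop(rowsum(as.vector(P), ix$sum_group))
  k_diff <- 0:(ng - 1)
  p_diff <- drop(rowsum(as.vector(P), ix$diff_group))
  plog <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- plog(px)
  HXY <- plog(P)
  pxy <- outer(px, px)
  HXY1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0] + texture_eps))
  HXY2 <- plog(pxy)
  da <- sum(k_diff * p_diff)
  autoc <- sum(i * j * P)

  corr <- if (var_x > 0) (autoc - mu_x * mu_y) / var_x else 1
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  # MCC: square root of the second-largest eigenvalue of
  # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) px(k))
  nz <- px > 0
  mcc <- if (sum(nz) > 1) {
    Psub <- P[nz, nz, drop = FALSE]
    pxs <- px[nz]
    Q <- (Psub / pxs) %*% (t(Psub) / pxs)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) > 1) sqrt(max(0, ev[2])) else 1
  } else 1

  cpm <- i + j - mu_x - mu_y
  c(Autocorrelation = autoc,
    JointAverage = mu_x,
    ClusterProminence = sum(cpm^4 * P),
    ClusterShade = sum(cpm^3 * P),
    ClusterTendency = sum(cpm^2 * P),
    Contrast = sum(ix$d^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = plog(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + ix$d^2)),
    Idmn = sum(P / (1 + (ix$d / ng)^2)),
    Id = sum(P / (1 + ix$absd)),
    Idn = sum(P / (1 + ix$absd / ng)),
    InverseVariance = sum(P[ix$absd > 0] / ix$d[ix$absd > 0]^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = plog(p_sum),
    SumSquares = var_x,
    MCC = mcc)
}

# shared statistics for the run/zone/dependence families; P is the raw
# count matrix (gray level x size), np the ROI voxel count
size_matrix_features <- function(P, np, prefix_names) {
  ns <- sum(P)
  if (ns == 0) stop("empty texture matrix")
  # trim to occupied rows/columns (values depend on indices, not shape)
  ri <- which(rowSums(P) > 0)
  ci <- which(colSums(P) > 0)
  Pt <- P[ri, ci, drop = FALSE]
  i <- matrix(ri, length(ri), length(ci))
  j <- matrix(ci, length(ri), length(ci), byrow = TRUE)
  p <- Pt / ns
  pg <- rowSums(Pt)  # per gray level
  ps <- colSums(Pt)  # per size
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pl <- p[p > 0]
  vals <- c(
    sum(pg^2) / ns,            # GrayLevelNonUniformity
    sum(pg^2) / ns^2,          # GrayLevelNonUniformityNormalized
    sum((i - mu_i)^2 * p),     # GrayLevelVariance
    sum(p * i^2),              # High gray level emphasis
    sum(p * j^2),              # Large size emphasis
    sum(p * i^2 * j^2),        # Large size + high gray
    sum(p * j^2 / i^2),        # Large size + low gray
    sum(p / i^2),              # Low gray level emphasis
    sum(ps^2) / ns,            # SizeNonUniformity
    sum(ps^2) / ns^2,          # SizeNonUniformityNormalized
    sum(p / j^2),              # Small size emphasis
    sum(p * i^2 / j^2),        # Small size + high gray
    sum(p / (i^2 * j^2)),      # Small size + low gray
    -sum(pl * log2(pl)),       # Entropy
    ns / np,                   # Percentage
    sum((j - mu_j)^2 * p))     # SizeVariance
  names(vals) <- prefix_names
  vals
}

#' Gray-level run-length matrix features
#'
#' Runs of equal gray level along each of the 13 unique directions; the 16
#' features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @param runs optional precomputed run-count array.
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(disc, runs = NULL) {
  ng <- disc$n_bins
  if (is.null(runs))
    runs <- .cpp_glrlm(as.integer(disc$levels),
                       as.integer(dim(disc$levels)), ng)
  maxrun <- length(runs) / (ng * 13)
  dim(runs) <- c(ng, maxrun, 13)
  np <- sum(disc$levels > 0)
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelRunEmphasis",
          "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
          "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
          "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
          "ShortRunLowGrayLevelEmphasis", "RunEntropy", "RunPercentage",
          "RunVariance")
  # all 13 directions at once: trim to occupied run lengths, then express
  # each feature as a weighted column sum of the (level x run) matrices
  used <- which(apply(runs, 2, sum) > 0)
  maxj <- if (length(used)) max(used) else 1
  R3 <- runs[, seq_len(maxj), , drop = FALSE]
  Pm <- matrix(R3, ng * maxj, 13)
  ns <- colSums(Pm)
  iv <- rep(seq_len(ng), maxj)
  jv <- rep(seq_len(maxj), each = ng)
  W <- cbind(i2 = iv^2, i2inv = 1 / iv^2, j2 = jv^2, j2inv = 1 / jv^2,
             i2j2 = iv^2 * jv^2, i2overj2 = iv^2 / jv^2,
             j2overi2 = jv^2 / iv^2, i2j2inv = 1 / (iv^2 * jv^2),
             i1 = iv, j1 = jv)
  S <- crossprod(W, Pm)              # weighted sums per direction
  pg <- rowsum(Pm, iv)               # per gray level, per direction
  ps <- rowsum(Pm, jv)               # per run length, per direction
  mu_i <- S["i1", ] / ns
  mu_j <- S["j1", ] / ns
  ent <- rv <- glv <- numeric(13)
  for (k in 1:13) {
    p <- Pm[, k][Pm[, k] > 0] / ns[k]
    ent[k] <- -sum(p * log2(p))
  }
  glv <- S["i2", ] / ns - mu_i^2
  rv <- S["j2", ] / ns - mu_j^2
  acc <- cbind(
    GrayLevelNonUniformity = colSums(pg^2) / ns,
    GrayLevelNonUniformityNormalized = colSums(pg^2) / ns^2,
    GrayLevelVariance = glv,
    HighGrayLevelRunEmphasis = S["i2", ] / ns,
    LongRunEmphasis = S["j2", ] / ns,
    LongRunHighGrayLevelEmphasis = S["i2j2", ] / ns,
    LongRunLowGrayLevelEmphasis = S["j2overi2", ] / ns,
    LowGrayLevelRunEmphasis = S["i2inv", ] / ns,
    RunLengthNonUniformity = colSums(ps^2) / ns,
    RunLengthNonUniformityNormalized = colSums(ps^2) / ns^2,
    ShortRunEmphasis = S["j2inv", ] / ns,
    ShortRunHighGrayLevelEmphasis = S["i2overj2", ] / ns,
    ShortRunLowGrayLevelEmphasis = S["i2j2inv", ] / ns,
    RunEntropy = ent,
    RunPercentage = ns / np,
    RunVariance = rv)
  out <- colMeans(acc)
  # canonical presentation order
  out[c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
        "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
        "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
        "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
        "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
        "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
        "ShortRunLowGrayLevelEmphasis")]
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level; 16 features from
#' the single zone matrix.
#'
#' @inheritParams glcm_features
#' @param zones optional precomputed (level, size) zone table.
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(disc, zones = NULL) {
  ng <- disc$n_bins
  if (is.null(zones))
    zones <- .cpp_glszm(as.integer(disc$levels),
                        as.integer(dim(disc$levels)), ng)
  np <- sum(disc$levels > 0)
  maxsize <- max(zones[, 2])
  P <- matrix(0, ng, maxsize)
  for (r in seq_len(nrow(zones)))
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
          "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
          "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
          "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
          "ZoneVariance")
  size_matrix_features(P, np, nm)
}

#' Neighbouring gray-tone difference matrix features
#'
#' 26-neighbourhood mean-difference statistics: Busyness, Coarseness,
#' Complexity, Contrast, Strength.
#'
#' @inheritParams glcm_features
#' @param M optional precomputed (n_i, s_i) table.
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(disc, M = NULL) {
  ng <- disc$n_bins
  if (is.null(M))
    M <- .cpp_ngtdm(as.integer(disc$levels), as.integer(dim(disc$levels)),
                    ng)
  nvp <- sum(M[, 1])
  if (nvp == 0) stop("NGTDM: no voxel with a valid neighbour")
  act <- which(M[, 1] > 0)
  p <- M[act, 1] / nvp
  s <- M[act, 2]
  iv <- act  # gray-level values of the active rows
  ngp <- length(act)
  ii <- matrix(iv, ngp, ngp)
  jj <- t(ii)
  pi_m <- matrix(p, ngp, ngp)
  pj_m <- t(pi_m)
  d2 <- (ii - jj)^2
  si_m <- matrix(p * s, ngp, ngp)
  pij_d2 <- sum(pi_m * pj_m * d2)
  busy_den <- sum(abs(ii * pi_m - jj * pj_m))
  strength_num <- sum((pi_m + pj_m) * d2)
  complexity <- sum(abs(ii - jj) * (si_m + t(si_m)) / (pi_m + pj_m))
  coars_den <- sum(p * s)
  c(Busyness = if (ngp > 1 && busy_den > 0) sum(p * s) / busy_den else 0,
    Coarseness = if (coars_den > 0) min(1 / coars_den, 1e6) else 1e6,
    Complexity = complexity / nvp,
    Contrast = if (ngp > 1) pij_d2 / (ngp * (ngp - 1)) * sum(s) / nvp else 0,
    Strength = if (sum(s) > 0) strength_num / sum(s) else 0)
}

#' Gray-level dependence matrix features
#'
#' A neighbour is dependent when its gray-level difference from the centre
#' is at most `alpha` (default 0); the dependence size of a voxel is the
#' dependent-neighbour count plus one (the centre). 14 features.
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance in gray levels.
#' @param M optional precomputed dependence matrix.
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(disc, alpha = 0, M = NULL) {
  ng <- disc$n_bins
  if (is.null(M))
    M <- .cpp_gldm(as.integer(disc$levels), as.integer(dim(disc$levels)),
                   ng, as.integer(alpha))
  dim(M) <- c(ng, 27)
  # column c holds voxels with c - 1 dependent neighbours, i.e. dependence
  # size c (centre included)
  np <- sum(M)
  nm16 <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelEmphasis",
            "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
            "DependenceNonUniformity", "DependenceNonUniformityNormalized",
            "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
            "SmallDependenceLowGrayLevelEmphasis", "DependenceEntropy",
            "DependencePercentage", "DependenceVariance")
  vals <- size_matrix_features(M, np, nm16)
  # the dependence family has 14 features: the percentage is identically 1
  # (every ROI voxel has a dependence size) and the normalized gray-level
  # non-uniformity is not part of the canonical set
  vals <- vals[setdiff(nm16, c("DependencePercentage",
                               "GrayLevelNonUniformityNormalized"))]
  vals[c("DependenceEntropy", "DependenceNonUniformity",
         "DependenceNonUniformityNormalized", "DependenceVariance",
         "GrayLevelNonUniformity", "GrayLevelVariance",
         "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
         "LargeDependenceHighGrayLevelEmphasis",
         "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
         "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
         "SmallDependenceLowGrayLevelEmphasis")]
}
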