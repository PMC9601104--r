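# Fixtures and independent oracles. Every oracle here is written against
# the definitions directly (plain-R enumeration or an established package)
# and never calls the implementation path it checks.

sphere_mask <- function(radius, spacing = 0.5, pad = 4L) {
  n <- as.integer(2 * ceiling(radius) + 2 * pad + 1)
  c0 <- (n + 1) / 2
  ax <- seq_len(n)
  q <- outer(outer((ax - c0)^2, (ax - c0)^2, `+`), (ax - c0)^2, `+`)
  binary_mask(q <= radius^2, rep(spacing, 3))
}

random_blob <- function(seed, n = 24L, spacing = 0.5, sigma = 2.5,
                        q = 0.85) {
  set.seed(seed)
  f <- radrobust:::gaussian_smooth(array(rnorm(n^3), rep(n, 3L)), sigma)
  vox <- f >= quantile(f, q)
  vox <- radrobust:::largest_component(vox, 6)
  binary_mask(vox, rep(spacing, 3))
}

random_levels <- function(seed, dims = c(5, 5, 5), n_bins = 4,
                          roi_frac = 0.7) {
  set.seed(seed)
  lev <- array(0L, dims)
  inside <- array(runif(prod(dims)) < roi_frac, dims)
  lev[inside] <- sample.int(n_bins, sum(inside), replace = TRUE)
  list(levels = lev, n_bins = as.integer(n_bins))
}

# all 26 neighbour offsets and the canonical 13-direction half
dirs26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
dirs26 <- dirs26[rowSums(abs(dirs26)) > 0, ]
dirs13 <- dirs26[dirs26[, 1] > 0 |
                   (dirs26[, 1] == 0 & dirs26[, 2] > 0) |
                   (dirs26[, 1] == 0 & dirs26[, 2] == 0 & dirs26[, 3] > 0), ]

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# brute-force symmetric GLCM counts per direction (array ng x ng x 13)
oracle_glcm_counts <- function(disc) {
  d <- dim(disc$levels)
  ng <- disc$n_bins
  out <- array(0, c(ng, ng, nrow(dirs13)))
  co <- which(disc$levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    a <- disc$levels[co[r, , drop = FALSE]]
    for (k in seq_len(nrow(dirs13))) {
      p2 <- co[r, ] + dirs13[k, ]
      if (!in_grid(p2, d)) next
      b <- disc$levels[matrix(p2, 1)]
      if (b == 0) next
      out[a, b, k] <- out[a, b, k] + 1
      out[b, a, k] <- out[b, a, k] + 1
    }
  }
  out
}

# brute-force run-length counts per direction (ng x maxlen x 13)
oracle_glrlm_counts <- function(disc) {
  d <- dim(disc$levels)
  ng <- disc$n_bins
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, nrow(dirs13)))
  co <- which(disc$levels > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(dirs13))) {
    v <- dirs13[k, ]
    for (r in seq_len(nrow(co))) {
      p <- co[r, ]
      a <- disc$levels[matrix(p, 1)]
      prev <- p - v
      if (in_grid(prev, d) && disc$levels[matrix(prev, 1)] == a) next
      len <- 1
      nxt <- p + v
      while (in_grid(nxt, d) && disc$levels[matrix(nxt, 1)] == a) {
        len <- len + 1
        nxt <- nxt + v
      }
      out[a, len, k] <- out[a, len, k] + 1
    }
  }
  out
}

# brute-force zones: BFS over 26-connected equal-level voxels
oracle_glszm_zones <- function(disc) {
  d <- dim(disc$levels)
  seen <- array(FALSE, d)
  zones <- NULL
  co <- which(disc$levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    p0 <- co[r, ]
    if (seen[matrix(p0, 1)]) next
    a <- disc$levels[matrix(p0, 1)]
    queue <- list(p0)
    seen[matrix(p0, 1)] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(dirs26))) {
        q <- p + dirs26[k, ]
        if (!in_grid(q, d)) next
        if (!seen[matrix(q, 1)] && disc$levels[matrix(q, 1)] == a) {
          seen[matrix(q, 1)] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones
}

# brute-force GLDM (ng x 27) and NGTDM (ng x 2) tables
oracle_gldm <- function(disc, alpha = 0) {
  d <- dim(disc$levels)
  ng <- disc$n_bins
  out <- matrix(0, ng, 27)
  co <- which(disc$levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    a <- disc$levels[co[r, , drop = FALSE]]
    dep <- 0
    for (k in seq_len(nrow(dirs26))) {
      q <- co[r, ] + dirs26[k, ]
      if (!in_grid(q, d)) next
      b <- disc$levels[matrix(q, 1)]
      if (b > 0 && abs(a - b) <= alpha) dep <- dep + 1
    }
    out[a, dep + 1] <- out[a, dep + 1] + 1
  }
  out
}

oracle_ngtdm <- function(disc) {
  d <- dim(disc$levels)
  ng <- disc$n_bins
  out <- matrix(0, ng, 2)
  co <- which(disc$levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    a <- disc$levels[co[r, , drop = FALSE]]
    nb <- c()
    for (k in seq_len(nrow(dirs26))) {
      q <- co[r, ] + dirs26[k, ]
      if (!in_grid(q, d)) next
      b <- disc$levels[matrix(q, 1)]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb)) {
      out[a, 1] <- out[a, 1] + 1
      out[a, 2] <- out[a, 2] + abs(a - mean(nb))
    }
  }
  out
}

# independent greedy mRMR (F via lm anova, Pearson via cor)
oracle_mrmr <- function(X, y, k) {
  f <- apply(X, 2, function(v) anova(lm(v ~ factor(y)))[["F value"]][1])
  sel <- integer(0)
  for (step in seq_len(k)) {
    if (step == 1) {
      score <- f
    } else {
      red <- sapply(seq_len(ncol(X)), function(j)
        max(mean(abs(cor(X[, j], X[, sel]))), 1e-6))
      score <- f / red
    }
    score[sel] <- -Inf
    sel <- c(sel, which.max(score))
  }
  colnames(X)[sel]
}

# trapezoidal ROC AUC oracle
oracle_auc <- function(scores, labels, positive = "LF") {
  th <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == positive
  tpr <- c(0, sapply(th, function(t) mean(scores[pos] >= t)), 1)
  fpr <- c(0, sapply(th, function(t) mean(scores[!pos] >= t)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small imaging study built directly (no cohort machinery)
toy_study <- function(seed = 1, n = 28L, radius = 4.5, contrast = 0.7,
                      noise = 0.03) {
  set.seed(seed)
  c0 <- (n + 1) / 2
  ax <- seq_len(n)
  q <- outer(outer((ax - c0)^2, (ax - c0)^2, `+`), (ax - c0)^2, `+`)
  mask <- q <= radius^2
  mk <- function(amp) {
    bg <- radrobust:::gaussian_smooth(array(rnorm(n^3), rep(n, 3L)), 4)
    v <- 0.25 + 0.04 * bg / sd(bg)
    v[mask] <- v[mask] + amp
    v + rnorm(n^3, sd = noise)
  }
  structure(list(patient_id = "T01", timepoint = "BL",
                 lesion_ids = "T01_L1",
                 channel_T1 = mk(contrast), channel_T2FLAIR = mk(contrast / 2),
                 gt_masks = list(T01_L1 = binary_mask(mask, rep(0.5, 3))),
                 spacing_mm = rep(0.5, 3)),
            class = "imaging_study")
}

# memoized small shared cohort for module tests
shared_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$cohort))
      env$cohort <- generate_cohort(cohort_config(
        n_train_patients = 6L, n_val_patients = 2L, n_test_patients = 4L,
        seed = 42L))
    env$cohort
  }
})
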