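# Independent oracles, written directly from the rule definitions and kept
# deliberately naive. They never call the package's scoring internals.

# -- scar-score oracles -------------------------------------------------------

# merge adjacent equal-state segments of one sample, the slow way
oracle_merge <- function(seg) {
  seg <- seg[order(match(seg$chrom, unique(seg$chrom)), seg$start), ]
  out <- seg[0, ]
  for (i in seq_len(nrow(seg))) {
    n <- nrow(out)
    if (n > 0 && out$chrom[n] == seg$chrom[i] &&
        out$end[n] == seg$start[i] &&
        out$major_cn[n] == seg$major_cn[i] &&
        out$minor_cn[n] == seg$minor_cn[i]) {
      out$end[n] <- seg$end[i]
    } else {
      out <- rbind(out, seg[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

oracle_loh <- function(profile, genome, min_len = 15e6) {
  seg <- oracle_merge(as.data.frame(profile))
  count <- 0L
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    chrlen <- genome$length[genome$chrom == seg$chrom[i]]
    if (seg$minor_cn[i] == 0 && seg$major_cn[i] > 0 &&
        len > min_len && len < chrlen) {
      count <- count + 1L
    }
  }
  count
}

oracle_tai <- function(profile, genome, min_len = 11e6) {
  seg <- oracle_merge(as.data.frame(profile))
  count <- 0L
  for (i in seq_len(nrow(seg))) {
    g <- genome[genome$chrom == seg$chrom[i], ]
    len <- seg$end[i] - seg$start[i]
    touches <- seg$start[i] == 0 || seg$end[i] == g$length
    overlaps_cen <- seg$start[i] < g$centromere_end &&
      seg$end[i] > g$centromere_start
    if (seg$major_cn[i] != seg$minor_cn[i] && len >= min_len &&
        touches && !overlaps_cen) {
      count <- count + 1L
    }
  }
  count
}

# replays the smoothing by hand: repeatedly drop the shortest sub-threshold
# segment (leftmost on ties), give its span to the longer neighbor (left on
# ties), re-merge, then count qualifying breakpoints
oracle_lst <- function(profile, genome, min_flank = 10e6, smooth_len = 3e6) {
  seg <- oracle_merge(as.data.frame(profile))
  count <- 0L
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, ]
    s <- s[order(s$start), ]
    repeat {
      if (nrow(s) <= 1) break
      lens <- s$end - s$start
      short <- which(lens < smooth_len)
      if (length(short) == 0) break
      i <- short[which.min(lens[short])]
      if (i == 1) j <- 2
      else if (i == nrow(s)) j <- nrow(s) - 1
      else j <- if (lens[i - 1] >= lens[i + 1]) i - 1 else i + 1
      s$start[j] <- min(s$start[j], s$start[i])
      s$end[j] <- max(s$end[j], s$end[i])
      s <- s[-i, ]
      s <- oracle_merge(s)
    }
    g <- genome[genome$chrom == chrom, ]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1)) {
      bp <- s$end[i]
      in_cen <- bp >= g$centromere_start && bp <= g$centromere_end
      if (!in_cen &&
          (s$end[i] - s$start[i]) >= min_flank &&
          (s$end[i + 1] - s$start[i + 1]) >= min_flank) {
        count <- count + 1L
      }
    }
  }
  count
}

# random tilings with arbitrary (possibly interacting) copy-number states
random_profile <- function(genome, seed, sample_id = "rnd") {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(genome)), function(ci) {
      len <- genome$length[ci]
      nbp <- sample(0:10, 1)
      bps <- sort(unique(round(runif(nbp, 1, len - 1))))
      starts <- c(0, bps)
      ends <- c(bps, len)
      major <- sample(0:3, length(starts), replace = TRUE)
      minor <- vapply(major, function(m) sample(0:m, 1), 0L)
      data.frame(chrom = genome$chrom[ci], start = starts, end = ends,
                 major_cn = major, minor_cn = minor,
                 stringsAsFactors = FALSE)
    })
    segment_profile(sample_id, do.call(rbind, rows), genome)
  })
}

# -- GSEA oracle --------------------------------------------------------------

# literal running-sum evaluation from the formula: per-position increments
# are assembled in an explicit loop, accumulated, and the signed maximum
# deviation picked with a strict comparison
oracle_es <- function(stats_sorted, genes_sorted, set_genes, weight_p = 1) {
  n <- length(stats_sorted)
  hit <- genes_sorted %in% set_genes
  nh <- sum(hit)
  if (nh == n) return(1)
  denom_hit <- sum(abs(stats_sorted[hit])^weight_p)
  inc <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) {
      inc[i] <- if (denom_hit > 0) {
        abs(stats_sorted[i])^weight_p / denom_hit
      } else {
        1 / nh
      }
    } else {
      inc[i] <- -1 / (n - nh)
    }
  }
  run <- cumsum(inc)
  best <- 0
  for (i in seq_len(n)) {
    if (abs(run[i]) > abs(best)) best <- run[i]
  }
  best
}

# -- signature-refit oracle ---------------------------------------------------

# projected-gradient least squares on the probability simplex
oracle_simplex_lsq <- function(tumor, P, n_iter = 5000) {
  K <- ncol(P)
  w <- rep(1 / K, K)
  L <- max(eigen(crossprod(P), only.values = TRUE)$values)
  for (i in seq_len(n_iter)) {
    grad <- as.numeric(crossprod(P, P %*% w - tumor))
    w <- project_simplex(w - grad / L)
  }
  w
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# -- Cox partial-likelihood oracle -------------------------------------------

# Newton-Raphson on the Efron-tied log partial likelihood, from the formula
oracle_cox_efron <- function(time, event, x, n_iter = 50) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  utimes <- sort(unique(time[event == 1]))
  for (it in seq_len(n_iter)) {
    U <- rep(0, p)
    I <- matrix(0, p, p)
    eta <- as.numeric(x %*% beta)
    w <- exp(eta)
    for (t in utimes) {
      D <- which(time == t & event == 1)
      R <- which(time >= t)
      d <- length(D)
      s0R <- sum(w[R]); s1R <- colSums(w[R] * x[R, , drop = FALSE])
      s2R <- crossprod(sqrt(w[R]) * x[R, , drop = FALSE])
      s0D <- sum(w[D]); s1D <- colSums(w[D] * x[D, , drop = FALSE])
      s2D <- crossprod(sqrt(w[D]) * x[D, , drop = FALSE])
      U <- U + colSums(x[D, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        s0 <- s0R - l / d * s0D
        s1 <- s1R - l / d * s1D
        s2 <- s2R - l / d * s2D
        U <- U - s1 / s0
        I <- I + s2 / s0 - tcrossprod(s1 / s0)
      }
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}
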