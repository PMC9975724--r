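# Independent brute-force oracles: explicit pair/run/zone enumeration and
# plain-loop feature formulas, kept free of the package's vectorized /
# compiled code paths.

oracleAngles <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

oLog2 <- function(p) if (p > 0) log2(p) else 0

# ---- GLCM ------------------------------------------------------------------

oracleGlcmCounts <- function(lev, ng, dr, dc) {
  out <- matrix(0, ng, ng)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- lev[r, c]; j <- lev[r2, c2]
      out[i, j] <- out[i, j] + 1
      out[j, i] <- out[j, i] + 1
    }
  }
  out
}

oracleGlcmOneAngle <- function(counts, ng) {
  p <- counts / sum(counts)
  px <- rowSums(p)
  ux <- 0
  for (i in 1:ng) ux <- ux + i * px[i]
  varx <- 0
  for (i in 1:ng) varx <- varx + (i - ux)^2 * px[i]
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = da, DifferenceEntropy = 0,
         DifferenceVariance = 0, Id = 0, Idm = 0, Idmn = 0, Idn = 0,
         Imc1 = 0, Imc2 = 0, InverseVariance = 0, JointAverage = ux,
         JointEnergy = 0, JointEntropy = 0, MCC = 0, MaximumProbability = 0,
         SumEntropy = 0, SumSquares = 0)
  hx <- 0
  for (i in 1:ng) hx <- hx - px[i] * oLog2(px[i])
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * v
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - 2 * ux)^4 * v
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - 2 * ux)^3 * v
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - 2 * ux)^2 * v
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * v
    f["Id"] <- f["Id"] + v / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + v / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + v / (1 + ((i - j) / ng)^2)
    f["Idn"] <- f["Idn"] + v / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] +
      v / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + v^2
    hxy <- hxy - v * oLog2(v)
    hxy1 <- hxy1 - v * oLog2(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * oLog2(px[i] * px[j])
  }
  f["JointEntropy"] <- hxy
  f["Correlation"] <- if (varx > 0) (f[["Autocorrelation"]] - ux^2) / varx
  else 1
  for (k in 0:(ng - 1)) {
    f["DifferenceEntropy"] <- f["DifferenceEntropy"] -
      pd[k + 1] * oLog2(pd[k + 1])
    f["DifferenceVariance"] <- f["DifferenceVariance"] +
      (k - da)^2 * pd[k + 1]
  }
  for (k in seq_along(ps)) f["SumEntropy"] <- f["SumEntropy"] -
    ps[k] * oLog2(ps[k])
  f["Imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  f["MaximumProbability"] <- max(p)
  f["SumSquares"] <- varx
  keep <- which(px > 0)
  f["MCC"] <- if (length(keep) < 2) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in seq_along(keep))
        s <- s + p[keep[a], keep[k]] * p[keep[b], keep[k]] /
          (px[keep[a]] * px[keep[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  f
}

oracleGlcmFeatures <- function(lev, ng) {
  per <- sapply(oracleAngles, function(o)
    oracleGlcmOneAngle(oracleGlcmCounts(lev, ng, o[1], o[2]), ng))
  rowMeans(per)
}

# ---- GLRLM -----------------------------------------------------------------

oracleGlrlmCounts <- function(lev, ng, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  out <- matrix(0, ng, max(nr, nc))
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (inb(r - dr, c - dc)) next  # not a line start
    rr <- r; cc <- c
    cur <- lev[rr, cc]; len <- 0
    while (inb(rr, cc)) {
      if (lev[rr, cc] == cur) len <- len + 1
      else {
        out[cur, len] <- out[cur, len] + 1
        cur <- lev[rr, cc]; len <- 1
      }
      rr <- rr + dr; cc <- cc + dc
    }
    out[cur, len] <- out[cur, len] + 1
  }
  out
}

oracleRlmOneAngle <- function(P, ng, np) {
  nr <- sum(P)
  L <- ncol(P)
  f <- setNames(numeric(16),
                c("ShortRunEmphasis", "LongRunEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                  "RunPercentage", "GrayLevelVariance", "RunVariance",
                  "RunEntropy", "LowGrayLevelRunEmphasis",
                  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                  "ShortRunHighGrayLevelEmphasis",
                  "LongRunLowGrayLevelEmphasis",
                  "LongRunHighGrayLevelEmphasis"))
  mu_i <- 0; mu_l <- 0
  for (i in 1:ng) for (l in 1:L) {
    mu_i <- mu_i + i * P[i, l] / nr
    mu_l <- mu_l + l * P[i, l] / nr
  }
  for (i in 1:ng) for (l in 1:L) {
    v <- P[i, l]
    f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] + v / l^2
    f["LongRunEmphasis"] <- f["LongRunEmphasis"] + v * l^2
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] +
      (i - mu_i)^2 * v / nr
    f["RunVariance"] <- f["RunVariance"] + (l - mu_l)^2 * v / nr
    f["RunEntropy"] <- f["RunEntropy"] - (v / nr) * oLog2(v / nr)
    f["LowGrayLevelRunEmphasis"] <- f["LowGrayLevelRunEmphasis"] + v / i^2
    f["HighGrayLevelRunEmphasis"] <- f["HighGrayLevelRunEmphasis"] +
      v * i^2
    f["ShortRunLowGrayLevelEmphasis"] <-
      f["ShortRunLowGrayLevelEmphasis"] + v / (i^2 * l^2)
    f["ShortRunHighGrayLevelEmphasis"] <-
      f["ShortRunHighGrayLevelEmphasis"] + v * i^2 / l^2
    f["LongRunLowGrayLevelEmphasis"] <-
      f["LongRunLowGrayLevelEmphasis"] + v * l^2 / i^2
    f["LongRunHighGrayLevelEmphasis"] <-
      f["LongRunHighGrayLevelEmphasis"] + v * i^2 * l^2
  }
  for (i in 1:ng) f["GrayLevelNonUniformity"] <-
    f["GrayLevelNonUniformity"] + sum(P[i, ])^2
  for (l in 1:L) f["RunLengthNonUniformity"] <-
    f["RunLengthNonUniformity"] + sum(P[, l])^2
  f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] / nr
  f["LongRunEmphasis"] <- f["LongRunEmphasis"] / nr
  f["GrayLevelNonUniformityNormalized"] <-
    f["GrayLevelNonUniformity"] / nr^2
  f["GrayLevelNonUniformity"] <- f["GrayLevelNonUniformity"] / nr
  f["RunLengthNonUniformityNormalized"] <-
    f["RunLengthNonUniformity"] / nr^2
  f["RunLengthNonUniformity"] <- f["RunLengthNonUniformity"] / nr
  f["RunPercentage"] <- nr / np
  for (nm in c("LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
               "ShortRunLowGrayLevelEmphasis",
               "ShortRunHighGrayLevelEmphasis",
               "LongRunLowGrayLevelEmphasis",
               "LongRunHighGrayLevelEmphasis"))
    f[nm] <- f[nm] / nr
  f
}

oracleGlrlmFeatures <- function(lev, ng) {
  per <- sapply(oracleAngles, function(o)
    oracleRlmOneAngle(oracleGlrlmCounts(lev, ng, o[1], o[2]), ng,
                      length(lev)))
  rowMeans(per)
}

# ---- GLSZM -----------------------------------------------------------------

oracleZones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    v <- lev[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- cur[1] + dr; c <- cur[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            !seen[r, c] && lev[r, c] == v) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = v, size = size)
  }
  do.call(rbind, zones)
}

oracleGlszmFeatures <- function(lev, ng) {
  z <- oracleZones(lev)
  np <- length(lev)
  nz <- nrow(z)
  i <- z[, "level"]; s <- z[, "size"]
  gln <- 0
  for (g in unique(i)) gln <- gln + sum(i == g)^2
  szn <- 0
  for (sz in unique(s)) szn <- szn + sum(s == sz)^2
  ze <- 0
  for (g in unique(i)) for (sz in unique(s)) {
    pc <- sum(i == g & s == sz) / nz
    ze <- ze - pc * oLog2(pc)
  }
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = gln / nz,
    GrayLevelNonUniformityNormalized = gln / nz^2,
    SizeZoneNonUniformity = szn / nz,
    SizeZoneNonUniformityNormalized = szn / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((i - mean(i))^2),
    ZoneVariance = mean((s - mean(s))^2),
    ZoneEntropy = ze,
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

# ---- GLDM ------------------------------------------------------------------

oracleGldmFeatures <- function(lev, ng, alpha = 0) {
  nr <- nrow(lev); nc <- ncol(lev)
  P <- matrix(0, ng, 9)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dep <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          abs(lev[r2, c2] - lev[r, c]) <= alpha)
        dep <- dep + 1
    }
    P[lev[r, c], dep] <- P[lev[r, c], dep] + 1
  }
  nz <- sum(P)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:9) {
    mu_i <- mu_i + i * P[i, j] / nz
    mu_j <- mu_j + j * P[i, j] / nz
  }
  f <- setNames(numeric(14),
                c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                  "GrayLevelNonUniformity", "DependenceNonUniformity",
                  "DependenceNonUniformityNormalized", "GrayLevelVariance",
                  "DependenceVariance", "DependenceEntropy",
                  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                  "SmallDependenceLowGrayLevelEmphasis",
                  "SmallDependenceHighGrayLevelEmphasis",
                  "LargeDependenceLowGrayLevelEmphasis",
                  "LargeDependenceHighGrayLevelEmphasis"))
  for (i in 1:ng) for (j in 1:9) {
    v <- P[i, j]
    f["SmallDependenceEmphasis"] <- f["SmallDependenceEmphasis"] + v / j^2
    f["LargeDependenceEmphasis"] <- f["LargeDependenceEmphasis"] + v * j^2
    f["GrayLevelVariance"] <- f["GrayLevelVariance"] +
      (i - mu_i)^2 * v / nz
    f["DependenceVariance"] <- f["DependenceVariance"] +
      (j - mu_j)^2 * v / nz
    f["DependenceEntropy"] <- f["DependenceEntropy"] -
      (v / nz) * oLog2(v / nz)
    f["LowGrayLevelEmphasis"] <- f["LowGrayLevelEmphasis"] + v / i^2
    f["HighGrayLevelEmphasis"] <- f["HighGrayLevelEmphasis"] + v * i^2
    f["SmallDependenceLowGrayLevelEmphasis"] <-
      f["SmallDependenceLowGrayLevelEmphasis"] + v / (i^2 * j^2)
    f["SmallDependenceHighGrayLevelEmphasis"] <-
      f["SmallDependenceHighGrayLevelEmphasis"] + v * i^2 / j^2
    f["LargeDependenceLowGrayLevelEmphasis"] <-
      f["LargeDependenceLowGrayLevelEmphasis"] + v * j^2 / i^2
    f["LargeDependenceHighGrayLevelEmphasis"] <-
      f["LargeDependenceHighGrayLevelEmphasis"] + v * i^2 * j^2
  }
  for (i in 1:ng) f["GrayLevelNonUniformity"] <-
    f["GrayLevelNonUniformity"] + sum(P[i, ])^2
  for (j in 1:9) f["DependenceNonUniformity"] <-
    f["DependenceNonUniformity"] + sum(P[, j])^2
  f["DependenceNonUniformityNormalized"] <-
    f["DependenceNonUniformity"] / nz^2
  for (nm in c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
               "GrayLevelNonUniformity", "DependenceNonUniformity",
               "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
               "SmallDependenceLowGrayLevelEmphasis",
               "SmallDependenceHighGrayLevelEmphasis",
               "LargeDependenceLowGrayLevelEmphasis",
               "LargeDependenceHighGrayLevelEmphasis"))
    f[nm] <- f[nm] / nz
  f
}

# ---- NGTDM -----------------------------------------------------------------

oracleNgtdmFeatures <- function(lev, ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        nb <- c(nb, lev[r2, c2])
    }
    v <- lev[r, c]
    n_i[v] <- n_i[v] + 1
    if (length(nb)) s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  N <- sum(n_i)
  p <- n_i / N
  pres <- which(p > 0)
  ngp <- length(pres)
  psSum <- sum(p[pres] * s_i[pres])
  contrast <- 0; busyD <- 0; complexity <- 0; strengthN <- 0
  for (i in pres) for (j in pres) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busyD <- busyD + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) *
      (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
    strengthN <- strengthN + (p[i] + p[j]) * (i - j)^2
  }
  c(Coarseness = if (psSum > 0) min(1 / psSum, 1e6) else 1e6,
    Contrast = if (ngp > 1) contrast / (ngp * (ngp - 1)) *
      sum(s_i[pres]) / N else 0,
    Busyness = if (busyD > 0) psSum / busyD else 0,
    Complexity = if (ngp > 1) complexity / N else 0,
    Strength = if (sum(s_i[pres]) > 0) strengthN / sum(s_i[pres]) else 0)
}

# ---- other oracles ---------------------------------------------------------

# brute-force valid-center enumeration by counting patch pixels directly
oracleValidCenters <- function(labels, roiLabel, side, minFrac) {
  nr <- nrow(labels); nc <- ncol(labels)
  h <- (side - 1) %/% 2
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r - h < 1 || r + h > nr || c - h < 1 || c + h > nc) next
    win <- labels[(r - h):(r + h), (c - h):(c + h)]
    if (mean(win == roiLabel) >= minFrac - 1e-12)
      out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# exhaustive OCP sweep over every candidate threshold
oracleOcp <- function(x, y) {
  u <- sort(unique(x))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                        u[length(u)] + 1)))
  best <- -Inf; bestT <- NA
  for (t in cand) {
    acc <- (sum(x >= t & y) + sum(x < t & !y)) / length(x)
    if (acc > best + 1e-15) {
      best <- acc; bestT <- t
    }
  }
  list(ocp = bestT, accuracy = best)
}

# plug-in mutual information from an explicit joint table
oracleMi <- function(a, b) {
  av <- sort(unique(a)); bv <- sort(unique(b))
  n <- length(a)
  mi <- 0
  for (x in av) for (y in bv) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  mi
}
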