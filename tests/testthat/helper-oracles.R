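# Independent oracles used to freeze expected values. These deliberately
# use different algorithms (brute-force loops, quadrature, closed forms)
# from the package implementations they check.

# strain of the piecewise stiffening model by adaptive numerical
# quadrature of the compliance 1/K'(sigma), split at the breakpoints
oracle_strain <- function(sigma, K0, s0, m, sR, post_frac = 0.01) {
  kprime <- function(s) {
    ifelse(s <= s0, K0,
           ifelse(s <= sR, K0 * (s / s0)^m, post_frac * K0 * (sR / s0)^m))
  }
  one <- function(s) {
    cuts <- sort(unique(c(0, s0, sR, s)))
    cuts <- cuts[cuts <= s]
    total <- 0
    for (j in seq_len(length(cuts) - 1)) {
      total <- total + stats::integrate(function(x) 1 / kprime(x),
                                        cuts[j], cuts[j + 1],
                                        rel.tol = 1e-10)$value
    }
    total
  }
  vapply(sigma, one, numeric(1))
}

# 4-connected components of a logical mask by explicit stack flood fill
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
          q <- (d[2] - 1L) * nr + d[1]
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
        }
      }
    }
  }
  lab
}

# pore statistics from the flood-fill labeling (border components excluded)
oracle_pores <- function(mask) {
  bg <- !mask
  lab <- oracle_flood_fill(bg)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border != 0]
  sizes <- tabulate(lab[lab != 0])
  enclosed <- setdiff(which(sizes > 0), border)
  list(porosity = sum(bg) / length(bg),
       n_pores = length(enclosed),
       mean_pore_area = if (length(enclosed)) mean(sizes[enclosed]) else NA)
}

# per-pixel loop count of skeleton branch points (>= 3 8-neighbors)
oracle_branch_points <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc])
        cnt <- cnt + 1L
    }
    if (cnt >= 3L) out[r, c] <- TRUE
  }
  out
}

# brute-force single-linkage cluster count by repeated merging
oracle_merge_count <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] &&
          sum((pts[i, ] - pts[j, ])^2) <= radius^2) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(grp))
}

# Spearman by hand: midranks then the Pearson product-moment formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# R^2 of an OLS fit of sigma on gamma for every prefix window, via lm()
oracle_prefix_r2 <- function(sigma, gamma) {
  n <- length(sigma)
  vapply(3:n, function(w) {
    f <- lm(sigma[1:w] ~ gamma[1:w])
    summary(f)$r.squared
  }, numeric(1))
}

# OLS coefficients from the normal equations
oracle_ols_coefs <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))
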