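# Fixture builders and independent oracles used across the suite.

# Minimal atom-table builder.
atoms_tbl <- function(chain, resno, resname, elety, element, x, y, z) {
  tibble::tibble(chain = chain, resno = resno, resname = resname,
                 elety = elety, element = element, x = x, y = y, z = z)
}

# Uniform ball of point scatterers with radius R (compact reference body).
ball_structure <- function(n = 400, R = 15, seed = 2) {
  withr::local_seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  r <- R * runif(n)^(1 / 3)
  xyz <- u / sqrt(rowSums(u^2)) * r
  new_structure(atoms_tbl("A", seq_len(n), "ALA", "CA", "C",
                          xyz[, 1], xyz[, 2], xyz[, 3]))
}

# --- brute-force global alignment oracle -----------------------------------
# Enumerates every monotone alignment path explicitly and scores it with
# affine gaps (gap of length L costs open + L * ext, end gaps penalized).
# Independent of the dynamic-programming implementation.
brute_force_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  paths <- list()
  walk <- function(i, j, ops) {
    if (i == n && j == m) {
      paths[[length(paths) + 1]] <<- ops
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, c(ops, "M"))
    if (i < n) walk(i + 1, j, c(ops, "X"))
    if (j < m) walk(i, j + 1, c(ops, "Y"))
  }
  walk(0, 0, character(0))
  score_path <- function(ops) {
    s <- 0; ia <- 0; ib <- 0
    for (op in ops) {
      if (op == "M") {
        ia <- ia + 1; ib <- ib + 1
        s <- s + mat[av[ia], bv[ib]]
      } else if (op == "X") ia <- ia + 1 else ib <- ib + 1
    }
    runs <- rle(ops)
    gap_cost <- sum(ifelse(runs$values %in% c("X", "Y"),
                           open + ext * runs$lengths, 0))
    s - gap_cost
  }
  max(vapply(paths, score_path, numeric(1)))
}

# --- rotation-space grid search oracle for Kabsch --------------------------
# Hierarchically refined Euler-angle grid (9 deg down to ~0.1 deg); for each
# rotation the optimal translation aligns the centroids, so the RMSD of the
# centered sets is minimized directly.
grid_search_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  euler <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_of <- function(a, b, g) {
    R <- euler(a, b, g)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- c(0, pi / 2, 0); best_val <- Inf
  step <- 9 * pi / 180
  grid_a <- seq(0, 2 * pi - step, by = step)
  grid_b <- seq(0, pi, by = step)
  grid_g <- grid_a
  for (a in grid_a) for (b in grid_b) for (g in grid_g) {
    v <- rmsd_of(a, b, g)
    if (v < best_val) { best_val <- v; best <- c(a, b, g) }
  }
  for (lvl in 1:4) {
    rng <- step; step <- step / 3
    ga <- best[1] + seq(-rng, rng, by = step)
    gb <- best[2] + seq(-rng, rng, by = step)
    gg <- best[3] + seq(-rng, rng, by = step)
    for (a in ga) for (b in gb) for (g in gg) {
      v <- rmsd_of(a, b, g)
      if (v < best_val) { best_val <- v; best <- c(a, b, g) }
    }
  }
  best_val
}

# --- independent redundancy-pruning oracle ---------------------------------
# Plain-loop re-implementation of the pruning rule, kept deliberately naive.
prune_oracle_ids <- function(m, target_n) {
  chars <- strsplit(m$seq, "")
  n <- length(chars)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- chars[[i]]; cj <- chars[[j]]
    comp <- ci != "-" & cj != "-"
    d[i, j] <- d[j, i] <- if (sum(comp) == 0) 1 else
      1 - sum(ci[comp] == cj[comp]) / sum(comp)
  }
  pr <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pr],
               pmin(m$id[pr[, 1]], m$id[pr[, 2]]),
               pmax(m$id[pr[, 1]], m$id[pr[, 2]]))
  pr <- pr[ord, , drop = FALSE]
  alive <- rep(TRUE, n)
  for (k in seq_len(nrow(pr))) {
    if (sum(alive) <= target_n) break
    i <- pr[k, 1]; j <- pr[k, 2]
    if (!alive[i] || !alive[j]) next
    oi <- alive; oi[i] <- FALSE
    oj <- alive; oj[j] <- FALSE
    mi <- mean(d[i, oi]); mj <- mean(d[j, oj])
    drop <- if (mi < mj) i else if (mj < mi) j else max(i, j)
    alive[drop] <- FALSE
  }
  m$id[alive]
}
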