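# Independent oracles used across the suite. These deliberately avoid the
# package's own footpoint / optimiser code paths: distances come from dense
# sampling of the curve (plus a 3-point parabolic refinement of the best
# cell), and parameter estimates from an exhaustive grid search.

# squared-distance profile oracle: min over a dense T grid, refined by the
# standard parabolic interpolation of the best three samples
oracle_min_dist2 <- function(A, k, T0, g0, T_grid) {
  psi <- (T_grid - T0)^2 + (A * (1 - exp(-k * T_grid)) - g0)^2
  j <- which.min(psi)
  if (j == 1 || j == length(psi)) return(psi[j])
  y1 <- psi[j - 1]; y2 <- psi[j]; y3 <- psi[j + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom <= 0) return(y2)
  h <- T_grid[2] - T_grid[1]
  delta <- 0.5 * h * (y1 - y3) / denom
  Tref <- T_grid[j] + delta
  (Tref - T0)^2 + (A * (1 - exp(-k * Tref)) - g0)^2
}

oracle_objective <- function(A, k, T_obs, g_obs, T_grid) {
  sum(vapply(seq_along(T_obs),
             function(i) oracle_min_dist2(A, k, T_obs[i], g_obs[i], T_grid),
             numeric(1)))
}

# exhaustive profile grid search: the objective has a long diagonal valley in
# (A, k), so a plain 2-D grid-and-refine loses the minimum; instead sweep an
# exhaustive log-grid in k, minimising over A at each k (1-D golden section
# over the box), then refine the k grid once around the incumbent
oracle_grid_fit <- function(T_obs, g_obs, A_range = c(1, 200),
                            k_range = c(0.001, 1), n_k = 160) {
  T_grid <- seq(0, max(T_obs) * 3 + 5, length.out = 2000)
  profile_A <- function(k) {
    o <- stats::optimize(function(lA) oracle_objective(exp(lA), k, T_obs,
                                                       g_obs, T_grid),
                         interval = log(A_range), tol = 1e-7)
    c(A = exp(o$minimum), obj = o$objective)
  }
  sweep_k <- function(lk_lo, lk_hi, m) {
    lks <- seq(lk_lo, lk_hi, length.out = m)
    prof <- vapply(exp(lks), profile_A, c(A = 0, obj = 0))
    j <- which.min(prof["obj", ])
    list(lk = lks[j], step = lks[2] - lks[1],
         A = prof["A", j], objective = prof["obj", j])
  }
  pass1 <- sweep_k(log(k_range[1]), log(k_range[2]), n_k)
  pass2 <- sweep_k(pass1$lk - pass1$step, pass1$lk + pass1$step, 41)
  best <- if (pass2$objective <= pass1$objective) pass2 else pass1
  list(A = unname(best$A), k = exp(best$lk), objective = unname(best$objective))
}

# exact points on a curve, convenient for noise-free fixtures
curve_points <- function(curve, T) {
  tibble::tibble(patch_time_min = T, gain_euro = gain(curve, T))
}

# partition of leaves obtained by merging all dendrogram joins at height <= h,
# via union-find over the hclust merge list (independent of cutree)
partition_at_height <- function(hc, h) {
  n <- length(hc$order)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_rep <- integer(nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    if (hc$height[s] > h) { cluster_rep[s] <- NA_integer_; next }
    get_rep <- function(id) if (id < 0) find(-id) else find(cluster_rep[id])
    a <- get_rep(hc$merge[s, 1]); b <- get_rep(hc$merge[s, 2])
    parent[b] <- a
    cluster_rep[s] <- a
  }
  vapply(seq_len(n), find, integer(1))
}
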