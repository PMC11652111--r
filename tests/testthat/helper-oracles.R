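# Independent oracles and shared fixtures. Each oracle is a brute-force or
# closed-form route that never touches the implementation it checks.

# The 4-tip worked tree: two cherries of depth 1 on stems of length 1.
worked_tree <- function() {
  load_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Exact NRI by enumerating every k-subset of the pool as an equally likely
# null community (population sd over the enumeration).
oracle_nri_exact <- function(tree, community, pool = tree$tip.label) {
  D <- ape::cophenetic.phylo(tree)
  pair_mpd <- function(s) { sub <- D[s, s]; mean(sub[lower.tri(sub)]) }
  k <- length(community)
  mpds <- apply(utils::combn(pool, k), 2, pair_mpd)
  mu <- mean(mpds)
  sdp <- sqrt(mean((mpds - mu)^2))
  obs <- pair_mpd(community)
  list(nri = -(obs - mu) / sdp, mean = mu, sd = sdp, obs = obs,
       skew = mean((mpds - mu)^3) / sdp^3,
       kurt = mean((mpds - mu)^4) / sdp^4)
}

# Monte-Carlo standard error of an NRI estimate: delta method for
# (obs - mean)/sd with the null's exact skewness and kurtosis (the null MPD
# distribution is discrete and skewed, so the normal-theory sd term is not
# enough).
nri_mc_se <- function(exact, n_reps) {
  z <- exact$nri
  v <- (1 + z^2 * (exact$kurt - 1) / 4 - z * exact$skew) / n_reps
  sqrt(max(v, 1 / (2 * n_reps)))
}

# Hand-written Fisher scoring for the log-link quasi-Poisson regression
# (slope/intercept only; dispersion does not move the point estimates).
oracle_irls_quasipois <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(log(mean(y) + 0.1), 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- drop(solve(t(X) %*% (mu * X), t(X) %*% (mu * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Partition counts of two species sets by direct membership enumeration.
oracle_partition <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- union(A, B)
  inA <- u %in% A; inB <- u %in% B
  list(a = sum(inA & !inB), b = sum(!inA & inB), c = sum(inA & inB))
}

# A tiny deterministic mountain: taxa w-z over 3 belts of 100 m.
toy_matrix <- function() {
  g <- build_grid("toy", 0, 300, 100)
  recs <- tibble::tibble(
    taxon_name = c("w", "w", "x", "x", "y", "z"),
    mountain_id = "toy",
    elevation_m = c(10, 150, 50, 250, 120, 260))
  assign_belts(recs, g, mode = "record")
}

# Presence matrix straight from true ranges (endpoint records only), the
# cheap path used by simulation-heavy tests.
matrix_from_ranges <- function(ranges, config, mountain_id = "sim") {
  grid <- build_grid(mountain_id, config$min_elev, config$max_elev,
                     config$belt_width_m)
  recs <- tibble::tibble(
    taxon_name = rep(ranges$taxon, 2),
    mountain_id = mountain_id,
    elevation_m = c(ranges$lo, ranges$hi))
  assign_belts(recs, grid, mode = "range_through")
}
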