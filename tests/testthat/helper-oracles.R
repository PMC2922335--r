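# Independent oracles and small fixture builders used across the suite.

# exhaustive-pair AUC (Mann-Whitney by enumeration, ties = 0.5)
brute_auc <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# Moran's I with rook neighbors by brute-force neighbor sums
brute_moran_i <- function(m) {
  z <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- 0; w <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; w <- w + 2 }
    if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; w <- w + 2 }
  }
  (length(m) / w) * num / sum(z^2)
}

# great-circle distance in km (same sphere radius geosphere uses by default)
brute_haversine_km <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  r * 2 * asin(pmin(1, sqrt(a))) / 1000
}

# generic convex solver over the full probability simplex: maximize entropy
# subject to feature-expectation constraints, by softmax parametrization with
# quadratic-penalty continuation (independent of the coordinate-descent path)
simplex_maxent_oracle <- function(Fb, pbar) {
  n <- nrow(Fb)
  qfun <- function(z) { z <- z - max(z); q <- exp(z); q / sum(q) }
  obj <- function(z, P) {
    q <- qfun(z)
    r <- as.vector(crossprod(Fb, q)) - pbar
    sum(q * log(pmax(q, 1e-300))) + P * sum(r^2)
  }
  gr <- function(z, P) {
    q <- qfun(z)
    r <- as.vector(crossprod(Fb, q)) - pbar
    v <- (1 + log(pmax(q, 1e-300))) + 2 * P * as.vector(Fb %*% r)
    q * (v - sum(q * v))
  }
  z <- rep(0, n)
  for (P in c(1e2, 1e3, 1e4, 1e5, 1e6)) {
    o <- stats::optim(z, obj, gr, P = P, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    z <- o$par
  }
  qfun(z)
}

kl_div <- function(p, q) sum(p * log(pmax(p, 1e-300) / pmax(q, 1e-300)))

# small landscape fixture
tiny_stack <- function(n = 40, n_layers = 3, range = 3, seed = 42, ...) {
  generate_climate_stack(landscape_spec(n, n, n_layers = n_layers,
                                        autocorrelation_range = range,
                                        seed = seed, ...))
}

# pooled target-group background built from several virtual species
make_pool <- function(stack, n_species = 6, n_each = 150, seed = 500,
                      pool_size = NULL) {
  occ <- lapply(seq_len(n_species), function(i) {
    sp <- random_virtual_species(stack, seed = seed + i)
    sample_occurrences(sp, stack, n_each, seed = seed + 100 + i)
  })
  build_target_group_background(occ, pool_size = pool_size, seed = seed)
}
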