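# Independent oracles and small fixtures used across the suite. These are
# deliberately brute-force / closed-form and share no code with the
# implementation they check.

# Exact two-sided Mann-Whitney p by enumerating all C(m+n, m) group
# assignments of the pooled sample (tie-free data).
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  U_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(length(pooled), n)
  Us <- apply(combs, 2, function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">"))
  })
  mu <- length(x) * length(y) / 2
  # two-sided: as extreme or more extreme in either direction
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# Exact two-sided Spearman p by full permutation of y (tie-free data).
spearman_permute <- function(x, y) {
  r_obs <- stats::cor(rank(x), rank(y))
  perms <- permute_all(length(y))
  rx <- rank(x)
  rs <- apply(perms, 1, function(p) stats::cor(rx, rank(y[p])))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

permute_all <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permute_all(n - 1)
  do.call(rbind, lapply(1:n, function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Closed-form OLS slope/intercept for a handful of (x, y) points
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Delta-method SD of the density-on-HU OLS slope when each insert ROI
# mean carries i.i.d. HU noise of sd sigma/sqrt(n_vox): numeric gradient
# of the slope with respect to the ROI means.
slope_sd_delta <- function(hu_means, densities, sigma, n_vox) {
  f <- function(x) ols_line(x, densities)["slope"]
  g <- vapply(seq_along(hu_means), function(i) {
    h <- 1e-4 * max(1, abs(hu_means[i]))
    xp <- hu_means; xm <- hu_means
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
  sqrt(sum(g^2) * sigma^2 / n_vox)
}

# Uniform-density column fixture: mask + model + elastic/plastic props
column_fixture <- function(nx = 2, ny = 2, nz = 8, h = 1.5, E = 1000,
                           nu = 0, sigy = Inf) {
  cells <- as.matrix(expand.grid(seq_len(nx), seq_len(ny), seq_len(nz)))
  storage.mode(cells) <- "integer"
  m <- nrow(cells)
  model <- femstrength:::mesh_from_cells(cells, rep(0.5, m),
                                         rep("bone", m), h)
  props <- tibble::tibble(E_MPa = rep(E, m), nu = nu, sigma_MPa = sigy)
  list(model = model, props = props, area = nx * ny * h^2, m = m)
}

# Small synthetic femur volume shared by pipeline tests (fast grid)
small_femur <- function(seed = 1, noise_sd = 0) {
  generate_femur_volume(dims = c(24L, 24L, 48L), preset = "femur",
                        phantom = femstrength:::default_phantom(c(24L, 24L, 48L)),
                        noise_sd = noise_sd, seed = seed)
}
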