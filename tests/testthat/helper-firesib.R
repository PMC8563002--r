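## Shared fixtures and independent oracles for the test suite. The oracles
## deliberately re-derive quantities by brute force (explicit loops,
## enumeration, dummy-variable regressions) so they share no code with the
## implementation they check.

## small coarse grid over the tropics with one seasonal fire region
toy_grid <- function(n_months = 24L, res = 2.5) {
  grid_spec(-10, 10, 10, 35, resolution = res, n_months = n_months,
            start_year = 2000L, start_month = 1L)
}

toy_region <- function(intensity = 10) {
  list(list(lat = c(-5, 5), lon = c(15, 30), months = 6:9,
            intensity = intensity))
}

## brute-force IDW: all-pairs loop with a hand-written haversine
oracle_idw <- function(coarse_vals, coarse_lat, coarse_lon, fine_lat,
                       fine_lon, power, k) {
  hav <- function(lat1, lon1, lat2, lon2, R = 6378137) {
    r <- pi / 180
    a <- sin((lat2 - lat1) * r / 2)^2 +
      cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
    2 * R * asin(pmin(1, sqrt(a)))
  }
  out <- matrix(NA_real_, length(fine_lat), length(fine_lon))
  cc <- expand.grid(lat = coarse_lat, lon = coarse_lon)
  v <- as.vector(coarse_vals)
  for (i in seq_along(fine_lat)) for (j in seq_along(fine_lon)) {
    d <- hav(fine_lat[i], fine_lon[j], cc$lat, cc$lon)
    o <- order(d)[seq_len(k)]
    if (d[o[1]] < 1e-6) { out[i, j] <- v[o[1]]; next }
    w <- d[o]^(-power)
    out[i, j] <- sum(w * v[o]) / sum(w)
  }
  out
}

## enumerated conditional log-likelihood for one coefficient, group sizes
## arbitrary (explicit subset loop via combn)
oracle_clogit_loglik <- function(beta, y, x, group) {
  ll <- 0
  for (g in unique(group)) {
    yi <- y[group == g]; xi <- x[group == g]
    k <- sum(yi)
    if (k == 0 || k == length(yi)) next
    subsets <- combn(length(yi), k)
    denom <- sum(apply(subsets, 2, function(s) exp(beta * sum(xi[s]))))
    ll <- ll + beta * sum(xi[yi == 1]) - log(denom)
  }
  ll
}

## small deterministic sibling data set with known structure
toy_sib_data <- function(G = 40, seed = 42, beta = -2, sigma = 5) {
  set.seed(seed)
  sz <- sample(2:3, G, TRUE)
  id <- rep(seq_len(G), sz)
  n <- length(id)
  x <- rnorm(G, 5, 2)[id] + rnorm(n)
  z <- rnorm(n)
  y <- 100 * rnorm(G)[id] + beta * x + 3 * z + sigma * rnorm(n)
  list(df = data.frame(y = y, x = x, z = z, group = id), n = n)
}

## quick retained-cohort builder from a generated fs_cohort
retained <- function(cohort) {
  gr <- build_groups(cohort$births)
  gr$births
}
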