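# Shared fixtures and independent oracles. Phantoms are cached per scenario
# so the suite builds each configuration once.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

noise_free_config <- function(scenario = "TLV", perfusion_shift = 0.8, ...) {
  phantom_config(scenario = scenario, perfusion_shift = perfusion_shift,
                 noise_sd_hu = 0, weight_noise_sd = 0,
                 fluorescence_noise_sdlog = 0, seed = 71, ...)
}

nf_phantom <- function(scenario = "TLV", perfusion_shift = 0.8) {
  cached_fixture(paste0("phantom_", scenario, "_", perfusion_shift), function() {
    make_phantom(noise_free_config(scenario, perfusion_shift))
  })
}

nf_rois <- function(truth) split_rois(truth$lung_left, truth$lung_right)

# Brute-force morphology oracle: exact nearest-distance scan (slow, for
# small grids only).
oracle_edt_sq <- function(mask) {
  dm <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dm)
  if (nrow(fg) == 0) return(out)
  all_idx <- which(array(TRUE, dm), arr.ind = TRUE)
  for (chunk in split(seq_len(nrow(all_idx)),
                      ceiling(seq_len(nrow(all_idx)) / 2048))) {
    pts <- all_idx[chunk, , drop = FALSE]
    d2 <- outer(pts[, 1], fg[, 1], `-`)^2 +
      outer(pts[, 2], fg[, 2], `-`)^2 +
      outer(pts[, 3], fg[, 3], `-`)^2
    out[chunk] <- apply(d2, 1, min)
  }
  out
}

oracle_dilate <- function(mask, r) oracle_edt_sq(mask) <= r^2 + 1e-9
oracle_erode <- function(mask, r) mask & !(oracle_edt_sq(!mask) <= r^2 + 1e-9)

# Closed-form least squares of y on x (normal equations), the independent
# oracle for the regression module.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       p_value = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE))
}

solid_sphere <- function(dm, center, radius) {
  ig <- vqpipe:::index_grid(dm)
  array((ig$i - center[1])^2 + (ig$j - center[2])^2 +
          (ig$k - center[3])^2 <= radius^2, dm)
}
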