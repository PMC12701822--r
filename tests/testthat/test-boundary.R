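# boundary-truncation scenario used across these tests: large TADs so
# every qualifying boundary (200-700 kb from a cut) is the first boundary,
# a broad domain wide enough to be near-flat over the profile flank, and
# sites sparse enough (as in a real genome) that neighbouring TADs carry
# no domain of their own
boundary_scenario <- function(seed) {
  sim_params(genome = c(chr1 = 140e6, chr2 = 140e6),
             tad_sizes = c(2.5e6, 3.5e6, 3e6),
             broad_sd = 3e6, broad_reads = 1e5, narrow_sd = 2.5e3,
             truncate_at_boundaries = TRUE, depth = NA, seed = seed)
}

flat_track <- function(value = 2, n = 1000, bin = 1e4)
  structure(list(chrom = "chrA", bin_size = bin, value = rep(value, n)),
            class = "enrichment_track")

test_that("uniform enrichment gives exactly zero drops", {
  trk <- list(chrA = flat_track())
  sites <- cut_sites("chrA", 3e6)
  bnd <- data.frame(chrom = "chrA", pos = 3.4e6)
  bd <- boundary_drop(trk, sites, bnd, dist_range = c(2e5, 7e5), flank = 1e5)
  expect_identical(bd$boundaries$drops, 0)
  expect_true(is.nan(bd$boundaries$t))   # single pair: t undefined, flagged
  expect_match(bd$boundaries$flag, "undefined")
})

test_that("drops are invariant to global scaling of the track", {
  set.seed(8)
  v <- 5 + abs(rnorm(2000))
  trk1 <- list(chrA = flat_track(1)); trk1$chrA$value <- v
  trk7 <- list(chrA = flat_track(1)); trk7$chrA$value <- 7 * v
  sites <- cut_sites("chrA", c(3e6, 9e6), rank = 1:2)
  bnd <- data.frame(chrom = "chrA", pos = c(3.4e6, 9.5e6))
  b1 <- boundary_drop(trk1, sites, bnd)
  b7 <- boundary_drop(trk7, sites, bnd)
  expect_equal(b1$boundaries$drops, b7$boundaries$drops, tolerance = 1e-12)
})

test_that("no qualifying pair raises a data error", {
  trk <- list(chrA = flat_track())
  sites <- cut_sites("chrA", 3e6)
  bnd <- data.frame(chrom = "chrA", pos = 8e6)   # 5 Mb away
  expect_error(boundary_drop(trk, sites, bnd), "no \\(site, boundary\\) pair")
})

test_that("random controls are deterministic, in-range and distance-matched", {
  p <- boundary_scenario(seed = 51)
  ms <- make_sites(p, 36, 7e6, 2e6)
  d <- c(2e5, 7e5)
  cl <- c(chr1 = 140e6, chr2 = 140e6)
  c1 <- sample_random_controls(ms$sites, ms$boundaries, d, 400, seed = 9,
                               chrom_lengths = cl)
  c2 <- sample_random_controls(ms$sites, ms$boundaries, d, 400, seed = 9,
                               chrom_lengths = cl)
  expect_identical(c1, c2)
  dist <- abs(c1$pos - c1$site_pos)
  expect_true(all(dist >= 2e5 & dist <= 7e5))
  for (j in seq_len(nrow(c1))) {
    b <- ms$boundaries$pos[ms$boundaries$chrom == c1$chrom[j]]
    expect_true(all(abs(b - c1$pos[j]) >= 1e5))
  }
  # empirical-CDF distance match (two-sample KS distance, computed directly)
  true_d <- with(subset(merge(ms$sites, ms$boundaries, by = "chrom"),
                        abs(pos.y - pos.x) >= 2e5 & abs(pos.y - pos.x) < 7e5),
                 abs(pos.y - pos.x))
  grid <- seq(2e5, 7e5, length.out = 400)
  ks <- max(abs(ecdf(true_d)(grid) - ecdf(dist)(grid)))
  expect_lt(ks, 0.1)
})

test_that("boundary truncation yields positive drops; matched controls do not", {
  p <- boundary_scenario(seed = 52)
  ms <- make_sites(p, 36, 7e6, 2e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  trk <- enrichment_track(chip$treated, chip$untreated)
  bd <- boundary_drop(trk, ms$sites, ms$boundaries, n_controls = 100,
                      seed = 5)
  expect_gt(bd$boundaries$mean, 0)
  expect_lt(bd$boundaries$p, 0.01)
  expect_lt(abs(bd$controls$mean), 3 * bd$controls$sem)
})

test_that("band membership follows the half-open convention on a crafted track", {
  # 3 bins of 0.5 Mb starting at +0 / +0.5 / +1.0 Mb from the cut
  v <- c(rep(0, 4), 10, 20, 40)          # cut at 2.0 Mb, bins of 0.5 Mb
  trk <- list(chrA = structure(list(chrom = "chrA", bin_size = 5e5,
                                    value = v), class = "enrichment_track"))
  sites <- cut_sites("chrA", c(2e6, 2e6 + 1), rank = 1:2)  # near-duplicate sites
  bd <- band_difference(trk, trk, sites,
                        bands = list(c(-1.5e6, 5e5), c(5e5, 1.5e6)))
  # bin centers at +0.25/+0.75/+1.25 Mb: first is proximal, last two distal
  expect_equal(bd$table$mean_A[1], mean(c(0, 0, 0, 10)))
  expect_equal(bd$table$mean_A[2], mean(c(20, 40)))
  expect_equal(bd$table$difference, c(0, 0))
  expect_true(all(bd$table$p == 1))
})

test_that("band differences are antisymmetric in the two conditions", {
  p <- tiny_chip_params(seed = 53)
  ms <- make_sites(p, 4, 1.6e6, 1.8e6)
  chipA <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  pB <- p; pB$broad_sd <- p$broad_sd * 1.5; pB$seed <- 999L
  chipB <- simulate_chip_pair(pB, ms$sites, ms$boundaries)
  ta <- enrichment_track(chipA$treated, chipA$untreated)
  tb <- enrichment_track(chipB$treated, chipB$untreated)
  ab <- band_difference(ta, tb, ms$sites)
  ba <- band_difference(tb, ta, ms$sites)
  expect_equal(ab$table$difference, -ba$table$difference, tolerance = 1e-12)
  expect_error(band_difference(ta, tb, ms$sites,
                               bands = list(c(-1e6, 5e5), c(4e5, 1e6))),
               "non-overlapping")
})

test_that("a broader domain in condition B raises the distal band", {
  p <- sim_params(genome = c(chrA = 20e6), tad_sizes = 5e6,
                  truncate_at_boundaries = FALSE, broad_sd = 2.5e5,
                  depth = 5e6, seed = 54)
  ms <- make_sites(p, 5, 3.2e6, 2e6)
  pB <- p; pB$broad_sd <- p$broad_sd * 1.5; pB$seed <- 1055L
  chipA <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  chipB <- simulate_chip_pair(pB, ms$sites, ms$boundaries)
  bd <- band_difference(enrichment_track(chipA$treated, chipA$untreated),
                        enrichment_track(chipB$treated, chipB$untreated),
                        ms$sites)
  # sign oracle from the analytic expected tracks
  band_mean_exp <- function(par) {
    et <- expected_chip_tracks(par, "chrA", ms$sites, treated = TRUE)
    eu <- expected_chip_tracks(par, "chrA", ms$sites, treated = FALSE)
    tt <- sum(et$fwd) + sum(et$rev); tu <- sum(eu$fwd) + sum(eu$rev)
    dens <- (et$fwd + et$rev) * 1e6 / tt - (eu$fwd + eu$rev) * 1e6 / tu
    ctr <- (seq_along(dens) - 0.5) * 100 - ms$sites$pos[1]
    c(prox = mean(dens[ctr >= -1.5e6 & ctr < 5e5]),
      dist = mean(dens[ctr >= 5e5 & ctr < 1.5e6]))
  }
  eA <- band_mean_exp(p); eB <- band_mean_exp(pB)
  expect_gt(eB[["dist"]] - eA[["dist"]], 0)
  expect_gt(bd$table$difference[2], 0)
  expect_equal(sign(bd$table$difference[1]), sign(eB[["prox"]] - eA[["prox"]]))
})
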