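test_that("RPM normalization scales by library size and is depth-invariant", {
  cov <- stranded_coverage("chrA", 100, c(4, 0, 2), c(0, 4, 2), 2e6)
  r <- rpm_normalize(cov)
  expect_equal(r$fwd[1], 2.0)
  expect_identical(r$normalization, "rpm")
  cov2 <- stranded_coverage("chrA", 100, 2 * c(4, 0, 2), 2 * c(0, 4, 2), 4e6)
  expect_equal(rpm_normalize(cov2)$fwd, r$fwd)
  bad <- stranded_coverage("chrA", 100, 1, 1, 10)
  bad$library_size <- 0
  expect_error(rpm_normalize(bad), "zero library")
})

test_that("synthetic RPM totals match the per-chromosome read share", {
  p <- sim_params(genome = c(chrA = 4e6, chrB = 4e6), seed = 41)
  ms <- make_sites(p, 2, 1e6, 1.5e6)
  chip <- simulate_chip_pair(p, ms$sites)
  cov <- chip$treated$chrA
  r <- rpm_normalize(cov)
  chrom_reads <- sum(cov$fwd) + sum(cov$rev)
  expect_equal(sum(r$fwd) + sum(r$rev), 1e6 * chrom_reads / cov$library_size,
               tolerance = 1e-9)
})

test_that("meta-profile reduces to a single-site window and nulls out on identity", {
  p <- tiny_chip_params(seed = 42)
  ms <- make_sites(p, 4, 1.6e6, 1.8e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  same <- meta_profile(chip$treated, chip$treated, ms$sites, 1e4, 500)
  expect_true(all(same$value == 0))
  # single site, zero untreated: profile equals that site's treated RPM window
  s1 <- cut_sites(ms$sites$chrom[1], ms$sites$pos[1])
  zero <- stranded_coverage("chrA", 100,
                            numeric(length(chip$treated$chrA$fwd)),
                            numeric(length(chip$treated$chrA$rev)), 1)
  pr <- meta_profile(chip$treated, list(chrA = zero), s1, 5e3, 100)
  tr <- rpm_normalize(chip$treated$chrA)
  v <- tr$fwd + tr$rev
  L <- s1$pos - 5e3 - 50
  j0 <- ceiling(L / 100 - 0.5)
  expect_equal(pr$value, v[(j0 + 1):(j0 + 101)], tolerance = 1e-12)
})

test_that("meta-profile is linear in the treated signal at fixed library sizes", {
  set.seed(99)
  n <- 2000
  L <- 1e8
  mk <- function(f, r) list(chrA = stranded_coverage("chrA", 100, f, r, L))
  f1 <- rpois(n, 5); r1 <- rpois(n, 5)
  f2 <- rpois(n, 3); r2 <- rpois(n, 3)
  u <- mk(rpois(n, 4), rpois(n, 4))
  sites <- cut_sites("chrA", 1e5)
  pm <- meta_profile(mk(2 * f1 + 3 * f2, 2 * r1 + 3 * r2), u, sites, 1e4, 500)
  p1 <- meta_profile(mk(f1, r1), u, sites, 1e4, 500)
  p2 <- meta_profile(mk(f2, r2), u, sites, 1e4, 500)
  uu <- meta_profile(u, mk(numeric(n), numeric(n)), sites, 1e4, 500)
  # profile(2 T1 + 3 T2 vs U) = 2 profile(T1,U) + 3 profile(T2,U) + 4 U-window
  expect_equal(pm$value, 2 * p1$value + 3 * p2$value + 4 * uu$value,
               tolerance = 1e-9)
})

test_that("meta-profile recovers the analytic peak and baseline", {
  p <- tiny_chip_params(seed = 44)
  ms <- make_sites(p, 6, 1.6e6, 1.8e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  coarse <- meta_profile(chip$treated, chip$untreated, ms$sites, 1.5e6, 5e3)
  # analytic expectation from the generator's expected tracks (the far
  # flank sits on the library-composition pedestal, not on zero)
  et <- expected_chip_tracks(p, "chrA", ms$sites, treated = TRUE)
  eu <- expected_chip_tracks(p, "chrA", ms$sites, treated = FALSE)
  tot_t <- sum(et$fwd) + sum(et$rev)
  tot_u <- sum(eu$fwd) + sum(eu$rev)
  dens_t <- (et$fwd + et$rev) * 1e6 / tot_t
  dens_u <- (eu$fwd + eu$rev) * 1e6 / tot_u
  # analytic meta-profile: identical windowing applied to the expected
  # RPM density difference
  k <- 5e3 / 100
  offs <- coarse$dist
  prof_exp <- Reduce(`+`, lapply(ms$sites$pos, function(pos) {
    L <- pos - 1.5e6 - 2.5e3
    j0 <- ceiling(L / 100 - 0.5)
    idx <- (j0 + 1):(j0 + length(offs) * k)
    colSums(matrix(dens_t[idx] - dens_u[idx], nrow = k))
  })) / nrow(ms$sites)
  ctr <- which(offs == 0)
  expect_equal(coarse$value[ctr], prof_exp[ctr], tolerance = 0.15)
  # far flank agrees with the analytic baseline (which sits on the
  # library-composition pedestal plus neighbouring-domain tails, not 0)
  edge <- abs(offs) > 1.4e6
  expect_equal(mean(coarse$value[edge]), mean(prof_exp[edge]),
               tolerance = 0.5)
})

test_that("two-component fit separates scales and is deterministic", {
  # sites far enough apart that broad domains do not contaminate each
  # other's coarse windows (real cut sites average tens of Mb apart)
  p <- sim_params(genome = c(chrA = 30e6), chip_bin_size = 100, depth = 5e6,
                  seed = 45, truncate_at_boundaries = FALSE)
  ms <- make_sites(p, 6, 4e6, 2e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  fine <- meta_profile(chip$treated, chip$untreated, ms$sites, 1.5e4, 100)
  coarse <- meta_profile(chip$treated, chip$untreated, ms$sites, 1.5e6, 5e3)
  f1 <- fit_two_component(fine, coarse)
  f2 <- fit_two_component(fine, coarse)
  expect_identical(coef(f1), coef(f2))
  expect_true(f1$converged)
  expect_lt(f1$narrow_fwhm, f1$broad_fwhm)
  expect_equal(f1$narrow_fwhm, 2.3548 * p$narrow_sd, tolerance = 0.15)
  expect_equal(f1$broad_fwhm, 2.3548 * p$broad_sd, tolerance = 0.15)
})

test_that("a pure narrow Gaussian yields a negligible broad component", {
  p <- tiny_chip_params(seed = 46, broad_reads = 0, narrow_sd = 2e3,
                        broad_sd = 2.5e5, narrow_reads = 1e5,
                        truncate_at_boundaries = FALSE)
  ms <- make_sites(p, 6, 1.6e6, 1.8e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  fine <- meta_profile(chip$treated, chip$untreated, ms$sites, 1.5e4, 100)
  coarse <- meta_profile(chip$treated, chip$untreated, ms$sites, 1.5e6, 5e3)
  f <- fit_two_component(fine, coarse)
  expect_lt(f$broad_amplitude, 0.05 * f$narrow_amplitude)
})

test_that("a flat profile fits with near-zero amplitudes and converges", {
  fine <- structure(list(dist = seq(-1.5e4, 1.5e4, 100),
                         value = rep(2, 301), bin_size = 100, n_sites = 1,
                         normalization = "rpm_diff", strand = "both"),
                    class = "meta_profile")
  coarse <- structure(list(dist = seq(-1.5e6, 1.5e6, 5e3),
                           value = rep(100, 601), bin_size = 5e3, n_sites = 1,
                           normalization = "rpm_diff", strand = "both"),
                      class = "meta_profile")
  f <- fit_two_component(fine, coarse)
  expect_true(f$converged)
  expect_lt(f$narrow_amplitude, 1e-6 * f$background + 1e-6)
  expect_lt(f$broad_amplitude, 1e-6 * f$background + 1e-6)
})

test_that("strand asymmetry switches polarity at the cut and negates on strand swap", {
  p <- tiny_chip_params(seed = 47, resection_span = 1e3, asym_fraction = 0.8)
  ms <- make_sites(p, 6, 1.6e6, 1.8e6)
  chip <- simulate_chip_pair(p, ms$sites, ms$boundaries)
  a <- strand_asymmetry(chip$treated, chip$untreated, ms$sites, 5e3, 200)
  expect_lt(mean(a$value[a$dist < 0]), 0)
  expect_gt(mean(a$value[a$dist > 0]), 0)
  expect_lt(abs(a$switch_pos), 500)
  expect_equal(a$extent, 2e3, tolerance = 0.5)
  swapped <- lapply(chip$treated, function(cv)
    stranded_coverage(cv$chrom, cv$bin_size, cv$rev, cv$fwd,
                      cv$library_size, cv$sample))
  swapped_u <- lapply(chip$untreated, function(cv)
    stranded_coverage(cv$chrom, cv$bin_size, cv$rev, cv$fwd,
                      cv$library_size, cv$sample))
  b <- strand_asymmetry(swapped, swapped_u, ms$sites, 5e3, 200)
  expect_equal(b$value, -a$value, tolerance = 1e-12)
})

test_that("symmetric strands give a flagged zero-extent asymmetry", {
  p <- tiny_chip_params(seed = 48, asym_fraction = 0)
  ms <- make_sites(p, 4, 1.6e6, 1.8e6)
  e <- expected_chip_tracks(p, "chrA", ms$sites)
  expect_identical(e$fwd, e$rev)
  # exactly identical strand inputs: degenerate, flagged
  cv <- simulate_chip_pair(p, ms$sites)$treated$chrA
  sym <- stranded_coverage("chrA", 100, cv$fwd, cv$fwd, 2 * sum(cv$fwd))
  symu <- stranded_coverage("chrA", 100, cv$rev, cv$rev, 2 * sum(cv$rev))
  a <- strand_asymmetry(list(chrA = sym), list(chrA = symu), ms$sites, 5e3, 200)
  expect_identical(a$extent, 0)
  expect_match(a$flag, "undefined")
})

test_that("coverage round-trips through bedGraph with library sidecar", {
  cov <- stranded_coverage("chrA", 100, c(0, 3, 0, 5, 1), c(2, 0, 0, 1, 0),
                           1e5, sample = "t")
  pre <- tempfile()
  write_coverage_bedgraph(cov, pre)
  r <- read_coverage_bedgraph(pre)
  expect_equal(r$fwd, cov$fwd)
  expect_equal(r$rev, cov$rev)
  expect_equal(r$library_size, cov$library_size)
})
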