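make_map <- function(n = 40, bin = 5e4, lambda = 30, seed = 1)
  contact_map("chrT", bin, rand_sym_matrix(n, lambda, seed = seed))

test_that("contact maps round-trip through dense TSV, NaN preserved", {
  m <- make_map(12)
  m$counts[3, ] <- NaN; m$counts[, 3] <- NaN
  m <- contact_map(m$chrom, m$bin_size, m$counts)
  f <- tempfile(fileext = ".tsv")
  write_contact_map(m, f)
  r <- read_contact_map(f)
  expect_identical(r$counts, m$counts)
  expect_equal(r$bin_size, m$bin_size)
  expect_error(read_contact_map(f, chromosome = "chrX"), "chrX")
  expect_error(read_contact_map(f, bin_size = 1e4), "resolution")
})

test_that("written synthetic map preserves the realized total", {
  p <- sim_params(genome = c(chrA = 6e6), contact_bin_size = 5e4, seed = 9)
  out <- simulate_contact_pair(p, cut_sites("chrA", 3e6))
  f <- tempfile(fileext = ".tsv")
  write_contact_map(out$treated$chrA, f)
  r <- read_contact_map(f)
  expect_identical(sum(r$counts), sum(out$treated$chrA$counts))
})

test_that("asymmetric input is rejected", {
  m <- matrix(1:16, 4, 4)
  expect_error(contact_map("chrT", 1e4, m), "asymmetric")
})

test_that("window extraction is centered, sized and bounds-checked", {
  m <- make_map(100, bin = 5e4)
  sites <- cut_sites(rep("chrT", 3), c(2.5e6, 1e5, 4.6e6), 1:3)
  st <- extract_windows(m, sites, 1.5e6)
  expect_equal(dim(st$windows), c(61, 61, 3))
  expect_identical(st$valid, c(TRUE, FALSE, FALSE))  # 2nd/3rd near the ends
  cb <- floor(2.5e6 / 5e4) + 1
  expect_identical(st$windows[31, 31, 1], m$counts[cb, cb])
  expect_error(extract_windows(m, cut_sites("chrT", 1e5), 1.5e6),
               "no site")
  expect_error(extract_windows(m, sites, 1.4e5), "multiple")
})

test_that("differential map identities and antisymmetry hold", {
  m <- make_map(60)
  sites <- cut_sites(rep("chrT", 2), c(1.4e6, 1.6e6), 1:2)
  st <- extract_windows(m, sites, 5e5)
  expect_true(all(differential_map(st, st)$matrix == 0))
  m2 <- m; m2$counts <- 2 * m$counts
  st2 <- extract_windows(m2, sites, 5e5)
  d <- differential_map(st2, st, epsilon = 0)
  expect_true(all(abs(d$matrix - 1) < 1e-12))
  a <- differential_map(st2, st, epsilon = 1)
  b <- differential_map(st, st2, epsilon = 1)
  expect_equal(a$matrix, -b$matrix, tolerance = 1e-14)
})

test_that("aggregation ignores invalid sites and site order", {
  m <- make_map(100)
  s1 <- cut_sites(rep("chrT", 2), c(2.0e6, 3.0e6), 1:2)
  s2 <- cut_sites(rep("chrT", 3), c(3.0e6, 2.0e6, 1e5), 1:3)  # reordered + invalid
  u <- make_map(100, seed = 2)
  d1 <- differential_map(extract_windows(m, s1, 1e6),
                         extract_windows(u, s1, 1e6))
  d2 <- differential_map(extract_windows(m, s2, 1e6),
                         extract_windows(u, s2, 1e6))
  expect_equal(d1$matrix, d2$matrix, tolerance = 1e-12)
  expect_equal(d2$n, 2)
})

test_that("synthetic stripe shows up on the cross and matches the expected-matrix oracle", {
  p <- sim_params(genome = c(chrA = 30e6), stripe_strength = 2,
                  stripe_extent = 1e6, seed = 21)
  m <- make_sites(p, 8, 1.5e6, 2e6)
  out <- simulate_contact_pair(p, m$sites)
  wt <- extract_windows(out$treated, m$sites, 1.5e6)
  wu <- extract_windows(out$untreated, m$sites, 1.5e6)
  agg <- differential_map(wt, wu)
  ctr <- 61
  cross <- c(agg$matrix[ctr, -ctr], agg$matrix[-ctr, ctr])
  off <- agg$matrix[-ctr, -ctr]
  expect_true(mean(cross) > mean(off))
  # oracle: same statistic on the analytic expected matrices
  ET <- expected_contact_matrix(p, "chrA", m$sites, TRUE)
  EU <- expected_contact_matrix(p, "chrA", m$sites, FALSE)
  lr <- log2((ET + 1) / (EU + 1))
  cb <- floor(m$sites$pos[1] / 25e3) + 1
  idx <- (cb - 60):(cb + 60)
  w <- lr[idx, idx]
  cross_exp <- mean(c(w[61, -61], w[-61, 61]))
  off_exp <- mean(w[-61, -61])
  expect_true(cross_exp > off_exp)
  # realized cross contrast within 25% of the analytic one
  expect_equal(mean(cross) - mean(off), cross_exp - off_exp, tolerance = 0.25)
})

test_that("virtual 4C extracts rows and the differential of identical maps is zero", {
  m <- make_map(40, bin = 5e4)
  pr <- virtual_4c(m, c(10e5, 10.5e5), 5e5)
  cb <- 21
  expect_identical(pr$value, m$counts[cb, (cb - 10):(cb + 10)])
  expect_identical(pr$dist, seq(-5e5, 5e5, by = 5e4))
  p2 <- virtual_4c(m, c(10e5, 10.5e5), 5e5)
  d <- differential_4c(list(pr), list(p2))
  expect_true(all(d$value == 0))
  masked <- m
  masked$counts[cb, ] <- NaN; masked$counts[, cb] <- NaN
  masked <- contact_map("chrT", 5e4, masked$counts)
  expect_error(virtual_4c(masked, c(10e5, 10.5e5), 5e5), "masked")
})

test_that("differential 4C is invariant to site permutation", {
  m <- make_map(80); u <- make_map(80, seed = 3)
  vps <- list(c(1e6, 1.05e6), c(2e6, 2.05e6), c(3e6, 3.05e6))
  t_prof <- lapply(vps, function(v) virtual_4c(m, v, 5e5))
  u_prof <- lapply(vps, function(v) virtual_4c(u, v, 5e5))
  a <- differential_4c(t_prof, u_prof)
  b <- differential_4c(t_prof[c(3, 1, 2)], u_prof[c(3, 1, 2)])
  expect_identical(a$value, b$value)
})

test_that("stripe excess decays below 10% of maximum beyond the stripe extent", {
  p <- sim_params(genome = c(chrA = 30e6), stripe_strength = 2,
                  stripe_extent = 1e6, cut_attenuation = 1,
                  tad_multiplier = 1, boundary_insulation = 1, seed = 22)
  m <- make_sites(p, 6, 3e6, 2.5e6)
  # oracle on the expected matrices: excess profile from the cut viewpoint
  excess_at <- function(E_T, E_U, cb, fb) {
    (E_T[cb, (cb - fb):(cb + fb)] - E_U[cb, (cb - fb):(cb + fb)])
  }
  ET <- expected_contact_matrix(p, "chrA", m$sites, TRUE)
  EU <- expected_contact_matrix(p, "chrA", m$sites, FALSE)
  fb <- 1.4e6 / 25e3
  exc <- Reduce(`+`, lapply(m$sites$pos, function(pos)
    excess_at(ET, EU, floor(pos / 25e3) + 1, fb))) / nrow(m$sites)
  dist <- seq(-fb, fb) * 25e3
  inner_max <- max(exc[abs(dist) <= 1e6])
  expect_true(all(exc[abs(dist) > 1e6] < 0.1 * inner_max))
  # realization: same conclusion from the simulated maps
  out <- simulate_contact_pair(p, m$sites)
  v <- site_differential_4c(out$treated, out$untreated, m$sites, 1.4e6,
                            viewpoint_mode = "center")
  realized_max <- max(v$value[abs(v$dist) <= 1e6])
  expect_true(mean(v$value[abs(v$dist) > 1.05e6]) < 0.1 * realized_max)
})

test_that("expected differential is mirror-symmetric for a centered site", {
  p <- sim_params(genome = c(chrA = 10e6), tad_multiplier = 1,
                  boundary_insulation = 1, seed = 1)
  s <- cut_sites("chrA", 5e6 + 12.5e3)   # center of a bin
  ET <- expected_contact_matrix(p, "chrA", s, TRUE)
  cb <- 201
  row <- ET[cb, (cb - 40):(cb + 40)]
  expect_equal(row, rev(row), tolerance = 1e-12)
})
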