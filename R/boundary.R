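#' Normalized enrichment drop at TAD boundaries
#'
#' For every (cut site, boundary) pair whose distance lies in
#' `dist_range`, extracts the enrichment profile over boundary
#' `+/- flank`, orients it so the cut-proximal side is on the left, and
#' normalizes it by its cut-proximal mean (pairs with non-positive
#' proximal mean are excluded and counted). The drop is
#' `1 - distal mean / proximal mean`: a positive drop means the signal
#' falls when crossing the boundary away from the break, i.e. the broad
#' domain is truncated there. The identical computation runs on
#' distance-matched random control positions; both groups get a one-sample
#' t-test against zero.
#'
#' @param track an `enrichment_track` (treated minus untreated RPM) or a
#'   named list per chromosome.
#' @param sites a `cut_sites`.
#' @param boundaries data frame (`chrom`, `pos`) of TAD boundary
#'   positions.
#' @param dist_range length-2 numeric, bp: qualifying site-boundary
#'   distances `[lo, hi)`. Default 200-700 kb.
#' @param flank half-width of the boundary profile, bp (default 100 kb).
#' @param n_controls number of random control positions (default 0: no
#'   control group).
#' @param seed seed for the control draw.
#' @return a `boundary_drop_result`: per-pair drops, per-control drops,
#'   mean +/- sem and t/p per group, averaged oriented profiles, and
#'   filtering counts.
#' @export
boundary_drop <- function(track, sites, boundaries,
                          dist_range = c(2e5, 7e5), flank = 1e5,
                          n_controls = 0, seed = 1L) {
  if (dist_range[1] >= dist_range[2]) stop_data("dist_range lower must be < upper")
  if (flank <= 0) stop_data("flank must be > 0")
  trk <- if (inherits(track, "enrichment_track"))
    stats::setNames(list(track), track$chrom) else track
  pairs <- qualifying_pairs(sites, boundaries, dist_range)
  if (!nrow(pairs)) stop_data("no (site, boundary) pair within the distance range")
  b <- drops_for_pairs(trk, pairs, flank)
  ctrl <- NULL
  if (n_controls > 0) {
    cp <- sample_random_controls(sites, boundaries, dist_range, n_controls,
                                 seed = seed, exclusion = flank,
                                 chrom_lengths = vapply(trk, function(t)
                                   length(t$value) * t$bin_size, numeric(1)))
    ctrl <- drops_for_pairs(trk, cp, flank)
  }
  grp <- function(d) {
    n <- length(d$drops)
    degenerate <- n < 2 || sd(d$drops) == 0
    tt <- if (!degenerate) t.test(d$drops, mu = 0) else NULL
    list(drops = d$drops, n = n, mean = mean(d$drops),
         sem = if (n > 1) sd(d$drops) / sqrt(n) else NA_real_,
         t = if (degenerate) NaN else unname(tt$statistic),
         p = if (degenerate) NaN else tt$p.value,
         profile = d$profile, n_excluded = d$n_excluded,
         flag = if (degenerate) "t-test undefined (<2 pairs or constant drops)" else NA_character_)
  }
  structure(list(boundaries = grp(b),
                 controls = if (!is.null(ctrl)) grp(ctrl) else NULL,
                 dist_range = dist_range, flank = flank,
                 normalization = "cut-proximal mean"),
            class = "boundary_drop_result")
}

qualifying_pairs <- function(sites, boundaries, dist_range) {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    b <- boundaries[boundaries$chrom == sites$chrom[i], , drop = FALSE]
    d <- abs(b$pos - sites$pos[i])
    keep <- d >= dist_range[1] & d < dist_range[2]
    if (!any(keep)) return(NULL)
    data.frame(chrom = sites$chrom[i], site_pos = sites$pos[i],
               pos = b$pos[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))]) %||%
    data.frame(chrom = character(), site_pos = numeric(), pos = numeric())
}

## oriented, proximal-normalized drops for (site_pos, pos) pairs.
## Pairs whose cut-proximal mean is not positive cannot be normalized and
## are excluded (counted); in addition, pairs whose proximal mean falls
## below 10% of the group's median positive proximal mean are excluded,
## because a ratio of near-zero noise means is unbounded and would swamp
## the drop statistic (a track with signal everywhere loses nothing).
drops_for_pairs <- function(trk, pairs, flank) {
  prox <- dist <- rep(NA_real_, nrow(pairs))
  profs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t <- trk[[pairs$chrom[i]]]
    if (is.null(t)) next
    bs <- t$bin_size
    fb <- ceiling(flank / bs)
    cb <- pos_to_bin(pairs$pos[i], bs)
    if (cb - fb < 1 || cb + fb - 1 > length(t$value)) next
    prof <- t$value[(cb - fb):(cb + fb - 1)]          # flank bins each side
    if (pairs$pos[i] < pairs$site_pos[i]) prof <- rev(prof)  # cut-proximal left
    prox[i] <- mean(prof[seq_len(fb)])
    dist[i] <- mean(prof[(fb + 1):(2 * fb)])
    profs[[i]] <- prof
  }
  pos_prox <- prox[is.finite(prox) & prox > 0]
  if (!length(pos_prox)) stop_data("no usable pair (all excluded or out of bounds)")
  floor_val <- 0.1 * median(pos_prox)
  use <- which(is.finite(prox) & prox > max(0, floor_val))
  n_excluded <- sum(is.finite(prox)) - length(use)
  if (!length(use)) stop_data("no usable pair (all excluded or out of bounds)")
  list(drops = 1 - dist[use] / prox[use],
       profile = Reduce(`+`, lapply(use, function(i) profs[[i]] / prox[i])) /
         length(use),
       n_excluded = n_excluded)
}

#' @export
print.boundary_drop_result <- function(x, ...) {
  b <- x$boundaries
  cat("<boundary_drop_result> ", b$n, " (site, boundary) pairs at ",
      fmt_bp(x$dist_range[1]), "-", fmt_bp(x$dist_range[2]), "\n", sep = "")
  cat(sprintf("  boundary drop: %.3g +/- %.2g (t=%.3g, p=%s; %d pairs excluded)\n",
              b$mean, b$sem, b$t, format.pval(b$p, digits = 3), b$n_excluded))
  if (!is.null(x$controls))
    cat(sprintf("  random-site drop: %.3g +/- %.2g (t=%.3g, p=%s, n=%d)\n",
                x$controls$mean, x$controls$sem, x$controls$t,
                format.pval(x$controls$p, digits = 3), x$controls$n))
  invisible(x)
}

#' Distance-matched random control positions
#'
#' Draws control positions at distances from cut sites sampled by inverse
#' empirical CDF from the true site-boundary distance distribution (so the
#' two distance distributions match), on a random side of a random site,
#' excluding positions within `exclusion` of any true boundary and outside
#' the chromosome. Deterministic given the seed.
#'
#' @inheritParams boundary_drop
#' @param n number of controls.
#' @param exclusion clearance from true boundaries, bp.
#' @param chrom_lengths named vector of chromosome lengths, bp (bounds
#'   check; positions must leave room for the profile flank).
#' @return data frame (`chrom`, `site_pos`, `pos`), usable as control
#'   pairs.
#' @export
sample_random_controls <- function(sites, boundaries, dist_range, n,
                                   seed = 1L, exclusion = 1e5,
                                   chrom_lengths = NULL) {
  if (n <= 0) stop_data("n must be > 0")
  d <- qualifying_pairs(sites, boundaries, dist_range)
  dists <- abs(d$pos - d$site_pos)
  if (!length(dists)) stop_data("no qualifying site-boundary distances to match")
  with_seed(seed, {
    out <- data.frame(chrom = character(), site_pos = numeric(), pos = numeric())
    tries <- 0L
    while (nrow(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop_data("cannot place ", n, " controls outside boundary exclusions")
      m <- n - nrow(out)
      dd <- as.numeric(quantile(dists, runif(m), type = 1))  # inverse ECDF
      si <- sample.int(nrow(sites), m, replace = TRUE)
      sign <- sample(c(-1, 1), m, replace = TRUE)
      cand <- data.frame(chrom = sites$chrom[si], site_pos = sites$pos[si],
                         pos = sites$pos[si] + sign * dd,
                         stringsAsFactors = FALSE)
      ok <- vapply(seq_len(m), function(j) {
        b <- boundaries$pos[boundaries$chrom == cand$chrom[j]]
        near <- length(b) && any(abs(b - cand$pos[j]) < exclusion)
        inb <- if (!is.null(chrom_lengths))
          cand$pos[j] - exclusion >= 0 &&
          cand$pos[j] + exclusion <= chrom_lengths[[cand$chrom[j]]]
        else cand$pos[j] >= 0
        !near && inb
      }, logical(1))
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Distance-band differential enrichment between two conditions
#'
#' Per site and condition, averages the damage-induced enrichment within
#' signed distance bands around the cut (half-open `[lo, hi)` on the
#' signed axis, default -1.5..0.5 Mb and 0.5..1.5 Mb), then compares the
#' two conditions per band with an unpaired two-sided t-test. The reported
#' difference is condition B minus condition A.
#'
#' @param chip_A,chip_B `enrichment_track`s (or named lists per
#'   chromosome) for the two conditions, on identical bins.
#' @param sites a `cut_sites` shared by both conditions.
#' @param bands list of length-2 numeric signed intervals, bp;
#'   non-overlapping.
#' @return a `band_difference_result` with a per-band table and retained
#'   per-site values.
#' @export
band_difference <- function(chip_A, chip_B, sites,
                            bands = list(c(-1.5e6, 5e5), c(5e5, 1.5e6))) {
  a <- if (inherits(chip_A, "enrichment_track"))
    stats::setNames(list(chip_A), chip_A$chrom) else chip_A
  b <- if (inherits(chip_B, "enrichment_track"))
    stats::setNames(list(chip_B), chip_B$chrom) else chip_B
  for (i in seq_along(bands)) for (j in seq_along(bands))
    if (i < j && bands[[i]][1] < bands[[j]][2] && bands[[j]][1] < bands[[i]][2])
      stop_data("bands must be non-overlapping")
  band_means <- function(trk) {
    vapply(seq_len(nrow(sites)), function(i) {
      t <- trk[[sites$chrom[i]]]
      if (is.null(t)) return(rep(NA_real_, length(bands)))
      bs <- t$bin_size
      centers <- (seq_along(t$value) - 0.5) * bs - sites$pos[i]
      vapply(bands, function(bd)
        mean(t$value[centers >= bd[1] & centers < bd[2]]), numeric(1))
    }, numeric(length(bands)))
  }
  ma <- band_means(a); mb <- band_means(b)   # bands x sites
  per_band <- lapply(seq_along(bands), function(k) {
    va <- ma[k, ]; vb <- mb[k, ]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2)
      stop_data("fewer than 2 sites per condition in band ", k)
    same <- isTRUE(all.equal(va, vb)) || (sd(va) == 0 && sd(vb) == 0)
    tt <- if (!same) t.test(vb, va) else NULL
    data.frame(lo = bands[[k]][1], hi = bands[[k]][2],
               mean_A = mean(va), mean_B = mean(vb),
               difference = mean(vb) - mean(va),
               t = if (same) NaN else unname(tt$statistic),
               p = if (same) 1 else tt$p.value,
               n_A = length(va), n_B = length(vb))
  })
  structure(list(table = do.call(rbind, per_band),
                 per_site_A = ma, per_site_B = mb, bands = bands),
            class = "band_difference_result")
}

#' @export
print.band_difference_result <- function(x, ...) {
  cat("<band_difference_result> condition B minus condition A\n")
  tb <- x$table
  for (k in seq_len(nrow(tb)))
    cat(sprintf("  band [%s, %s): difference %.3g (t=%.3g, p=%s, n=%d/%d)\n",
                fmt_bp(tb$lo[k]), fmt_bp(tb$hi[k]), tb$difference[k], tb$t[k],
                format.pval(tb$p[k], digits = 3), tb$n_A[k], tb$n_B[k]))
  invisible(x)
}
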