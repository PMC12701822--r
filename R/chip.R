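#' Site-averaged ChIP meta-profile
#'
#' Averages RPM coverage around cut sites on a signed-distance axis and
#' subtracts the untreated average from the treated one. Native bins are
#' re-binned to `out_bin` by summation (so values are RPM per `out_bin`);
#' the axis is symmetric about the cut with an odd number of bins. Sites
#' whose window leaves the chromosome are excluded; the axis is oriented
#' genomically (no per-site strand flipping).
#'
#' @param treated,untreated `stranded_coverage` objects or named lists per
#'   chromosome, on identical native bins.
#' @param sites a `cut_sites`.
#' @param half_width half window, bp; multiple of `out_bin`.
#' @param out_bin output bin size, bp; integer multiple of the native bin.
#' @param strand_mode `"both"` (forward + reverse), `"forward"` or
#'   `"reverse"`.
#' @return a `meta_profile` (`dist`, `value`, `bin_size`, `n_sites`).
#' @export
meta_profile <- function(treated, untreated, sites, half_width, out_bin,
                         strand_mode = c("both", "forward", "reverse")) {
  strand_mode <- match.arg(strand_mode)
  tr <- if (inherits(treated, "stranded_coverage"))
    stats::setNames(list(treated), treated$chrom) else treated
  un <- if (inherits(untreated, "stranded_coverage"))
    stats::setNames(list(untreated), untreated$chrom) else untreated
  native <- tr[[1]]$bin_size
  if (out_bin %% native != 0) stop_data("out_bin must be an integer multiple of the native bin")
  if (half_width %% out_bin != 0) stop_data("half_width must be a multiple of out_bin")
  tr <- rpm_normalize(tr); un <- rpm_normalize(un)
  strand_vec <- function(cov) switch(strand_mode,
    both = cov$fwd + cov$rev, forward = cov$fwd, reverse = cov$rev)
  offs <- seq(-half_width, half_width, by = out_bin)
  site_rows <- function(covs) {
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      ch <- sites$chrom[i]
      if (!ch %in% names(covs)) return(NULL)
      v <- strand_vec(covs[[ch]])
      nb <- length(v)
      ## native bins whose centers fall in [pos+off-out_bin/2, pos+off+out_bin/2)
      L <- sites$pos[i] - half_width - out_bin / 2
      j0 <- ceiling(L / native - 0.5)   # 0-based first native bin with center >= L
      k <- out_bin / native
      need <- length(offs) * k
      if (j0 < 0 || j0 + need > nb) return(NULL)
      colSums(matrix(v[(j0 + 1):(j0 + need)], nrow = k))
    })
    rows[!vapply(rows, is.null, logical(1))]
  }
  rt <- site_rows(tr); ru <- site_rows(un)
  if (!length(rt) || !length(ru)) stop_data("no site with a full in-bounds window")
  structure(list(dist = offs,
                 value = Reduce(`+`, rt) / length(rt) -
                         Reduce(`+`, ru) / length(ru),
                 bin_size = out_bin, n_sites = length(rt),
                 normalization = "rpm_diff", strand = strand_mode),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("<meta_profile> ", x$strand, " strand(s), ", length(x$dist),
      " bins of ", fmt_bp(x$bin_size), " over +/-", fmt_bp(max(x$dist)),
      ", n=", x$n_sites, " sites; peak ", signif(max(x$value), 3),
      " RPM/bin at ", fmt_bp(x$dist[which.max(x$value)]), "\n", sep = "")
  invisible(x)
}

#' Two-component (narrow peak + broad domain) width estimation
#'
#' Fits `f(x) = c + A_n exp(-x^2 / 2 s_n^2) + A_b exp(-x^2 / 2 s_b^2)` to a
#' pair of meta-profiles spanning two scales, and reports each component's
#' FWHM (`2 sqrt(2 ln 2) * s`). Because the two widths are ~100x apart, a
#' joint fit lets the broad component swallow the narrow one; the default
#' two-stage scheme fits the broad component on the coarse profile with the
#' narrow region masked, then fits the narrow component on the fine profile
#' with the broad component held fixed. Both stages use
#' [minpack.lm::nlsLM()] with non-negative amplitude bounds and a
#' deterministic 5-point multi-start over the width initialization; the
#' best residual wins. Profiles are internally converted to per-bp density
#' so the two scales share units.
#'
#' @param fine `meta_profile` with bin <= 200 bp covering at least
#'   +/- 15 kb.
#' @param coarse `meta_profile` with bin <= 10 kb covering at least
#'   +/- 1.5 Mb.
#' @param two_stage set `FALSE` for a single-stage joint fit on the
#'   concatenated profiles.
#' @param maxiter,tol iteration cap and convergence tolerance.
#' @return a `two_component_fit` with background, per-component amplitude
#'   (per-bp density), FWHM and standard errors, residual norm and a
#'   convergence flag. `coef()` returns the named parameter vector.
#' @export
fit_two_component <- function(fine, coarse, two_stage = TRUE,
                              maxiter = 500, tol = 1e-8) {
  stopifnot(inherits(fine, "meta_profile"), inherits(coarse, "meta_profile"))
  if (fine$bin_size > 200) stop_data("fine profile bin must be <= 200 bp")
  if (coarse$bin_size > 1e4) stop_data("coarse profile bin must be <= 10 kb")
  if (max(fine$dist) < 1.5e4) stop_data("fine profile must span >= +/-15 kb")
  if (max(coarse$dist) < 1.5e6) stop_data("coarse profile must span >= +/-1.5 Mb")
  fx <- fine$dist;  fy <- fine$value / fine$bin_size
  cx <- coarse$dist; cy <- coarse$value / coarse$bin_size
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = tol, ptol = tol)
  gauss <- function(x, s) exp(-x^2 / (2 * s^2))
  fit_once <- function(formula, data, start, lower, upper) {
    tryCatch(minpack.lm::nlsLM(formula, data = data, start = start,
                               lower = lower, upper = upper, control = ctrl),
             error = function(e) NULL)
  }
  best_of <- function(fits) {
    ok <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(ok)) return(NULL)
    ok[[which.min(vapply(ok, function(f) sum(residuals(f)^2), numeric(1)))]]
  }
  sn_inits <- max(fx) * c(0.05, 0.1, 0.2, 0.3, 0.5)
  sb_inits <- max(cx) * c(0.05, 0.1, 0.15, 0.25, 0.4)
  if (two_stage) {
    ## stage 1: broad on coarse, narrow region masked
    mask <- 3 * stats::median(sn_inits)
    keep <- abs(cx) > mask
    d1 <- data.frame(x = cx[keep], y = cy[keep])
    c0 <- stats::median(d1$y)
    ab0 <- max(max(d1$y) - c0, 1e-12)
    f1 <- best_of(lapply(sb_inits, function(s0)
      fit_once(y ~ c + ab * exp(-x^2 / (2 * sb^2)), d1,
               start = list(c = c0, ab = ab0, sb = s0),
               lower = c(-Inf, 0, coarse$bin_size),
               upper = c(Inf, Inf, max(cx) * 2))))
    if (is.null(f1)) {
      ## signal-free profile: the Gaussian gradient is singular at ab = 0;
      ## fall back to the constant model with a zero-amplitude component
      p1 <- c(c = mean(d1$y), ab = 0, sb = stats::median(sb_inits))
      v1 <- c(stats::var(d1$y) / nrow(d1), NA_real_, NA_real_)
      f1 <- NULL
      conv1 <- TRUE; rss1 <- sum((d1$y - p1[["c"]])^2)
    } else {
      conv1 <- isTRUE(f1$convInfo$isConv); rss1 <- sum(residuals(f1)^2)
      v1 <- tryCatch(diag(stats::vcov(f1)), error = function(e) rep(NA_real_, 3))
      p1 <- coef(f1)
    }
    ## stage 2: narrow on fine, broad + background fixed
    base <- p1[["c"]] + p1[["ab"]] * gauss(fx, p1[["sb"]])
    d2 <- data.frame(x = fx, y = fy - base)
    an0 <- max(max(d2$y), 1e-12)
    f2 <- best_of(lapply(sn_inits, function(s0)
      fit_once(y ~ c2 + an * exp(-x^2 / (2 * sn^2)), d2,
               start = list(c2 = 0, an = an0, sn = s0),
               lower = c(-Inf, 0, fine$bin_size / 2),
               upper = c(Inf, Inf, p1[["sb"]]))))
    if (is.null(f2)) {
      p2 <- c(c2 = mean(d2$y), an = 0, sn = stats::median(sn_inits))
      v2 <- c(stats::var(d2$y) / nrow(d2), NA_real_, NA_real_)
      conv2 <- TRUE; rss2 <- sum((d2$y - p2[["c2"]])^2)
    } else {
      conv2 <- isTRUE(f2$convInfo$isConv); rss2 <- sum(residuals(f2)^2)
      v2 <- tryCatch(diag(stats::vcov(f2)), error = function(e) rep(NA_real_, 3))
      p2 <- coef(f2)
    }
    conv <- conv1 && conv2
    res <- sqrt(rss1 + rss2)
    out <- list(background = unname(p1[["c"]]),
                narrow_amplitude = unname(p2[["an"]]),
                narrow_sd = unname(p2[["sn"]]),
                narrow_sd_se = sqrt(unname(v2[3])),
                broad_amplitude = unname(p1[["ab"]]),
                broad_sd = unname(p1[["sb"]]),
                broad_sd_se = sqrt(unname(v1[3])))
  } else {
    d <- data.frame(x = c(fx, cx), y = c(fy, cy))
    c0 <- stats::median(cy)
    starts <- mapply(function(sn0, sb0) list(c = c0, an = max(fy) - c0,
                                             sn = sn0, ab = max(cy) - c0, sb = sb0),
                     sn_inits, sb_inits, SIMPLIFY = FALSE)
    f <- best_of(lapply(starts, function(s)
      fit_once(y ~ c + an * exp(-x^2 / (2 * sn^2)) + ab * exp(-x^2 / (2 * sb^2)),
               d, start = s,
               lower = c(-Inf, 0, fine$bin_size / 2, 0, coarse$bin_size),
               upper = c(Inf, Inf, Inf, Inf, max(cx) * 2))))
    if (is.null(f)) stop_data("joint two-component fit failed on all starts")
    p <- coef(f); v <- tryCatch(diag(stats::vcov(f)), error = function(e) rep(NA_real_, 5))
    conv <- isTRUE(f$convInfo$isConv)
    res <- sqrt(sum(residuals(f)^2))
    out <- list(background = unname(p[["c"]]),
                narrow_amplitude = unname(p[["an"]]), narrow_sd = unname(p[["sn"]]),
                narrow_sd_se = sqrt(unname(v[3])),
                broad_amplitude = unname(p[["ab"]]), broad_sd = unname(p[["sb"]]),
                broad_sd_se = sqrt(unname(v[5])))
  }
  if (out$narrow_sd >= out$broad_sd) {
    warning("narrow component not narrower than broad component; fit is degenerate")
    conv <- FALSE
  }
  k <- 2 * sqrt(2 * log(2))
  structure(c(out, list(narrow_fwhm = k * out$narrow_sd,
                        narrow_fwhm_se = k * out$narrow_sd_se,
                        broad_fwhm = k * out$broad_sd,
                        broad_fwhm_se = k * out$broad_sd_se,
                        residual_norm = res, converged = conv,
                        two_stage = two_stage)),
            class = "two_component_fit")
}

#' @export
print.two_component_fit <- function(x, ...) {
  cat("Two-component enrichment fit (", if (x$two_stage) "two-stage" else "joint",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  cat(sprintf("  narrow: FWHM %.3g kb (se %.2g), amplitude %.3g\n",
              x$narrow_fwhm / 1e3, x$narrow_fwhm_se / 1e3, x$narrow_amplitude))
  cat(sprintf("  broad:  FWHM %.3g kb (se %.2g), amplitude %.3g\n",
              x$broad_fwhm / 1e3, x$broad_fwhm_se / 1e3, x$broad_amplitude))
  cat(sprintf("  background %.3g, residual norm %.3g\n",
              x$background, x$residual_norm))
  invisible(x)
}

#' @exportS3Method stats::coef
coef.two_component_fit <- function(object, ...) {
  c(background = object$background,
    narrow_amplitude = object$narrow_amplitude, narrow_sd = object$narrow_sd,
    broad_amplitude = object$broad_amplitude, broad_sd = object$broad_sd)
}

#' @exportS3Method base::summary
summary.two_component_fit <- function(object, ...) {
  df <- data.frame(
    component = c("narrow", "broad"),
    fwhm_bp = c(object$narrow_fwhm, object$broad_fwhm),
    fwhm_se_bp = c(object$narrow_fwhm_se, object$broad_fwhm_se),
    amplitude = c(object$narrow_amplitude, object$broad_amplitude))
  structure(list(table = df, background = object$background,
                 converged = object$converged), class = "summary.two_component_fit")
}

#' @export
print.summary.two_component_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Strand-specific asymmetry profile around cut sites
#'
#' Computes per-strand meta-profiles (treated minus untreated, RPM) and
#' their difference `forward - reverse`. Resection loads the recombinase on
#' 3' single-stranded tails, so the asymmetry switches polarity at the
#' break; the switch position is the zero crossing of the sign-smoothed
#' asymmetry nearest the cut, and the extent is the total span of the
#' above-threshold lobes flanking the cut (threshold a fraction of the
#' maximum absolute asymmetry).
#'
#' @inheritParams meta_profile
#' @param threshold lobe threshold as a fraction of `max(|asymmetry|)`.
#' @return an `asymmetry_profile` with `dist`, `value`, `switch_pos`,
#'   `extent` (bp) and a degeneracy flag.
#' @export
strand_asymmetry <- function(treated, untreated, sites, half_width, out_bin,
                             threshold = 0.1) {
  f <- meta_profile(treated, untreated, sites, half_width, out_bin, "forward")
  r <- meta_profile(treated, untreated, sites, half_width, out_bin, "reverse")
  a <- f$value - r$value
  x <- f$dist
  if (all(a == 0)) {
    return(structure(list(dist = x, value = a, switch_pos = NA_real_,
                          extent = 0, threshold = threshold,
                          n_sites = f$n_sites,
                          flag = "all-zero asymmetry; switch undefined"),
                     class = "asymmetry_profile"))
  }
  ## polarity switch: zero crossing of the 3-bin sign-smoothed track nearest 0
  s <- sign(a)
  sm <- stats::filter(s, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- s[is.na(sm)]
  cross <- which(sm[-length(sm)] * sm[-1] < 0)
  switch_pos <- if (length(cross)) {
    mid <- (x[cross] + x[cross + 1]) / 2
    mid[which.min(abs(mid))]
  } else NA_real_
  ## extent: span of the contiguous above-threshold lobes flanking the cut
  hi <- abs(a) >= threshold * max(abs(a))
  ctr <- which.min(abs(x))
  lobe_edge <- function(dir) {
    i <- ctr
    while (i + dir >= 1 && i + dir <= length(x) && !hi[i]) i <- i + dir
    if (!hi[i]) return(NA_integer_)
    while (i + dir >= 1 && i + dir <= length(x) && hi[i + dir]) i <- i + dir
    i
  }
  le <- lobe_edge(-1L); re <- lobe_edge(1L)
  extent <- if (is.na(le) || is.na(re)) 0 else
    (x[re] + out_bin / 2) - (x[le] - out_bin / 2)
  structure(list(dist = x, value = a, switch_pos = switch_pos,
                 extent = extent, threshold = threshold,
                 n_sites = f$n_sites, flag = NA_character_),
            class = "asymmetry_profile")
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat("<asymmetry_profile> n=", x$n_sites, " sites; polarity switch at ",
      if (is.na(x$switch_pos)) "NA" else fmt_bp(x$switch_pos),
      ", extent ", fmt_bp(x$extent), " (threshold ",
      x$threshold * 100, "% of max)\n", sep = "")
  if (!is.na(x$flag)) cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}

#' Write a meta or asymmetry profile as TSV
#'
#' Two-column TSV (`dist`, `value`) with `#key=value` metadata header
#' lines.
#'
#' @param profile a `meta_profile` or `asymmetry_profile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  meta <- c(paste0("#class=", class(profile)[1]),
            paste0("#n_sites=", profile$n_sites))
  if (!is.null(profile$bin_size))
    meta <- c(meta, paste0("#bin_size=", format(profile$bin_size, scientific = FALSE)))
  if (!is.null(profile$extent))
    meta <- c(meta, paste0("#extent=", profile$extent),
              paste0("#switch_pos=", profile$switch_pos))
  writeLines(meta, path)
  data.table::fwrite(data.frame(dist = profile$dist, value = profile$value),
                     path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
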