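#' Expected (noise-free) stranded ChIP tracks of the generative model
#'
#' Untreated expectation is flat background `b` per bin, split 1:1 across
#' strands. The treated expectation adds, per cut site, a narrow Gaussian
#' component (total mass `narrow_reads`, s.d. `narrow_sd`) and a broad
#' Gaussian domain (mass `broad_reads`, s.d. `broad_sd`), the broad
#' component truncated at the first TAD boundary on each side of the cut
#' when enabled. Within `resection_span` of the cut, a fraction
#' `asym_fraction` of narrow-component reads is assigned to the strand
#' matching 3' resection polarity: forward-dominant on the telomeric
#' (right) side, reverse-dominant on the centromeric (left) side.
#'
#' @param params a [sim_params()].
#' @param chrom chromosome name.
#' @param sites a `cut_sites`.
#' @param boundaries data frame (`chrom`, `pos`) of TAD boundaries used for
#'   truncation; defaults to the edges of `params$tads`.
#' @param treated logical.
#' @return list with numeric vectors `fwd` and `rev` of expected reads/bin.
#' @export
expected_chip_tracks <- function(params, chrom, sites, boundaries = NULL,
                                 treated = TRUE) {
  validate_params(params)
  len <- params$genome[[chrom]]
  if (is.null(len)) stop_data("chromosome ", chrom, " not in genome spec")
  if (is.null(boundaries)) boundaries <- tad_boundaries(params)
  bs <- params$chip_bin_size
  n <- as.integer(ceiling(len / bs))
  centers <- (seq_len(n) - 0.5) * bs
  fwd <- rep(params$background / 2, n)
  rev <- rep(params$background / 2, n)
  if (!treated) return(list(fwd = fwd, rev = rev))
  bnd <- boundaries$pos[boundaries$chrom == chrom]
  for (pos in sites$pos[sites$chrom == chrom]) {
    ## evaluate each Gaussian only within +/- 6 sd (beyond that the
    ## density underflows any count scale used here)
    reach <- ceiling(6 * params$broad_sd / bs)
    cb <- pos_to_bin(pos, bs)
    idx <- max(1L, cb - reach):min(n, cb + reach)
    x <- centers[idx] - pos
    narrow <- params$narrow_reads * dnorm(x, 0, params$narrow_sd) * bs
    broad <- params$broad_reads * dnorm(x, 0, params$broad_sd) * bs
    if (params$truncate_at_boundaries && length(bnd)) {
      lb <- if (any(bnd < pos)) max(bnd[bnd < pos]) else -Inf
      rb <- if (any(bnd > pos)) min(bnd[bnd > pos]) else Inf
      broad[centers[idx] < lb | centers[idx] >= rb] <- 0
    }
    ## strand split: symmetric except the narrow component inside the
    ## resection span, where polarity follows the resected 3' ends
    f_share <- rep(0.5, length(idx))
    in_span <- abs(x) <= params$resection_span & x != 0
    f_share[in_span & x > 0] <- (1 + params$asym_fraction) / 2
    f_share[in_span & x < 0] <- (1 - params$asym_fraction) / 2
    fwd[idx] <- fwd[idx] + broad / 2 + narrow * f_share
    rev[idx] <- rev[idx] + broad / 2 + narrow * (1 - f_share)
  }
  list(fwd = fwd, rev = rev)
}

#' Simulate a treated/untreated stranded ChIP coverage pair
#'
#' Poisson-samples per bin and strand around the expected tracks of
#' [expected_chip_tracks()]. When `params$depth` is set, both conditions'
#' expectations are first rescaled so each library's expected genome-wide
#' total equals `depth` (as if sequenced to a fixed depth); otherwise the
#' natural scale of `background`/`narrow_reads`/`broad_reads` is kept.
#' Library sizes record the realized genome-wide totals.
#'
#' @inheritParams expected_chip_tracks
#' @return list with `treated` and `untreated` (named lists of
#'   `stranded_coverage` per chromosome) and `truth` (a `sim_truth`).
#' @export
simulate_chip_pair <- function(params, sites, boundaries = NULL) {
  validate_params(params)
  if (is.null(boundaries)) boundaries <- tad_boundaries(params)
  warnings <- character()
  for (ch in unique(sites$chrom)) {
    sp <- sort(sites$pos[sites$chrom == ch])
    if (length(sp) > 1 && any(diff(sp) < 2 * params$broad_sd))
      warnings <- c(warnings, paste0(
        "cut sites on ", ch, " closer than 2*broad_sd; domains superpose"))
  }
  chroms <- names(params$genome)
  exp_tracks <- lapply(c(TRUE, FALSE), function(tr)
    lapply(stats::setNames(chroms, chroms), function(ch)
      expected_chip_tracks(params, ch, sites, boundaries, treated = tr)))
  names(exp_tracks) <- c("treated", "untreated")
  if (!is.na(params$depth)) {
    for (cond in names(exp_tracks)) {
      tot <- sum(vapply(exp_tracks[[cond]],
                        function(t) sum(t$fwd) + sum(t$rev), numeric(1)))
      f <- params$depth / tot
      exp_tracks[[cond]] <- lapply(exp_tracks[[cond]], function(t)
        list(fwd = t$fwd * f, rev = t$rev * f))
    }
  }
  out <- lapply(names(exp_tracks), function(cond) {
    covs <- lapply(chroms, function(ch) {
      e <- exp_tracks[[cond]][[ch]]
      seed <- derive_seed(params$seed, paste0("chip/", ch, "/", cond))
      with_seed(seed, list(fwd = rpois(length(e$fwd), e$fwd),
                           rev = rpois(length(e$rev), e$rev)))
    })
    lib <- sum(vapply(covs, function(x) sum(x$fwd) + sum(x$rev), numeric(1)))
    stats::setNames(lapply(seq_along(chroms), function(i)
      stranded_coverage(chroms[i], params$chip_bin_size,
                        covs[[i]]$fwd, covs[[i]]$rev, lib, sample = cond)),
      chroms)
  })
  names(out) <- names(exp_tracks)
  list(treated = out$treated, untreated = out$untreated,
       truth = sim_truth(params, sites, boundaries, warnings = warnings))
}
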