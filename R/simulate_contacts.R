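#' Expected (noise-free) contact matrix of the generative model
#'
#' Builds the mean matrix the Poisson sampler draws from: power-law
#' distance decay `A * ((s + s0)/s0)^(-alpha)`, multiplied by the within-TAD
#' factor for same-TAD pairs and by the boundary-insulation factor once per
#' TAD boundary separating a pair; in the treated condition, pairs with one
#' end in a cut-site bin and the other within the stripe extent gain the
#' factor `1 + k * (1 - d/L)`, and pairs whose ends flank the cut bin are
#' attenuated by the cross-cut factor.
#'
#' Exposed so tests and oracles can compare realized statistics against the
#' analytic means.
#'
#' @param params a [sim_params()].
#' @param chrom chromosome name in `params$genome`.
#' @param sites a `cut_sites` (only sites on `chrom` are used).
#' @param treated logical; apply the break perturbation.
#' @return numeric matrix of expected counts.
#' @export
expected_contact_matrix <- function(params, chrom, sites, treated) {
  validate_params(params)
  len <- params$genome[[chrom]]
  if (is.null(len)) stop_data("chromosome ", chrom, " not in genome spec")
  bs <- params$contact_bin_size
  n <- as.integer(ceiling(len / bs))
  idx <- seq_len(n)
  centers <- (idx - 0.5) * bs
  sep <- abs(outer(idx, idx, "-")) * bs
  E <- params$base_intensity *
    ((sep + params$decay_offset) / params$decay_offset)^(-params$decay_exponent)
  ## TAD structure
  tads <- params$tads[[chrom]]
  tid <- rep(0L, n)
  for (k in seq_len(nrow(tads)))
    tid[centers >= tads[k, 1] & centers < tads[k, 2]] <- k
  same <- outer(tid, tid, "==") & tid > 0
  E[same] <- E[same] * params$tad_multiplier
  bnd <- tad_boundaries(params)
  bnd <- bnd$pos[bnd$chrom == chrom]
  if (length(bnd)) {
    cum <- vapply(centers, function(x) sum(bnd <= x), integer(1))
    ncross <- abs(outer(cum, cum, "-"))
    E <- E * params$boundary_insulation^ncross
  }
  if (treated) {
    sp <- sites$pos[sites$chrom == chrom]
    bad <- sp < 0 | sp >= len
    if (any(bad))
      stop_data("cut site at ", paste(sp[bad], collapse = ", "),
                " outside chromosome ", chrom)
    for (pos in sp) {
      cb <- pos_to_bin(pos, bs)
      d <- abs(idx - cb) * bs
      fac <- 1 + params$stripe_strength *
        pmax(0, 1 - d / params$stripe_extent) * (d <= params$stripe_extent)
      E[cb, ] <- E[cb, ] * fac
      E[, cb] <- E[, cb] * fac
      ## the cut-bin self pair picked up the factor twice; undo one
      E[cb, cb] <- E[cb, cb] / fac[cb]
      if (params$cut_attenuation < 1 && cb > 1 && cb < n) {
        left <- idx < cb; right <- idx > cb
        E[left, right] <- E[left, right] * params$cut_attenuation
        E[right, left] <- E[right, left] * params$cut_attenuation
      }
    }
  }
  E
}

#' Simulate a treated/untreated contact-map pair
#'
#' Draws independent Poisson counts per upper-triangle bin around the
#' expected matrices of [expected_contact_matrix()] and symmetrizes. The
#' untreated map carries the TAD landscape only; the treated map adds the
#' break-anchored stripe and cross-break attenuation at every cut site.
#'
#' @param params a [sim_params()].
#' @param sites a `cut_sites`; all must lie within the genome spec.
#' @return list with `treated` and `untreated` (named lists of
#'   `contact_map`, one per chromosome) and `truth` (a `sim_truth`).
#' @export
simulate_contact_pair <- function(params, sites) {
  validate_params(params)
  bad <- !(sites$chrom %in% names(params$genome)) |
    sites$pos < 0 | sites$pos >= params$genome[sites$chrom]
  if (any(bad))
    stop_data("cut site ", sites$chrom[bad][1], ":", sites$pos[bad][1],
              " outside the genome spec")
  sample_one <- function(chrom, treated) {
    E <- expected_contact_matrix(params, chrom, sites, treated)
    n <- nrow(E)
    seed <- derive_seed(params$seed,
                        paste0("hic/", chrom, "/", if (treated) "T" else "U"))
    X <- matrix(0, n, n)
    ut <- upper.tri(E, diag = TRUE)
    X[ut] <- with_seed(seed, rpois(sum(ut), E[ut]))
    lt <- lower.tri(X)
    X[lt] <- t(X)[lt]
    contact_map(chrom, params$contact_bin_size, X,
                partial_bin = params$genome[[chrom]] %% params$contact_bin_size != 0)
  }
  chroms <- names(params$genome)
  treated <- lapply(chroms, sample_one, treated = TRUE)
  untreated <- lapply(chroms, sample_one, treated = FALSE)
  names(treated) <- names(untreated) <- chroms
  list(treated = treated, untreated = untreated,
       truth = sim_truth(params, sites, tad_boundaries(params)))
}
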