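#' Extract cut-site-centered contact windows
#'
#' For every site, pulls the square submatrix of `2*half_width/bin + 1`
#' bins centered on the bin containing the cut. Sites whose window crosses
#' a chromosome end are kept in the stack but flagged invalid and excluded
#' from all averages, so aggregation is invariant to their presence.
#'
#' @param map a `contact_map`, or a named list of them (one per
#'   chromosome, shared bin size).
#' @param sites a `cut_sites`.
#' @param half_width half window width in bp; multiple of the bin size.
#' @return a `window_stack`: 3-D array (bin x bin x site) with site ids,
#'   validity mask, bin size and half width.
#' @export
extract_windows <- function(map, sites, half_width) {
  maps <- if (inherits(map, "contact_map")) {
    stats::setNames(list(map), map$chrom)
  } else map
  bs <- maps[[1]]$bin_size
  stopifnot(all(vapply(maps, function(m) m$bin_size == bs, logical(1))))
  if (half_width %% bs != 0)
    stop_data("half_width must be a multiple of the bin size")
  hw <- as.integer(half_width / bs)
  w <- 2L * hw + 1L
  keep <- sites$chrom %in% names(maps)
  sites <- sites[keep, , drop = FALSE]
  nsite <- nrow(sites)
  arr <- array(NaN, dim = c(w, w, nsite))
  valid <- logical(nsite)
  for (i in seq_len(nsite)) {
    m <- maps[[sites$chrom[i]]]
    cb <- pos_to_bin(sites$pos[i], bs, m$origin)
    n <- nrow(m$counts)
    if (cb - hw >= 1L && cb + hw <= n) {
      arr[, , i] <- m$counts[(cb - hw):(cb + hw), (cb - hw):(cb + hw)]
      valid[i] <- TRUE
    }
  }
  if (!any(valid)) stop_data("no site has a full in-bounds window")
  structure(list(windows = arr, half_width = half_width, bin_size = bs,
                 site_id = paste0(sites$chrom, ":", sites$pos),
                 valid = valid),
            class = "window_stack")
}

#' Averaged log2-ratio differential contact map
#'
#' Per site, computes `log2((T + eps) / (U + eps))` elementwise on the
#' aligned treated/untreated windows, then averages across valid sites
#' ignoring NaN bins. The cross-shaped stripe of break-anchored contacts
#' appears as the row and column through the center bin.
#'
#' @param treated,untreated `window_stack`s on identical sites and shape.
#' @param epsilon pseudocount added to both conditions (default 1 count;
#'   the log2 ratio is undefined on zero bins).
#' @return an `aggregate_map` with the averaged matrix, `n` sites used and
#'   the pseudocount.
#' @export
differential_map <- function(treated, untreated, epsilon = 1) {
  stopifnot(inherits(treated, "window_stack"),
            inherits(untreated, "window_stack"))
  if (!identical(dim(treated$windows), dim(untreated$windows)) ||
      !identical(treated$site_id, untreated$site_id))
    stop_data("window stacks are not aligned on identical sites/shape")
  valid <- treated$valid & untreated$valid
  if (!any(valid)) stop_data("no jointly valid sites")
  lr <- log2((treated$windows[, , valid, drop = FALSE] + epsilon) /
             (untreated$windows[, , valid, drop = FALSE] + epsilon))
  avg <- apply(lr, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NaN
  })
  structure(list(matrix = avg, n = sum(valid), epsilon = epsilon,
                 op = "log2ratio", bin_size = treated$bin_size,
                 half_width = treated$half_width),
            class = "aggregate_map")
}

#' Mean aggregate of a window stack
#'
#' NaN-aware per-bin mean across valid sites (the plain pileup companion
#' of [differential_map()]).
#'
#' @param stack a `window_stack`.
#' @return an `aggregate_map` with op tag `"mean"`.
#' @export
aggregate_windows <- function(stack) {
  stopifnot(inherits(stack, "window_stack"))
  avg <- apply(stack$windows[, , stack$valid, drop = FALSE], c(1, 2),
               function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NaN })
  structure(list(matrix = avg, n = sum(stack$valid), epsilon = NA_real_,
                 op = "mean", bin_size = stack$bin_size,
                 half_width = stack$half_width),
            class = "aggregate_map")
}

#' @export
print.aggregate_map <- function(x, ...) {
  cat("<aggregate_map> ", x$op, " over ", x$n, " sites, ",
      nrow(x$matrix), "x", nrow(x$matrix), " bins of ", fmt_bp(x$bin_size),
      if (x$op == "log2ratio") paste0(", eps=", x$epsilon), "\n", sep = "")
  invisible(x)
}

#' Virtual-4C profile from a contact map
#'
#' Sums the contact rows of all bins overlapping the viewpoint interval and
#' returns the signed-distance profile over `+/- flank` around the
#' viewpoint's center bin.
#'
#' @param map a `contact_map`.
#' @param viewpoint length-2 numeric `[start, end)` in bp.
#' @param flank profile reach in bp, multiple of the bin size.
#' @param normalize `"none"` or `"per_million"` (of the map total).
#' @return a `v4c_profile` (signed distance axis, contact vector).
#' @export
virtual_4c <- function(map, viewpoint, flank, normalize = "none") {
  stopifnot(inherits(map, "contact_map"), length(viewpoint) == 2)
  bs <- map$bin_size
  if (flank %% bs != 0) stop_data("flank must be a multiple of the bin size")
  n <- nrow(map$counts)
  vb <- seq(pos_to_bin(viewpoint[1], bs, map$origin),
            pos_to_bin(viewpoint[2] - 1, bs, map$origin))
  if (any(vb < 1 | vb > n)) stop_data("viewpoint outside the contact map")
  rows <- map$counts[vb, , drop = FALSE]
  if (all(!is.finite(rows))) stop_data("viewpoint is fully masked")
  prof <- colSums(rows, na.rm = TRUE)
  prof[colSums(is.finite(rows)) == 0] <- NaN
  if (normalize == "per_million") {
    tot <- sum(map$counts[upper.tri(map$counts, diag = TRUE)], na.rm = TRUE)
    prof <- prof * 1e6 / tot
  }
  cb <- pos_to_bin(mean(viewpoint), bs, map$origin)
  fb <- as.integer(flank / bs)
  rel <- (-fb):fb
  vals <- rep(NaN, length(rel))
  ok <- cb + rel >= 1 & cb + rel <= n
  vals[ok] <- prof[cb + rel[ok]]
  structure(list(viewpoint = viewpoint, dist = rel * bs, value = vals,
                 normalization = normalize),
            class = "v4c_profile")
}

#' Differential (site-averaged) virtual-4C profile
#'
#' Averages treated and untreated profile sets NaN-aware across sites on a
#' shared axis and returns their difference (default) or log2 ratio.
#'
#' @param treated_profiles,untreated_profiles lists of `v4c_profile`s with
#'   matched axes (one per site).
#' @param mode `"difference"` or `"log2"`.
#' @param epsilon pseudocount for the log2 mode.
#' @return a `v4c_profile` of the aggregated differential signal.
#' @export
differential_4c <- function(treated_profiles, untreated_profiles,
                            mode = c("difference", "log2"), epsilon = 1) {
  mode <- match.arg(mode)
  ax <- treated_profiles[[1]]$dist
  all_ax <- c(treated_profiles, untreated_profiles)
  if (!all(vapply(all_ax, function(p) identical(p$dist, ax), logical(1))))
    stop_data("profile axes do not match")
  tm <- rowMeans(sapply(treated_profiles, `[[`, "value"), na.rm = TRUE)
  um <- rowMeans(sapply(untreated_profiles, `[[`, "value"), na.rm = TRUE)
  val <- if (mode == "difference") tm - um
         else log2((tm + epsilon) / (um + epsilon))
  structure(list(viewpoint = NULL, dist = ax, value = val,
                 normalization = paste0("aggregate_", mode)),
            class = "v4c_profile")
}

#' Cut-site-centered differential virtual-4C
#'
#' Convenience wrapper building per-site viewpoint profiles from matched
#' treated/untreated maps and aggregating them with [differential_4c()].
#' `viewpoint_mode = "flanking"` uses the two bins immediately left and
#' right of the cut bin, mirroring the left profile so positive distances
#' point away from the break on both sides, then averages the two;
#' `"center"` uses the cut bin itself (the break-anchored stripe lives in
#' the cut bin's own row).
#'
#' @param treated_maps,untreated_maps named lists of `contact_map` per
#'   chromosome.
#' @param sites a `cut_sites`.
#' @param flank profile reach, bp.
#' @param viewpoint_mode `"flanking"` or `"center"`.
#' @param normalize per-profile normalization, as [virtual_4c()].
#' @param mode aggregation mode, as [differential_4c()].
#' @return a `v4c_profile`.
#' @export
site_differential_4c <- function(treated_maps, untreated_maps, sites,
                                 flank, viewpoint_mode = c("flanking", "center"),
                                 normalize = "none",
                                 mode = c("difference", "log2")) {
  viewpoint_mode <- match.arg(viewpoint_mode)
  mode <- match.arg(mode)
  bs <- treated_maps[[1]]$bin_size
  one_side <- function(maps, chrom, pos, shift) {
    cb0 <- floor(pos / bs) * bs     # cut-bin start
    vp <- c(cb0 + shift * bs, cb0 + (shift + 1) * bs)
    p <- virtual_4c(maps[[chrom]], vp, flank, normalize)
    if (shift < 0) p$value <- rev(p$value)   # mirror: + points away from cut
    p
  }
  site_profiles <- function(maps) {
    lapply(seq_len(nrow(sites)), function(i) {
      ch <- sites$chrom[i]; pos <- sites$pos[i]
      if (viewpoint_mode == "center") {
        cb0 <- floor(pos / bs) * bs
        virtual_4c(maps[[ch]], c(cb0, cb0 + bs), flank, normalize)
      } else {
        l <- one_side(maps, ch, pos, -1L)
        r <- one_side(maps, ch, pos, 1L)
        l$value <- (l$value + r$value) / 2
        l
      }
    })
  }
  tp <- site_profiles(treated_maps)
  up <- site_profiles(untreated_maps)
  differential_4c(tp, up, mode = mode)
}
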