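#' Simulation parameters for the synthetic break-response generator
#'
#' Bundles every knob of the generative model: a power-law distance-decay
#' contact landscape with TAD blocks, a break-anchored cross-shaped stripe
#' and cross-break attenuation in the treated map, and ChIP coverage built
#' from background + narrow cut-site peak + broad surrounding domain with
#' strand asymmetry inside the resection span.
#'
#' The defaults encode the study conditions the analyses are calibrated
#' against: 25 kb contact bins, a ~1 Mb stripe extent, cross-break
#' attenuation 0.4, a narrow component with s.d. 2.5 kb and a broad
#' component with s.d. 250 kb (FWHM about 5.9 kb and 590 kb), a 1 kb
#' resection span per side with asymmetry fraction 0.8, and TAD blocks of
#' 0.6-1.2 Mb.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param contact_bin_size contact-map bin size, bp.
#' @param decay_exponent power-law exponent `alpha` of the distance decay.
#' @param decay_offset offset `s0` (bp): expected counts follow
#'   `A * ((s + s0)/s0)^(-alpha)` at separation `s`.
#' @param base_intensity `A`, expected counts at separation 0.
#' @param tads list (named by chromosome) of two-column matrices of TAD
#'   `[start, end)` intervals in bp, or `NULL` to tile each chromosome with
#'   blocks of `tad_sizes`.
#' @param tad_sizes cycle of TAD sizes (bp) used when `tads` is `NULL`.
#' @param tad_multiplier within-TAD contact multiplier, >= 1.
#' @param boundary_insulation multiplicative attenuation in (0, 1] applied
#'   once per TAD boundary separating a bin pair.
#' @param stripe_strength `k`, strength of the break-anchored stripe (>= 0).
#' @param stripe_extent stripe reach `L` in bp; the stripe kernel decays
#'   linearly to zero at `L`.
#' @param cut_attenuation multiplicative factor in (0, 1] applied to pairs
#'   spanning a cut site in the treated map.
#' @param chip_bin_size native ChIP coverage bin size, bp.
#' @param background expected background reads per ChIP bin.
#' @param narrow_reads,narrow_sd expected total reads and Gaussian s.d. (bp)
#'   of the narrow cut-site peak, per site.
#' @param broad_reads,broad_sd expected total reads and Gaussian s.d. (bp)
#'   of the broad domain, per site.
#' @param resection_span span `rho` (bp, per side of the cut) within which
#'   narrow-peak reads are strand-assigned asymmetrically.
#' @param asym_fraction fraction `phi` in `[0, 1]` of narrow reads within the
#'   resection span assigned to the resection-polarity strand.
#' @param depth target expected total reads per ChIP sample; `NA` keeps the
#'   natural scale of `background`/`narrow_reads`/`broad_reads`.
#' @param truncate_at_boundaries logical; drop the broad component beyond the
#'   first TAD boundary on each side of the cut.
#' @param seed integer seed; all draws of a simulation call flow from it.
#' @return an object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(genome = c(chrA = 60e6, chrB = 60e6),
                       contact_bin_size = 25e3,
                       decay_exponent = 1,
                       decay_offset = 25e3,
                       base_intensity = 60,
                       tads = NULL,
                       tad_sizes = c(8e5, 1.2e6, 6e5, 1e6),
                       tad_multiplier = 2,
                       boundary_insulation = 0.5,
                       stripe_strength = 2,
                       stripe_extent = 1e6,
                       cut_attenuation = 0.4,
                       chip_bin_size = 100,
                       background = 10,
                       narrow_reads = 2e4,
                       narrow_sd = 2.5e3,
                       broad_reads = 1e5,
                       broad_sd = 2.5e5,
                       resection_span = 1e3,
                       asym_fraction = 0.8,
                       depth = NA_real_,
                       truncate_at_boundaries = TRUE,
                       seed = 1L) {
  p <- list(genome = genome, contact_bin_size = contact_bin_size,
            decay_exponent = decay_exponent, decay_offset = decay_offset,
            base_intensity = base_intensity, tads = tads,
            tad_sizes = tad_sizes, tad_multiplier = tad_multiplier,
            boundary_insulation = boundary_insulation,
            stripe_strength = stripe_strength, stripe_extent = stripe_extent,
            cut_attenuation = cut_attenuation, chip_bin_size = chip_bin_size,
            background = background, narrow_reads = narrow_reads,
            narrow_sd = narrow_sd, broad_reads = broad_reads,
            broad_sd = broad_sd, resection_span = resection_span,
            asym_fraction = asym_fraction, depth = depth,
            truncate_at_boundaries = truncate_at_boundaries,
            seed = as.integer(seed))
  if (is.null(p$tads)) p$tads <- default_tads(p)
  class(p) <- "sim_params"
  validate_params(p)
  p
}

## regular-ish TAD tiling: block sizes cycle through tad_sizes, snapped to
## contact bins so boundaries align with bin edges
default_tads <- function(p) {
  bs <- p$contact_bin_size
  sizes <- round(p$tad_sizes / bs) * bs
  lapply(p$genome, function(len) {
    edges <- 0
    i <- 0L
    while (tail(edges, 1L) < len) {
      i <- i + 1L
      edges <- c(edges, min(tail(edges, 1L) + sizes[(i - 1L) %% length(sizes) + 1L], len))
    }
    cbind(start = head(edges, -1L), end = edges[-1L])
  })
}

validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (is.null(names(p$genome)) || any(!nzchar(names(p$genome))))
    stop_data("genome chromosomes must be named")
  if (any(p$genome <= 0)) stop_data("chromosome lengths must be positive")
  for (f in c("contact_bin_size", "decay_offset", "base_intensity",
              "stripe_extent", "chip_bin_size", "narrow_sd", "broad_sd",
              "resection_span"))
    if (p[[f]] <= 0) stop_data(f, " must be > 0")
  if (p$decay_exponent <= 0) stop_data("decay_exponent must be > 0")
  if (p$narrow_sd >= p$broad_sd) stop_data("narrow_sd must be < broad_sd")
  if (p$asym_fraction < 0 || p$asym_fraction > 1)
    stop_data("asym_fraction must lie in [0, 1]")
  if (p$tad_multiplier < 1) stop_data("tad_multiplier must be >= 1")
  if (p$boundary_insulation <= 0 || p$boundary_insulation > 1)
    stop_data("boundary_insulation must lie in (0, 1]")
  if (p$cut_attenuation <= 0 || p$cut_attenuation > 1)
    stop_data("cut_attenuation must lie in (0, 1]")
  if (p$stripe_strength < 0) stop_data("stripe_strength must be >= 0")
  if (!setequal(names(p$tads), names(p$genome)))
    stop_data("tads must cover exactly the genome's chromosomes")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic break-response parameters\n")
  cat("  genome: ", paste0(names(x$genome), " (", fmt_bp(x$genome), ")",
                           collapse = ", "), "\n", sep = "")
  cat("  contacts: bin ", fmt_bp(x$contact_bin_size),
      ", decay alpha ", x$decay_exponent,
      ", stripe k=", x$stripe_strength, " over ", fmt_bp(x$stripe_extent),
      ", cross-cut x", x$cut_attenuation, "\n", sep = "")
  cat("  ChIP: bin ", fmt_bp(x$chip_bin_size),
      ", narrow sd ", fmt_bp(x$narrow_sd), ", broad sd ", fmt_bp(x$broad_sd),
      ", resection ", fmt_bp(x$resection_span), "/side, phi ",
      x$asym_fraction, "\n", sep = "")
  invisible(x)
}

#' Record of a simulation's generative truth
#'
#' Captures the parameters, realized cut sites and TAD boundaries, and the
#' seed of a simulation, so downstream estimates can be checked against the
#' injected truth and the run regenerated bit-identically.
#'
#' @param params the `sim_params` used.
#' @param sites the realized `cut_sites` data frame.
#' @param boundaries data frame of TAD boundary positions (chrom, pos).
#' @param warnings character vector of generator warnings.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(params, sites, boundaries, warnings = character()) {
  structure(list(params = params, sites = sites, boundaries = boundaries,
                 seed = params$seed, warnings = warnings),
            class = "sim_truth")
}

#' Write / read a simulation truth record (YAML)
#'
#' The record round-trips losslessly: regenerating with the reread
#' parameters and seed reproduces the original data bit-for-bit.
#'
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @return `read_truth` returns a `sim_truth`; `write_truth` its path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  p <- truth$params
  p$tads <- lapply(p$tads, function(m) list(start = as.numeric(m[, 1]),
                                            end = as.numeric(m[, 2])))
  p$genome <- as.list(p$genome)
  obj <- list(params = unclass(p),
              sites = as.list(as.data.frame(truth$sites)),
              boundaries = as.list(truth$boundaries),
              seed = truth$seed,
              warnings = as.list(truth$warnings))
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::yaml.load_file(path)
  p <- obj$params
  p$genome <- unlist(p$genome)
  p$tads <- lapply(p$tads, function(t) cbind(start = unlist(t$start),
                                             end = unlist(t$end)))
  p$depth <- if (is.null(p$depth)) NA_real_ else as.numeric(p$depth)
  p$seed <- as.integer(p$seed)
  class(p) <- "sim_params"
  validate_params(p)
  sites <- as.data.frame(lapply(obj$sites, unlist), stringsAsFactors = FALSE)
  class(sites) <- c("cut_sites", "data.frame")
  bnd <- as.data.frame(lapply(obj$boundaries, unlist), stringsAsFactors = FALSE)
  sim_truth(p, sites, bnd, warnings = as.character(unlist(obj$warnings)))
}
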