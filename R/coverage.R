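#' Stranded binned ChIP coverage
#'
#' Per-bin read counts for the forward and reverse strand of one
#' chromosome, with the genome-wide library size (total mapped reads) used
#' for RPM normalization.
#'
#' @param chrom chromosome name.
#' @param bin_size bin size, bp.
#' @param fwd,rev numeric vectors of per-bin counts (equal length, >= 0).
#' @param library_size total mapped reads of the library.
#' @param sample sample tag.
#' @param normalization `"counts"` or `"rpm"`.
#' @return object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(chrom, bin_size, fwd, rev, library_size,
                              sample = "sample", normalization = "counts") {
  if (length(fwd) != length(rev)) stop_data("strand vectors differ in length")
  if (any(fwd < 0, na.rm = TRUE) || any(rev < 0, na.rm = TRUE))
    stop_data("coverage counts must be non-negative")
  if (normalization == "counts" &&
      library_size < sum(fwd, na.rm = TRUE) + sum(rev, na.rm = TRUE) - 1e-6)
    stop_data("library size smaller than chromosome totals")
  structure(list(chrom = as.character(chrom), bin_size = bin_size,
                 fwd = as.numeric(fwd), rev = as.numeric(rev),
                 library_size = library_size, sample = sample,
                 normalization = normalization),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("<stranded_coverage> ", x$sample, " ", x$chrom, ": ",
      length(x$fwd), " bins of ", fmt_bp(x$bin_size), " (", x$normalization,
      "), library ", format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' Scales both strand vectors by `1e6 / library_size` and tags the object
#' `rpm`. Idempotent input check: already-RPM coverage is returned as is.
#'
#' @param cov a `stranded_coverage` (or named list of them, normalized
#'   element-wise).
#' @return the normalized object(s).
#' @export
rpm_normalize <- function(cov) {
  if (is.list(cov) && !inherits(cov, "stranded_coverage"))
    return(lapply(cov, rpm_normalize))
  stopifnot(inherits(cov, "stranded_coverage"))
  if (cov$normalization == "rpm") return(cov)
  if (cov$library_size <= 0) stop_data("zero library size")
  f <- 1e6 / cov$library_size
  stranded_coverage(cov$chrom, cov$bin_size, cov$fwd * f, cov$rev * f,
                    cov$library_size, cov$sample, normalization = "rpm")
}

#' Damage-induced enrichment track
#'
#' Combined-strand treated minus untreated coverage in RPM, the per-bin
#' enrichment signal all site/boundary statistics are computed from.
#'
#' @param treated,untreated `stranded_coverage` objects (or matched named
#'   lists per chromosome) on identical bins.
#' @return an `enrichment_track` (chrom, bin_size, value) or a named list
#'   of them.
#' @export
enrichment_track <- function(treated, untreated) {
  if (is.list(treated) && !inherits(treated, "stranded_coverage")) {
    stopifnot(identical(names(treated), names(untreated)))
    return(mapply(enrichment_track, treated, untreated, SIMPLIFY = FALSE))
  }
  stopifnot(inherits(treated, "stranded_coverage"),
            inherits(untreated, "stranded_coverage"),
            treated$chrom == untreated$chrom,
            treated$bin_size == untreated$bin_size,
            length(treated$fwd) == length(untreated$fwd))
  t <- rpm_normalize(treated); u <- rpm_normalize(untreated)
  structure(list(chrom = t$chrom, bin_size = t$bin_size,
                 value = (t$fwd + t$rev) - (u$fwd + u$rev)),
            class = "enrichment_track")
}

#' Write / read stranded coverage as bedGraph
#'
#' One bedGraph per strand (`<prefix>_fwd.bedGraph`,
#' `<prefix>_rev.bedGraph`) plus a YAML sidecar
#' (`<prefix>_library.yaml`) carrying library size, bin size and sample
#' tag. Zero bins are omitted from the bedGraph (standard sparse
#' convention) and restored on read.
#'
#' @param cov a `stranded_coverage`.
#' @param prefix path prefix for the three files.
#' @param chrom_length chromosome length in bp (recovers trailing zero
#'   bins on read).
#' @return `read_coverage_bedgraph` returns a `stranded_coverage`.
#' @export
write_coverage_bedgraph <- function(cov, prefix) {
  stopifnot(inherits(cov, "stranded_coverage"))
  n <- length(cov$fwd)
  starts <- (seq_len(n) - 1) * cov$bin_size
  for (strand in c("fwd", "rev")) {
    v <- cov[[strand]]
    keep <- v != 0
    gr <- GenomicRanges::GRanges(
      cov$chrom, IRanges::IRanges(start = starts[keep] + 1,
                                  width = cov$bin_size),
      score = v[keep])
    rtracklayer::export(gr, paste0(prefix, "_", strand, ".bedGraph"),
                        format = "bedGraph")
  }
  writeLines(yaml::as.yaml(list(chrom = cov$chrom, bin_size = cov$bin_size,
                                n_bins = n, library_size = cov$library_size,
                                sample = cov$sample,
                                normalization = cov$normalization),
                           precision = 15L),
             paste0(prefix, "_library.yaml"))
  invisible(prefix)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(prefix, chrom_length = NULL) {
  side <- yaml::yaml.load_file(paste0(prefix, "_library.yaml"))
  n <- side$n_bins
  vecs <- lapply(c("fwd", "rev"), function(strand) {
    gr <- rtracklayer::import(paste0(prefix, "_", strand, ".bedGraph"),
                              format = "bedGraph")
    v <- numeric(n)
    b <- (GenomicRanges::start(gr) - 1) / side$bin_size + 1
    v[b] <- S4Vectors::mcols(gr)$score
    v
  })
  stranded_coverage(side$chrom, side$bin_size, vecs[[1]], vecs[[2]],
                    side$library_size, side$sample, side$normalization)
}
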