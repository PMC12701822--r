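#' Binned contact maps
#'
#' A `contact_map` holds the symmetric binned Hi-C contact matrix of one
#' chromosome. Masked bins are `NaN`. Counts may be raw or balanced; the
#' tag is carried through all downstream operations.
#'
#' @param chrom chromosome name.
#' @param bin_size bin size, bp.
#' @param counts square symmetric numeric matrix (NaN = masked).
#' @param origin 0-based coordinate of the first bin's start; must be a
#'   multiple of `bin_size`.
#' @param normalization `"raw"` or `"balanced"`.
#' @param partial_bin logical; TRUE when the last bin is a trailing partial
#'   bin (chromosome length not a bin multiple).
#' @param tol relative tolerance for the symmetry check.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(chrom, bin_size, counts, origin = 0,
                        normalization = "raw", partial_bin = FALSE,
                        tol = 1e-8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop_data("contact matrix must be square")
  if (origin %% bin_size != 0) stop_data("origin must be a multiple of bin_size")
  ok <- is.finite(counts) & is.finite(t(counts))
  d <- abs(counts - t(counts))
  if (any(d[ok] > tol * (abs(counts[ok]) + 1)))
    stop_data("contact matrix asymmetric beyond tolerance for ", chrom)
  structure(list(chrom = as.character(chrom), bin_size = bin_size,
                 origin = origin, counts = unname(counts),
                 normalization = normalization, partial_bin = partial_bin),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$chrom, ": ", nrow(x$counts), " bins of ",
      fmt_bp(x$bin_size), " (", x$normalization, "), total ",
      format(sum(x$counts, na.rm = TRUE), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Write / read a dense contact-map TSV
#'
#' Plain dense matrix TSV with `#key=value` metadata header lines
#' (chromosome, bin size, origin, normalization), the interchange format
#' used throughout the pipeline.
#'
#' @param map a `contact_map`.
#' @param path file path.
#' @param chromosome,bin_size optional expectations checked against the
#'   file's metadata.
#' @return `read_contact_map` returns a `contact_map`.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  hdr <- c(paste0("#chrom=", map$chrom),
           paste0("#bin_size=", format(map$bin_size, scientific = FALSE)),
           paste0("#origin=", format(map$origin, scientific = FALSE)),
           paste0("#normalization=", map$normalization),
           paste0("#partial_bin=", map$partial_bin))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(map$counts), path, sep = "\t",
                     col.names = FALSE, append = TRUE, na = "nan")
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path, chromosome = NULL, bin_size = NULL) {
  if (!file.exists(path)) stop_data("no such contact map file: ", path)
  hdr_lines <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    hdr_lines <- c(hdr_lines, l)
  }
  kv <- strsplit(sub("^#", "", hdr_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (!is.null(chromosome) && !identical(meta[["chrom"]], chromosome))
    stop_data("chromosome ", chromosome, " not found in ", path,
              " (file holds ", meta[["chrom"]], ")")
  bs <- as.numeric(meta[["bin_size"]])
  if (!is.null(bin_size) && bs != bin_size)
    stop_data("resolution ", fmt_bp(bin_size), " not available in ", path)
  m <- as.matrix(data.table::fread(path, sep = "\t", skip = length(hdr_lines),
                                   header = FALSE, na.strings = c("nan", "NA")))
  m[is.na(m)] <- NaN
  contact_map(meta[["chrom"]], bs, m, origin = as.numeric(meta[["origin"]]),
              normalization = meta[["normalization"]],
              partial_bin = identical(meta[["partial_bin"]], "TRUE"))
}
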