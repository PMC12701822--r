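#' Cut-site sets
#'
#' A `cut_sites` object is a data frame with columns `chrom`, `pos`
#' (0-based bp; the break position, assigned to the bin containing it) and
#' `rank` (cleavage-strength rank, 1 = strongest, unique), plus a
#' `provenance` attribute.
#'
#' @param chrom character chromosome names.
#' @param pos numeric 0-based positions, bp.
#' @param rank integer cleavage ranks; defaults to input order.
#' @param provenance free-text origin tag.
#' @return a `cut_sites` data frame.
#' @export
cut_sites <- function(chrom, pos, rank = seq_along(pos),
                      provenance = "user") {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), length(rank) == length(pos))
  if (anyDuplicated(rank)) stop_data("cleavage ranks must be unique")
  x <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  rank = as.integer(rank), stringsAsFactors = FALSE)
  attr(x, "provenance") <- provenance
  class(x) <- c("cut_sites", "data.frame")
  x
}

#' Place synthetic cut sites and derive TAD boundaries
#'
#' Deterministically (given the seed in `params`) places `n_sites` break
#' positions at least `min_separation` apart and at least `edge_margin`
#' from chromosome ends, and returns the internal TAD-segment edges as the
#' boundary list. Sites are allotted to chromosomes in proportion to their
#' placeable span; each site receives a unique synthetic cleavage rank.
#'
#' @param params a [sim_params()] object (genome + TADs + seed).
#' @param n_sites number of sites to place.
#' @param min_separation minimum pairwise distance between sites, bp.
#' @param edge_margin clearance from chromosome ends, bp; should cover the
#'   largest analysis half-window used downstream.
#' @return list with elements `sites` (a `cut_sites`) and `boundaries`
#'   (data frame `chrom`, `pos` of internal TAD edges).
#' @export
make_sites <- function(params, n_sites, min_separation = 1e6,
                       edge_margin = 2e6) {
  validate_params(params)
  spans <- pmax(params$genome - 2 * edge_margin, 0)
  capacity <- ifelse(spans >= 0 & params$genome > 2 * edge_margin,
                     floor(spans / min_separation) + 1, 0)
  if (sum(capacity) < n_sites)
    stop_data("cannot place ", n_sites, " sites ", fmt_bp(min_separation),
              " apart with ", fmt_bp(edge_margin), " end margins")
  ## proportional allotment, largest-remainder rounding
  want <- n_sites * capacity / sum(capacity)
  n_per <- pmin(floor(want), capacity)
  rem <- order(want - floor(want), decreasing = TRUE)
  i <- 1L
  while (sum(n_per) < n_sites) {
    k <- rem[(i - 1L) %% length(rem) + 1L]
    if (n_per[k] < capacity[k]) n_per[k] <- n_per[k] + 1L
    i <- i + 1L
  }
  pos <- with_seed(derive_seed(params$seed, "sites"), {
    out <- lapply(seq_along(params$genome), function(k) {
      n <- n_per[k]
      if (n == 0L) return(numeric(0))
      span <- spans[k]
      slack <- span - (n - 1) * min_separation
      u <- sort(runif(n, 0, slack))
      edge_margin + u + (seq_len(n) - 1) * min_separation
    })
    ranks <- sample.int(n_sites)
    list(pos = out, ranks = ranks)
  })
  chrom <- rep(names(params$genome), times = lengths(pos$pos))
  sites <- cut_sites(chrom, round(unlist(pos$pos)), pos$ranks,
                     provenance = "synthetic")
  list(sites = sites, boundaries = tad_boundaries(params))
}

## internal TAD edges (excluding chromosome ends)
tad_boundaries <- function(params) {
  out <- lapply(names(params$tads), function(ch) {
    edges <- unique(sort(c(params$tads[[ch]][, 1], params$tads[[ch]][, 2])))
    edges <- edges[edges > 0 & edges < params$genome[[ch]]]
    if (!length(edges)) return(NULL)
    data.frame(chrom = ch, pos = edges, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read / write cut sites or boundaries as BED6
#'
#' Sites are written as 1 bp features with the cleavage rank in the BED
#' score column; boundary positions the same with score 0.
#'
#' @param x a `cut_sites` object or a `chrom`/`pos` data frame.
#' @param path file path.
#' @return `read_sites_bed` returns a `cut_sites`; writers return the path.
#' @export
write_sites_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(start = x$pos + 1, width = 1),
                               strand = "*")
  S4Vectors::mcols(gr)$name <- if (!is.null(x$rank))
    sprintf("site_%03d", seq_len(nrow(x))) else sprintf("bnd_%03d", seq_len(nrow(x)))
  S4Vectors::mcols(gr)$score <- if (!is.null(x$rank)) x$rank else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  score <- as.integer(S4Vectors::mcols(gr)$score)
  ## boundary BEDs carry score 0 everywhere; fall back to file order
  if (is.null(score) || anyDuplicated(score)) score <- seq_along(gr)
  cut_sites(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1,
            rank = score,
            provenance = path)
}
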