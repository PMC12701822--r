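#' Sliding-square insulation score
#'
#' For each bin `i` with a full square in bounds, the raw score is the mean
#' contact count over the square of bins `(i-d..i-1) x (i+1..i+d)`,
#' `d = square_size / bin_size` — the contacts crossing bin `i`. The
#' normalized score is `log2(raw / mean(raw))` with the mean taken over all
#' finite raw scores on the chromosome, so the track is invariant to global
#' scaling of the matrix. Local minima mark TAD boundaries; a lower score
#' means stronger insulation.
#'
#' Masked (NaN) bins are excluded from each square's mean; bins whose
#' square is more than half masked, and bins within `d` of a chromosome
#' end, are NaN.
#'
#' @param map a `contact_map`.
#' @param square_size side of the sliding square in bp; a multiple of the
#'   bin size, at least 2 bins. Default 500 kb (20 bins at 25 kb).
#' @return an `insulation_track` with `score` (normalized) and `raw`.
#' @export
insulation_score <- function(map, square_size = 5e5) {
  stopifnot(inherits(map, "contact_map"))
  bs <- map$bin_size
  if (square_size %% bs != 0) stop_data("square_size must be a multiple of the bin size")
  d <- as.integer(square_size / bs)
  if (d < 2L) stop_data("square_size must be at least 2 bins")
  n <- nrow(map$counts)
  raw <- rep(NaN, n)
  if (n >= 2L * d + 1L) {
    for (i in (d + 1L):(n - d)) {
      sq <- map$counts[(i - d):(i - 1L), (i + 1L):(i + d)]
      fin <- is.finite(sq)
      if (sum(fin) < length(sq) / 2) next
      raw[i] <- sum(sq[fin]) / sum(fin)
    }
  }
  if (!any(is.finite(raw))) stop_data("all-NaN insulation track for ", map$chrom)
  ok <- is.finite(raw)
  score <- log2(raw / (sum(raw[ok]) / sum(ok)))
  structure(list(chrom = map$chrom, bin_size = bs, square_size = square_size,
                 score = score, raw = raw),
            class = "insulation_track")
}

#' Per-site damage-induced insulation change
#'
#' For each cut site, averages `treated - untreated` normalized insulation
#' over the bins overlapping the window centered on the cut (half-open
#' `[pos - window/2, pos + window/2)`; at 25 kb bins a 50 kb window covers
#' 2 or 3 bins depending on phase). Sites with any NaN bin in the window
#' are excluded. A negative change (a drop) means damage-induced gain of
#' insulation. Summarized by mean +/- sem and a one-sample t-test against
#' zero across sites.
#'
#' @param treated,untreated `insulation_track`s (or named lists per
#'   chromosome) with identical bin and square sizes.
#' @param sites a `cut_sites`.
#' @param window averaging window, bp (default 50 kb).
#' @return a `delta_insulation` object: per-site table (`dIS`, and
#'   `drop = -dIS`), mean, sem, t statistic, p-value, and n.
#' @export
delta_insulation <- function(treated, untreated, sites, window = 5e4) {
  tr <- if (inherits(treated, "insulation_track"))
    stats::setNames(list(treated), treated$chrom) else treated
  un <- if (inherits(untreated, "insulation_track"))
    stats::setNames(list(untreated), untreated$chrom) else untreated
  stopifnot(identical(sort(names(tr)), sort(names(un))))
  for (ch in names(tr))
    if (tr[[ch]]$bin_size != un[[ch]]$bin_size ||
        tr[[ch]]$square_size != un[[ch]]$square_size)
      stop_data("treated/untreated tracks differ in bin or square size")
  if (window < tr[[1]]$bin_size) stop_data("window must be >= bin size")
  per <- lapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    if (!ch %in% names(tr)) return(NULL)
    bs <- tr[[ch]]$bin_size
    lo <- sites$pos[i] - window / 2
    hi <- sites$pos[i] + window / 2
    bins <- which((seq_along(tr[[ch]]$score) - 1) * bs < hi &
                  seq_along(tr[[ch]]$score) * bs > lo)
    dv <- tr[[ch]]$score[bins] - un[[ch]]$score[bins]
    data.frame(site_id = paste0(ch, ":", sites$pos[i]), chrom = ch,
               pos = sites$pos[i], dIS = mean(dv),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  per <- per[is.finite(per$dIS), , drop = FALSE]
  if (!nrow(per)) stop_data("no site with a fully finite insulation window")
  per$drop <- -per$dIS
  n <- nrow(per)
  m <- mean(per$dIS)
  s <- if (n > 1) sd(per$dIS) / sqrt(n) else NA_real_
  degenerate <- n < 2 || sd(per$dIS) == 0
  tt <- if (!degenerate) t.test(per$dIS, mu = 0) else NULL
  structure(list(per_site = per, mean = m, sem = s,
                 t = if (degenerate) NaN else unname(tt$statistic),
                 p = if (degenerate) NaN else tt$p.value,
                 n = n, window = window,
                 flag = if (degenerate) "t-test undefined (constant or single value)" else NA_character_),
            class = "delta_insulation")
}

#' @export
print.delta_insulation <- function(x, ...) {
  cat("<delta_insulation> n=", x$n, " sites, mean dIS = ",
      signif(x$mean, 4), " +/- ", signif(x$sem, 3),
      " (t=", signif(x$t, 4), ", p=", format.pval(x$p, digits = 3), ")\n",
      sep = "")
  cat("  sites with insulation drop (dIS<0): ", sum(x$per_site$dIS < 0),
      " of ", x$n, "\n", sep = "")
  invisible(x)
}

#' Spearman correlation of insulation drop with ChIP enrichment
#'
#' Rank correlation (average ranks on ties) between per-site
#' damage-induced insulation drop and per-site repair-factor enrichment.
#' The p-value uses the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` by default; `method = "permutation"`
#' gives an exact enumeration for n <= 9 and a seeded Monte-Carlo
#' permutation p otherwise.
#'
#' @param drop_per_site,enrichment_per_site equal-length numeric vectors;
#'   only jointly finite pairs are used (at least 4 required).
#' @param method `"large_sample"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo path.
#' @return a `correlation_result` (`rho`, `p`, `n`, method tag, the paired
#'   values).
#' @export
correlate_enrichment <- function(drop_per_site, enrichment_per_site,
                                 method = c("large_sample", "permutation"),
                                 n_perm = 1e4, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(drop_per_site) == length(enrichment_per_site))
  ok <- is.finite(drop_per_site) & is.finite(enrichment_per_site)
  x <- drop_per_site[ok]; y <- enrichment_per_site[ok]
  n <- length(x)
  if (n < 4) stop_data("need at least 4 finite pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = method, x = x, y = y,
                          flag = "rho undefined on a constant vector"),
                     class = "correlation_result"))
  rho <- cor(x, y, method = "spearman")
  if (method == "large_sample") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    tag <- "large-sample"
  } else if (n <= 9) {
    perms <- all_permutations(n)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(ix) cor(rank(x), ry[ix]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    tag <- "permutation-exact"
  } else {
    null_rho <- with_seed(seed, replicate(n_perm, cor(x, sample(y),
                                                      method = "spearman")))
    p <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    tag <- "permutation-mc"
  }
  structure(list(rho = rho, p = min(p, 1), n = n, method = tag,
                 x = x, y = y, flag = NA_character_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> Spearman rho = ", signif(x$rho, 3),
      " (n=", x$n, ", p=", format.pval(x$p, digits = 3), ", ", x$method,
      ")\n", sep = "")
  if (!is.na(x$flag)) cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}

## all permutations of 1..n as a matrix (n! rows); used for exact p-values
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Per-site enrichment summary
#'
#' Sums the treated-minus-untreated RPM enrichment over a window centered
#' on each cut site; the per-site scalar paired with the insulation drop
#' in [correlate_enrichment()].
#'
#' @param track an `enrichment_track` or named list per chromosome.
#' @param sites a `cut_sites`.
#' @param window total window width, bp (default 20 kb: +/- 10 kb).
#' @return numeric vector, one value per site (NA off-track).
#' @export
site_enrichment <- function(track, sites, window = 2e4) {
  trk <- if (inherits(track, "enrichment_track"))
    stats::setNames(list(track), track$chrom) else track
  vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    if (!ch %in% names(trk)) return(NA_real_)
    bs <- trk[[ch]]$bin_size
    lo <- sites$pos[i] - window / 2; hi <- sites$pos[i] + window / 2
    bins <- which((seq_along(trk[[ch]]$value) - 1) * bs < hi &
                  seq_along(trk[[ch]]$value) * bs > lo)
    sum(trk[[ch]]$value[bins])
  }, numeric(1))
}
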