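# Regional and chromosome-level summaries of interference strength:
# chromosome thirds, the bounded L1 histogram distance delta, difference
# ratios between regions, boxplot statistics and length-vs-interference
# fits.

#' Region boundaries of a linkage group
#'
#' Splits the linkage group's cM span into `k` equal-length intervals
#' (default thirds, labelled `NO.1`, `NO.2`, `NO.3`). Intervals are
#' half-open `[a, b)` except the last, which is closed.
#'
#' @param map Genetic map.
#' @param lg Linkage-group id.
#' @param k Number of regions.
#' @return Numeric vector of `k + 1` break positions.
#' @export
region_breaks <- function(map, lg, k = 3L) {
  pos <- map$position_cM[map$linkage_group == lg]
  if (!length(pos)) stop("linkage group not in map: ", lg)
  seq(min(pos), max(pos), length.out = k + 1L)
}

.region_of <- function(pos, breaks) {
  i <- findInterval(pos, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  paste0("NO.", i)
}

#' Assign scan windows to chromosome regions
#'
#' Each window is assigned by its representative position (`pos_mid`, the
#' midpoint of its outer markers) to one of the `k` equal-length regions of
#' its linkage group. Every window lands in exactly one region.
#'
#' @param scan Scan data frame from [scan_interference()].
#' @param map Genetic map.
#' @param k Number of regions per linkage group (default 3).
#' @return The scan data frame with an added `region` column
#'   (`"NO.1" ... "NO.k"`).
#' @export
assign_regions <- function(scan, map, k = 3L) {
  region <- character(nrow(scan))
  for (lg in unique(scan$lg)) {
    sel <- scan$lg == lg
    br <- region_breaks(map, lg, k)
    region[sel] <- .region_of(scan$pos_mid[sel], br)
  }
  scan$region <- region
  scan
}

#' L1 histogram distance between two sets of interference-strength values
#'
#' Both value sets are binned on shared edges; with per-bin proportions
#' \eqn{p_{i1}, p_{i2}} the statistic is
#' \deqn{\delta = \sum_{i=1}^N |p_{i1} - p_{i2}|, \qquad 0 \le \delta \le 2.}
#' \eqn{\delta = 0} when the binned distributions coincide and
#' \eqn{\delta = 2} when they share no bin. Non-finite values (including
#' undefined coincidence coefficients) are excluded and counted.
#'
#' @param values_a,values_b Numeric vectors of interference-strength values
#'   for the two regions.
#' @param breaks Optional shared bin edges. By default `n_bins` equal-width
#'   bins spanning the pooled range of the finite values; values outside
#'   user-supplied breaks are clamped into the outer bins.
#' @param n_bins Number of equal-width bins when `breaks` is `NULL`.
#' @return A list with `delta`, `p1`, `p2`, `counts_a`, `counts_b`,
#'   `breaks`, `n_a`, `n_b`, `excluded_a`, `excluded_b`, and `absent`
#'   (`TRUE`, with `delta = NA`, when either region has no finite value).
#' @examples
#' delta_statistic(c(1, 1, 2), c(1, 1, 2))$delta   # 0
#' delta_statistic(rep(0, 5), rep(10, 5))$delta    # 2
#' @export
delta_statistic <- function(values_a, values_b, breaks = NULL, n_bins = 10L) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  excl_a <- length(values_a) - length(a)
  excl_b <- length(values_b) - length(b)
  if (!length(a) || !length(b)) {
    return(list(delta = NA_real_, p1 = NULL, p2 = NULL,
                counts_a = NULL, counts_b = NULL, breaks = breaks,
                n_a = length(a), n_b = length(b),
                excluded_a = excl_a, excluded_b = excl_b, absent = TRUE))
  }
  if (is.null(breaks)) {
    rg <- range(c(a, b))
    breaks <- if (diff(rg) == 0) {
      c(rg[1] - 0.5, rg[1] + 0.5)
    } else {
      seq(rg[1], rg[2], length.out = n_bins + 1L)
    }
  }
  nb <- length(breaks) - 1L
  bin <- function(x) {
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = nb)
  }
  ca <- bin(a); cb <- bin(b)
  p1 <- ca / sum(ca); p2 <- cb / sum(cb)
  list(delta = sum(abs(p1 - p2)), p1 = p1, p2 = p2,
       counts_a = ca, counts_b = cb, breaks = breaks,
       n_a = length(a), n_b = length(b),
       excluded_a = excl_a, excluded_b = excl_b, absent = FALSE)
}

.region_pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))

#' Difference ratios of interference strength between chromosome regions
#'
#' For each linkage group (or for the genome pooled across linkage groups)
#' compares the interference-strength distributions of region pairs
#' NO.1-NO.2, NO.2-NO.3 and NO.1-NO.3. The default comparison is the
#' bounded L1 proportion distance of [delta_statistic()]; `method =
#' "counts"` instead reports the unnormalized sum of absolute bin-count
#' differences (an alternative reading of a "sum of difference values").
#'
#' @param scan Scan data frame.
#' @param map Genetic map.
#' @param strength Which coefficient measures interference strength
#'   (default `"C4"`, the triple-interval coefficient; any of
#'   `"C1" ... "C4"`).
#' @param k Number of regions per linkage group.
#' @param n_bins Histogram bins for the comparison.
#' @param method `"delta"` (default) or `"counts"`.
#' @param pool If `TRUE`, pool windows of all linkage groups by region and
#'   report a single genome-wide triple (`lg = "genome"`).
#' @return Data frame with columns `lg`, `pair`, `value`, `n_a`, `n_b`,
#'   `excluded`, `absent`. Pairs with an empty region are flagged absent
#'   (`value = NA`), not zero.
#' @export
difference_ratios <- function(scan, map, strength = "C4", k = 3L,
                              n_bins = 10L, method = c("delta", "counts"),
                              pool = FALSE) {
  method <- match.arg(method)
  stopifnot(strength %in% c("C1", "C2", "C3", "C4"))
  sc <- assign_regions(scan, map, k)
  groups <- if (pool) list(genome = sc) else split(sc, sc$lg)
  rows <- list()
  for (lg in names(groups)) {
    sub <- groups[[lg]]
    for (pr in .region_pairs) {
      va <- sub[[strength]][sub$region == paste0("NO.", pr[1])]
      vb <- sub[[strength]][sub$region == paste0("NO.", pr[2])]
      d <- delta_statistic(va, vb, n_bins = n_bins)
      value <- if (d$absent) {
        NA_real_
      } else if (method == "delta") {
        d$delta
      } else {
        sum(abs(d$counts_a - d$counts_b))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lg = lg, pair = sprintf("NO.%d-NO.%d", pr[1], pr[2]),
        value = value, n_a = d$n_a, n_b = d$n_b,
        excluded = d$excluded_a + d$excluded_b, absent = d$absent,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "strength") <- strength
  attr(out, "n_bins") <- n_bins
  attr(out, "method") <- method
  out
}

#' Chromosome-level five-number summaries of interference strength
#'
#' Per linkage group: mean, minimum, lower quartile, median, upper
#' quartile, maximum and IQR of the defined (finite) strength values, the
#' number of windows, the number of excluded (undefined) values, and the
#' linkage-group length in cM (max - min marker position). Quartiles use
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param scan Scan data frame.
#' @param map Genetic map.
#' @param strength Strength coefficient, default `"C4"`.
#' @return Data frame with one row per linkage group present in the scan;
#'   groups with no defined value are flagged `absent` with `NA` statistics.
#' @export
chromosome_summaries <- function(scan, map, strength = "C4") {
  stopifnot(strength %in% c("C1", "C2", "C3", "C4"))
  lgs <- unique(scan$lg)
  rows <- lapply(lgs, function(lg) {
    v <- scan[[strength]][scan$lg == lg]
    fin <- v[is.finite(v)]
    pos <- map$position_cM[map$linkage_group == lg]
    len <- if (length(pos)) max(pos) - min(pos) else NA_real_
    if (!length(fin)) {
      return(data.frame(lg = lg, length_cM = len, n_windows = length(v),
                        n_undefined = length(v), mean_C = NA_real_,
                        min = NA_real_, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, max = NA_real_, iqr_C = NA_real_,
                        absent = TRUE, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(fin, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(lg = lg, length_cM = len, n_windows = length(v),
               n_undefined = length(v) - length(fin), mean_C = mean(fin),
               min = min(fin), q1 = q[1], median = q[2], q3 = q[3],
               max = max(fin), iqr_C = q[3] - q[1], absent = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "strength") <- strength
  attr(out, "quartile_type") <- 7L
  out
}

.ols_report <- function(df) {
  if (nrow(df) < 3L) stop("length fit needs at least 3 chromosomes per group")
  if (diff(range(df$length_cM)) == 0) {
    stop("degenerate length fit: all chromosome lengths equal")
  }
  fit <- stats::lm(mean_C ~ length_cM, data = df)
  s <- summary(fit)
  list(lgs = df$lg, n = nrow(df),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adj_r_squared = s$adj.r.squared)
}

#' Linear fits of mean interference strength on chromosome length
#'
#' Ordinary least squares of per-chromosome mean strength on genetic
#' length, fitted separately for a named group of chromosomes and for the
#' remaining ones, with outlier chromosomes excluded from both fits.
#'
#' @param summaries Output of [chromosome_summaries()].
#' @param group_a Linkage-group ids fitted as the first group.
#' @param exclude Linkage-group ids excluded from both fits (outliers).
#' @return A list with elements `group_a` and `group_b`, each a list with
#'   `lgs`, `n`, `slope`, `intercept`, `adj_r_squared`.
#' @export
length_fit <- function(summaries, group_a, exclude = character()) {
  s <- summaries[!summaries$absent & !(summaries$lg %in% exclude), ,
                 drop = FALSE]
  a <- s[s$lg %in% group_a, , drop = FALSE]
  b <- s[!(s$lg %in% group_a), , drop = FALSE]
  list(group_a = .ols_report(a), group_b = .ols_report(b))
}
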