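# Genome scan: partition each linkage group into four-marker windows and
# estimate per-window recombination fractions and coincidence coefficients.

#' Build four-marker windows over a genetic map
#'
#' @param map Genetic map, see [read_genetic_map()].
#' @param scheme `"nonoverlap"` (default): consecutive disjoint quadruples
#'   in map order per linkage group, trailing remainder (< 4 markers)
#'   dropped — floor(m/4) windows for m markers. `"sliding"`: stride-1
#'   quadruples — max(0, m - 3) windows.
#' @return A list of windows; each window is a list with `lg`, `markers`
#'   (4 names) and `positions` (4 cM positions). Linkage groups with fewer
#'   than 4 markers contribute no windows (a message is emitted).
#' @export
make_windows <- function(map, scheme = c("nonoverlap", "sliding")) {
  scheme <- match.arg(scheme)
  out <- list()
  for (lg in unique(map$linkage_group)) {
    sub <- map[map$linkage_group == lg, , drop = FALSE]
    m <- nrow(sub)
    if (m < 4L) {
      message(sprintf("linkage group %s has %d marker(s) (< 4): no windows",
                      lg, m))
      next
    }
    starts <- if (scheme == "nonoverlap") {
      seq(1L, m - 3L, by = 4L)
    } else {
      seq_len(m - 3L)
    }
    for (s in starts) {
      idx <- s:(s + 3L)
      out[[length(out) + 1L]] <- list(
        lg = lg,
        markers = sub$name[idx],
        positions = sub$position_cM[idx]
      )
    }
  }
  out
}

.empty_scan <- function() {
  df <- data.frame(
    r_AB = numeric(0), r_BC = numeric(0), r_CD = numeric(0),
    r_AC = numeric(0), r_BD = numeric(0), r_AD = numeric(0),
    C1 = numeric(0), C2 = numeric(0), C3 = numeric(0), C4 = numeric(0),
    lg = character(0),
    marker1 = character(0), marker2 = character(0),
    marker3 = character(0), marker4 = character(0),
    method = character(0), n_used = integer(0), pos_mid = numeric(0),
    reason = character(0),
    stringsAsFactors = FALSE
  )
  for (gn in .gamete_type_names) df[[gn]] <- numeric(0)
  df
}

#' Scan a genome for crossover interference
#'
#' Runs [estimate_window()] on every four-marker window of the map,
#' converts the estimated gamete frequencies to recombination fractions and
#' coincidence coefficients, and returns one row per window. A window whose
#' estimation fails yields a `method = "skipped"` row with a reason; the
#' scan never aborts. Deterministic given the inputs and `seed`.
#'
#' @param map Genetic map.
#' @param geno Genotype matrix matching the map.
#' @param scheme Windowing scheme, see [make_windows()].
#' @param em_control Arguments passed to [em_estimate()] for hk_hk windows.
#' @param seed Base seed; window i uses `seed + i` for any stochastic step
#'   of its estimator.
#' @return Data frame with columns `r_AB ... r_AD`, `C1 ... C4`, `lg`,
#'   `marker1 ... marker4`, `method`, `n_used`, `pos_mid` (midpoint of the
#'   outer markers, the window's representative position), `reason`, and
#'   the estimated gamete frequencies `g000 ... g111`.
#' @export
scan_interference <- function(map, geno, scheme = c("nonoverlap", "sliding"),
                              em_control = list(), seed = 20190515L) {
  scheme <- match.arg(scheme)
  wins <- make_windows(map, scheme)
  out <- .empty_scan()
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    ctl <- em_control
    if (is.null(ctl$seed)) ctl$seed <- seed + i
    res <- tryCatch(
      estimate_window(geno, w$markers, map, em_control = ctl),
      error = function(e) {
        list(method = "skipped", g_hat = NULL, n_used = NA_integer_,
             n_dropped = NA_integer_, reason = conditionMessage(e),
             detail = NULL)
      }
    )
    row <- list(lg = w$lg,
                marker1 = w$markers[1], marker2 = w$markers[2],
                marker3 = w$markers[3], marker4 = w$markers[4],
                method = res$method, n_used = res$n_used,
                pos_mid = (w$positions[1] + w$positions[4]) / 2,
                reason = res$reason)
    if (res$method == "skipped") {
      row <- c(row,
               as.list(stats::setNames(rep(NA_real_, 6),
                                       c("r_AB", "r_BC", "r_CD",
                                         "r_AC", "r_BD", "r_AD"))),
               as.list(stats::setNames(rep(NA_real_, 4),
                                       paste0("C", 1:4))),
               as.list(stats::setNames(rep(NA_real_, 8),
                                       .gamete_type_names)))
    } else {
      r <- recombination_fractions(res$g_hat)
      C <- coincidence_coefficients(res$g_hat, r)
      row <- c(row, as.list(r), as.list(C), as.list(res$g_hat))
    }
    out[nrow(out) + 1L, names(row)] <- row
  }
  rownames(out) <- NULL
  out
}
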