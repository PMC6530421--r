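# Recombination fractions and coincidence coefficients from gamete-type
# frequencies, and the inverse map used by the simulator.

#' Pairwise recombination fractions from gamete-type frequencies
#'
#' The six recombination fractions of a four-marker window are sums of the
#' gamete-type frequencies whose crossover-indicator pattern makes the
#' gamete recombinant for that marker pair:
#' \deqn{r_{AB} = g_{111}+g_{110}+g_{101}+g_{100}}
#' \deqn{r_{BC} = g_{111}+g_{110}+g_{011}+g_{010}}
#' \deqn{r_{CD} = g_{111}+g_{101}+g_{011}+g_{001}}
#' \deqn{r_{AC} = g_{101}+g_{100}+g_{011}+g_{010}}
#' \deqn{r_{BD} = g_{110}+g_{010}+g_{101}+g_{001}}
#' \deqn{r_{AD} = g_{111}+g_{010}+g_{100}+g_{001}}
#' Values are reported untruncated: configurations with excess multi-interval
#' crossover mass can yield r above 0.5, as printed estimates from real
#' linkage scans sometimes do.
#'
#' @param g Gamete-type frequencies, see [gamete_frequencies()].
#' @return Named numeric vector `r_AB, r_BC, r_CD, r_AC, r_BD, r_AD`.
#' @examples
#' recombination_fractions(independence_gametes(0.1, 0.2, 0.1))
#' @export
recombination_fractions <- function(g) {
  g <- gamete_frequencies(g)
  i1 <- .type_bits[, 1]; i2 <- .type_bits[, 2]; i3 <- .type_bits[, 3]
  c(
    r_AB = sum(g[i1 == 1L]),
    r_BC = sum(g[i2 == 1L]),
    r_CD = sum(g[i3 == 1L]),
    r_AC = sum(g[(i1 + i2) %% 2L == 1L]),
    r_BD = sum(g[(i2 + i3) %% 2L == 1L]),
    r_AD = sum(g[(i1 + i2 + i3) %% 2L == 1L])
  )
}

# observed/expected ratio with the zero-denominator convention:
# 0/0 -> 0 (no multi-recombinants possible and none observed),
# x/0 with x > 0 -> NA ("undefined"; propagated as missing downstream).
.coc_ratio <- function(num, den) {
  if (den > 0) return(num / den)
  if (num > 0) NA_real_ else 0
}

#' Coincidence coefficients C1-C4 of a four-marker window
#'
#' The coefficient of coincidence is the observed frequency of
#' multi-interval recombinant gametes divided by the frequency expected if
#' crossovers in the intervals were independent. For intervals A-B, B-C, C-D
#' with recombination fractions \eqn{r_{AB}, r_{BC}, r_{CD}}:
#' \deqn{C_1 = (g_{111}+g_{110}) / (r_{AB} r_{BC})}
#' \deqn{C_2 = (g_{111}+g_{011}) / (r_{BC} r_{CD})}
#' \deqn{C_3 = (g_{111}+g_{101}) / (r_{AB} r_{CD})}
#' \deqn{C_4 = g_{111} / (r_{AB} r_{BC} r_{CD})}
#' C = 1 means no interference, C < 1 positive interference (crossovers
#' suppress each other), C > 1 negative interference / clustering. C4
#' measures simultaneous recombination across all three intervals
#' ("high-dimensional" interference).
#'
#' Zero-denominator convention: a coefficient with zero denominator is 0 when
#' its numerator is also 0, and `NA` ("undefined") when the numerator is
#' positive; undefined values are treated as missing by all downstream
#' summaries.
#'
#' @param g Gamete-type frequencies.
#' @param r Recombination fractions; must equal `recombination_fractions(g)`
#'   within `tol` (supplied for interface symmetry, recomputed checkable).
#' @param tol Consistency tolerance between `g` and `r`.
#' @return Named numeric vector `C1, C2, C3, C4` (entries may be `NA`).
#' @examples
#' g <- independence_gametes(0.1, 0.2, 0.1)
#' coincidence_coefficients(g)  # all 1
#' @export
coincidence_coefficients <- function(g, r = recombination_fractions(g),
                                     tol = 1e-9) {
  g <- gamete_frequencies(g)
  r0 <- recombination_fractions(g)
  if (max(abs(r[names(r0)] - r0)) > tol) {
    stop("r is inconsistent with g: supply r = recombination_fractions(g)")
  }
  c(
    C1 = .coc_ratio(g[["g111"]] + g[["g110"]], r0[["r_AB"]] * r0[["r_BC"]]),
    C2 = .coc_ratio(g[["g111"]] + g[["g011"]], r0[["r_BC"]] * r0[["r_CD"]]),
    C3 = .coc_ratio(g[["g111"]] + g[["g101"]], r0[["r_AB"]] * r0[["r_CD"]]),
    C4 = .coc_ratio(g[["g111"]],
                    r0[["r_AB"]] * r0[["r_BC"]] * r0[["r_CD"]])
  )
}

#' Gamete-type frequencies under crossover independence
#'
#' The no-interference baseline: crossovers in the three intervals occur
#' independently, so \eqn{g_{ijk} = \prod_m (r_m)^{[m]} (1-r_m)^{1-[m]}}
#' over the interval indicators. By construction all four coincidence
#' coefficients equal 1.
#'
#' @param r_AB,r_BC,r_CD Interval recombination fractions in `[0, 0.5]`.
#' @return Gamete-type frequencies, see [gamete_frequencies()].
#' @examples
#' independence_gametes(0, 0, 0)          # g000 = 1
#' independence_gametes(0.5, 0.5, 0.5)    # uniform 1/8
#' @export
independence_gametes <- function(r_AB, r_BC, r_CD) {
  r <- c(r_AB, r_BC, r_CD)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5)) {
    stop("interval recombination fractions must lie in [0, 0.5]")
  }
  g <- apply(.type_bits, 1L, function(b) prod(ifelse(b == 1L, r, 1 - r)))
  gamete_frequencies(g)
}

#' Invert recombination fractions and coincidence coefficients to gamete
#' frequencies
#'
#' Solves the defining ratios of C1-C4 for the gamete-type frequencies:
#' \eqn{g_{111} = C_4 r_{AB} r_{BC} r_{CD}},
#' \eqn{g_{110} = C_1 r_{AB} r_{BC} - g_{111}}, and so on down to
#' \eqn{g_{000} = 1 - \sum \text{others}}. Not every (r, C) combination is a
#' valid probability vector; infeasible combinations (any negative entry)
#' raise an error naming the violated entry. This is how extreme printed
#' parameterizations from real scans can be screened: see [coc_feasible()].
#'
#' @param r_AB,r_BC,r_CD Interval recombination fractions (non-negative).
#' @param C1,C2,C3,C4 Coincidence coefficients (non-negative), default 1
#'   (independence).
#' @param tol Negative values above `-tol` are treated as rounding error and
#'   clamped to 0.
#' @return Gamete-type frequencies, see [gamete_frequencies()].
#' @examples
#' # with all C = 1 this is the independence product
#' gametes_from_r_and_coc(0.1, 0.2, 0.1)
#' @export
gametes_from_r_and_coc <- function(r_AB, r_BC, r_CD,
                                   C1 = 1, C2 = 1, C3 = 1, C4 = 1,
                                   tol = 1e-12) {
  v <- c(r_AB, r_BC, r_CD, C1, C2, C3, C4)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("recombination fractions and coincidence coefficients must be non-negative")
  }
  g <- .solve_gametes(r_AB, r_BC, r_CD, C1, C2, C3, C4)
  bad <- names(g)[g < -tol]
  if (length(bad)) {
    stop("infeasible (r, C) parameterization: ",
         paste(sprintf("%s = %.6g", bad, g[bad]), collapse = ", "),
         " would be negative")
  }
  g[g < 0] <- 0
  gamete_frequencies(g / sum(g), tol = 1e-9)
}

.solve_gametes <- function(r_AB, r_BC, r_CD, C1, C2, C3, C4) {
  g111 <- C4 * r_AB * r_BC * r_CD
  g110 <- C1 * r_AB * r_BC - g111
  g011 <- C2 * r_BC * r_CD - g111
  g101 <- C3 * r_AB * r_CD - g111
  g100 <- r_AB - g111 - g110 - g101
  g010 <- r_BC - g111 - g110 - g011
  g001 <- r_CD - g111 - g101 - g011
  g000 <- 1 - (g111 + g110 + g101 + g011 + g100 + g010 + g001)
  c(g000 = g000, g001 = g001, g010 = g010, g011 = g011,
    g100 = g100, g101 = g101, g110 = g110, g111 = g111)
}

#' Check whether an (r, C) parameterization admits valid gamete frequencies
#'
#' @inheritParams gametes_from_r_and_coc
#' @return A list with `feasible` (logical), `violated` (names of the gamete
#'   types that would be negative), and `g` (the frequencies when feasible,
#'   otherwise `NULL`).
#' @examples
#' coc_feasible(0.1, 0.1, 0.1, C4 = 12)  # infeasible with C1..C3 = 1
#' @export
coc_feasible <- function(r_AB, r_BC, r_CD, C1 = 1, C2 = 1, C3 = 1, C4 = 1,
                         tol = 1e-12) {
  g <- .solve_gametes(r_AB, r_BC, r_CD, C1, C2, C3, C4)
  bad <- names(g)[g < -tol]
  if (length(bad)) {
    list(feasible = FALSE, violated = bad, g = NULL)
  } else {
    g[g < 0] <- 0
    list(feasible = TRUE, violated = character(),
         g = gamete_frequencies(g / sum(g)))
  }
}
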