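# Independent brute-force oracles for the four-point gamete algebra.
# These deliberately re-derive the enumeration from scratch (string keys,
# dictionary accumulation) so they share no code path with the package's
# indexed implementations.

# the 16 concrete gametes as allele vectors, with their type frequency share
oracle_gamete_pool <- function(g) {
  stopifnot(length(g) == 8)
  pool <- list()
  for (t in 0:7) {
    bits <- c(t %/% 4 %% 2, t %/% 2 %% 2, t %% 2)  # (i_AB, i_BC, i_CD)
    for (h1 in c(1, 0)) {
      h <- numeric(4)
      h[1] <- h1
      for (k in 1:3) h[k + 1] <- (h[k] + bits[k]) %% 2
      pool[[length(pool) + 1]] <- list(alleles = h, type = t + 1,
                                       bits = bits, freq = g[t + 1] / 2)
    }
  }
  pool
}

# recombination fraction between marker pair (i, j): total frequency of
# gametes whose alleles mismatch at i and j
oracle_recombination <- function(g) {
  pool <- oracle_gamete_pool(g)
  pair_r <- function(i, j) {
    sum(vapply(pool, function(x) {
      if (x$alleles[i] != x$alleles[j]) x$freq else 0
    }, numeric(1)))
  }
  c(r_AB = pair_r(1, 2), r_BC = pair_r(2, 3), r_CD = pair_r(3, 4),
    r_AC = pair_r(1, 3), r_BD = pair_r(2, 4), r_AD = pair_r(1, 4))
}

# coincidence coefficients as observed multi-recombinant mass over the
# product of single-interval recombinant masses, classified per gamete
oracle_coc <- function(g) {
  pool <- oracle_gamete_pool(g)
  mass <- function(sel) sum(vapply(pool, function(x) {
    if (sel(x$bits)) x$freq else 0
  }, numeric(1)))
  rab <- mass(function(b) b[1] == 1)
  rbc <- mass(function(b) b[2] == 1)
  rcd <- mass(function(b) b[3] == 1)
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num > 0) NA_real_ else 0
  }
  c(C1 = ratio(mass(function(b) b[1] == 1 && b[2] == 1), rab * rbc),
    C2 = ratio(mass(function(b) b[2] == 1 && b[3] == 1), rbc * rcd),
    C3 = ratio(mass(function(b) b[1] == 1 && b[3] == 1), rab * rcd),
    C4 = ratio(mass(function(b) all(b == 1)), rab * rbc * rcd))
}

# 81-class genotype distribution by dictionary accumulation over all
# 16 x 16 ordered gamete pairs, keyed by the genotype-code string
oracle_class_table <- function(g_m, g_p = g_m) {
  pm <- oracle_gamete_pool(g_m)
  pp <- oracle_gamete_pool(g_p)
  acc <- new.env(parent = emptyenv())
  for (a in pm) {
    for (b in pp) {
      key <- paste(a$alleles + b$alleles, collapse = "")
      prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
      acc[[key]] <- prev + a$freq * b$freq
    }
  }
  keys <- ls(acc)
  stats::setNames(vapply(keys, function(k) acc[[k]], numeric(1)), keys)
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  list(slope = sl, intercept = ic)
}

# random valid gamete-frequency vector
random_g <- function(alpha = rep(1, 8)) {
  x <- stats::rgamma(8, shape = alpha)
  x / sum(x)
}

# small map / genotype fixture writers
write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
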