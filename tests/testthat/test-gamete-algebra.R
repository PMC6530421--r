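# Four-locus gamete algebra: recombination fractions, coincidence
# coefficients, independence baseline, genotype class table.

test_that("recombination fractions follow the four-term sums of the gamete algebra", {
  g0 <- gamete_frequencies(c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(recombination_fractions(g0)), rep(0, 6))

  # a pure single-interval crossover pool: g100 = 1 makes exactly the
  # A-spanning pairs recombinant
  g100 <- gamete_frequencies(c(0, 0, 0, 0, 1, 0, 0, 0))
  r <- recombination_fractions(g100)
  expect_equal(r[["r_AB"]], 1)
  expect_equal(r[["r_AC"]], 1)
  expect_equal(r[["r_AD"]], 1)
  expect_equal(r[["r_BC"]], 0)
  expect_equal(r[["r_CD"]], 0)
  expect_equal(r[["r_BD"]], 0)

  # literal four-term sums, written out independently
  set.seed(41)
  for (k in 1:25) {
    g <- stats::setNames(random_g(), names(g0))
    r <- recombination_fractions(g)
    expect_equal(r[["r_AB"]],
                 g[["g111"]] + g[["g110"]] + g[["g101"]] + g[["g100"]])
    expect_equal(r[["r_BC"]],
                 g[["g111"]] + g[["g110"]] + g[["g011"]] + g[["g010"]])
    expect_equal(r[["r_CD"]],
                 g[["g111"]] + g[["g101"]] + g[["g011"]] + g[["g001"]])
    expect_equal(r[["r_AC"]],
                 g[["g101"]] + g[["g100"]] + g[["g011"]] + g[["g010"]])
    expect_equal(r[["r_BD"]],
                 g[["g110"]] + g[["g010"]] + g[["g101"]] + g[["g001"]])
    expect_equal(r[["r_AD"]],
                 g[["g111"]] + g[["g010"]] + g[["g100"]] + g[["g001"]])
    # brute-force mismatch counting over the 16-gamete pool agrees
    expect_equal(r, oracle_recombination(g), tolerance = 1e-12)
  }
})

test_that("gamete frequency validation rejects malformed vectors", {
  expect_error(gamete_frequencies(c(0.5, 0.5)), "length 8")
  expect_error(gamete_frequencies(c(1.2, -0.2, rep(0, 6))), "negative")
  expect_error(gamete_frequencies(rep(0.2, 8)), "sum to 1")
  expect_error(recombination_fractions(rep(0.2, 8)), "sum to 1")
})

test_that("coincidence coefficients match the enumeration oracle and zero conventions", {
  # independence baseline
  g <- independence_gametes(0.1, 0.2, 0.1)
  expect_equal(unname(coincidence_coefficients(g)), rep(1, 4),
               tolerance = 1e-12)

  # complete triple-interval interference: g111 = 0 with positive interval r
  g0 <- gametes_from_r_and_coc(0.1, 0.1, 0.1, C4 = 0)
  expect_identical(coincidence_coefficients(g0)[["C4"]], 0)

  # zero-denominator, zero-numerator coefficients report 0
  gz <- gamete_frequencies(c(0.9, 0.1, 0, 0, 0, 0, 0, 0))  # r_AB = r_BC = 0
  C <- coincidence_coefficients(gz)
  expect_identical(C[["C1"]], 0)
  expect_identical(C[["C4"]], 0)

  # inconsistent r rejected
  expect_error(coincidence_coefficients(g, r = recombination_fractions(g) + 0.1),
               "inconsistent")

  set.seed(42)
  for (k in 1:25) {
    g <- random_g()
    expect_equal(coincidence_coefficients(g), oracle_coc(g),
                 tolerance = 1e-12)
  }
})

test_that("independence gametes are the interval-product distribution", {
  expect_equal(unname(independence_gametes(0, 0, 0)),
               c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(independence_gametes(0.5, 0.5, 0.5)), rep(0.125, 8))
  expect_error(independence_gametes(0.6, 0.1, 0.1), "\\[0, 0.5\\]")
  # coincidence of the product measure is 1 across a grid
  for (r1 in c(0.05, 0.25, 0.5)) {
    for (r2 in c(0.1, 0.4)) {
      g <- independence_gametes(r1, r2, 0.3)
      expect_equal(unname(coincidence_coefficients(g)), rep(1, 4),
                   tolerance = 1e-9)
    }
  }
})

test_that("offspring classification is a bijection over the 81 code quadruples", {
  codes <- as.matrix(expand.grid(a = 0:2, b = 0:2, c = 0:2, d = 0:2))
  idx <- classify_offspring(codes)
  expect_length(unique(idx), 81)
  expect_setequal(idx, 1:81)
  expect_equal(genotype_class_names()[classify_offspring(c(2, 2, 2, 2))],
               "2222")
  expect_equal(genotype_class_names()[classify_offspring(c(0, 0, 0, 0))],
               "0000")
  expect_true(is.na(classify_offspring(c(2, NA, 1, 0))))
  expect_error(classify_offspring(c(3, 0, 0, 0)), "0, 1, 2")
})

test_that("genotype class table is the 16 x 16 pair enumeration", {
  # two non-crossover parents: 1/4 - 1/2 - 1/4 over the fully homozygous
  # and fully heterozygous classes
  g <- gamete_frequencies(c(1, 0, 0, 0, 0, 0, 0, 0))
  tab <- genotype_class_table(g)
  expect_equal(tab$freq[["2222"]], 0.25)
  expect_equal(tab$freq[["1111"]], 0.5)
  expect_equal(tab$freq[["0000"]], 0.25)
  expect_equal(sum(tab$freq), 1)

  # dictionary-accumulation oracle agrees class by class, including with
  # asymmetric parents
  set.seed(43)
  for (k in 1:10) {
    gm <- random_g()
    gp <- random_g()
    tab <- genotype_class_table(gm, gp)
    expect_equal(sum(tab$freq), 1, tolerance = 1e-12)
    ora <- oracle_class_table(gm, gp)
    expect_equal(tab$freq[names(ora)], ora, tolerance = 1e-12)
  }
})

test_that("unambiguous classes mix only the expected gamete-type products", {
  set.seed(44)
  tab <- genotype_class_table(random_g())
  comp <- tab$components
  # class 2221 (AABBCCDd) arises only from g000 x g001 pairings
  c2221 <- comp[comp$class_name == "2221" & comp$prob > 0, ]
  expect_true(all(sort(unique(c(c2221$m_type, c2221$p_type))) ==
                    c("g000", "g001")))
  expect_true(all((c2221$m_type == "g000" & c2221$p_type == "g001") |
                    (c2221$m_type == "g001" & c2221$p_type == "g000")))
  # class 2222 arises only from g000 x g000
  c2222 <- comp[comp$class_name == "2222" & comp$prob > 0, ]
  expect_true(all(c2222$m_type == "g000" & c2222$p_type == "g000"))
})

test_that("phase-pair symmetry makes the class table complement-invariant", {
  # because both complementary gametes of a type carry g_t/2, relabelling
  # the parental phase (complementing every allele in both gametes) maps
  # class abcd onto (2-a)(2-b)(2-c)(2-d) with equal mass, even for
  # asymmetric parents
  set.seed(45)
  for (k in 1:5) {
    tab <- genotype_class_table(random_g(), random_g())
    nm <- names(tab$freq)
    comp_nm <- vapply(strsplit(nm, ""), function(d) {
      paste(2 - as.integer(d), collapse = "")
    }, character(1))
    expect_equal(unname(tab$freq[comp_nm]), unname(tab$freq),
                 tolerance = 1e-15)
  }
})
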