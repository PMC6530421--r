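# Meiosis simulator: parameter inversion, family simulation, whole-study
# generation, testcross encoding.

test_that("the (r, C) inversion reproduces independence and round-trips", {
  # all C = 1 is exactly the independence product
  expect_equal(gametes_from_r_and_coc(0.1, 0.2, 0.1),
               independence_gametes(0.1, 0.2, 0.1), tolerance = 1e-15)

  # algebraic round trip: g -> (r, C) -> g is the identity on valid g
  set.seed(401)
  for (k in 1:30) {
    g <- gamete_frequencies(random_g())
    r <- recombination_fractions(g)
    C <- coincidence_coefficients(g, r)
    g2 <- gametes_from_r_and_coc(r[["r_AB"]], r[["r_BC"]], r[["r_CD"]],
                                 C[["C1"]], C[["C2"]], C[["C3"]], C[["C4"]])
    expect_equal(g2, g, tolerance = 1e-12)
  }

  expect_error(gametes_from_r_and_coc(-0.1, 0.1, 0.1), "non-negative")
})

test_that("infeasible printed parameterizations are rejected by name", {
  # three published four-marker rows, screened by the feasibility check:
  # moderate-C4 row admits a valid g; the two strongest-interference rows
  # do not
  f_lg2 <- coc_feasible(0.02, 0.04, 0.02, 11.53, 15.37, 7.69, 177.29)
  expect_true(f_lg2$feasible)
  expect_equal(sum(f_lg2$g), 1)

  f_lg5 <- coc_feasible(0.03, 0.04, 0.09, 17.70, 5.68, 0.52, 14.20)
  expect_false(f_lg5$feasible)
  expect_setequal(f_lg5$violated, c("g010", "g101"))

  f_lg6 <- coc_feasible(0.01, 0.01, 0.02, 44.45, 37.22, 9.80, 873.87)
  expect_false(f_lg6$feasible)
  expect_equal(f_lg6$violated, "g010")

  expect_error(gametes_from_r_and_coc(0.03, 0.04, 0.09,
                                      17.70, 5.68, 0.52, 14.20),
               "g101")
})

test_that("two non-crossover parents give the 1/4 - 1/2 - 1/4 class split", {
  g <- gamete_frequencies(c(1, 0, 0, 0, 0, 0, 0, 0))
  fam <- simulate_family(g, n = 400, seed = 402)
  idx <- classify_offspring(fam)
  p <- tabulate(idx, 81)[classify_offspring(rbind(c(2, 2, 2, 2),
                                                  c(1, 1, 1, 1),
                                                  c(0, 0, 0, 0)))] / 400
  expect_lt(max(abs(p - c(0.25, 0.5, 0.25))), 0.09)  # ~4 sigma at n = 400
  expect_equal(sum(tabulate(idx, 81)), 400)
})

test_that("empirical class frequencies converge to the enumeration", {
  set.seed(403)
  g <- gamete_frequencies(random_g(c(20, 2, 2, 1, 2, 1, 1, 0.5)))
  n <- 1e6
  fam <- simulate_family(g, n = n, seed = 404)
  emp <- tabulate(classify_offspring(fam), 81) / n
  expected <- genotype_class_table(g)$freq
  se <- sqrt(expected * (1 - expected) / n)
  # 4 SE: 81 classes are checked jointly
  expect_true(all(abs(emp - expected) < 4 * se + 1e-12))
})

test_that("drawn gamete types converge to the type frequencies over seeds", {
  g <- independence_gametes(0.2, 0.2, 0.2)
  n <- 5000
  se <- sqrt(g * (1 - g) / n)
  pass <- 0
  for (s in 1:100) {
    set.seed(s)
    emp <- tabulate(attr(draw_gametes(g, n), "type"), 8) / n
    if (all(abs(emp - g) < 3 * se)) pass <- pass + 1
  }
  # per-seed joint pass probability is ~0.98 for 8 components at 3 SE
  expect_gte(pass, 94)
})

test_that("simulation is reproducible and testcross encoding is invertible", {
  g <- independence_gametes(0.1, 0.1, 0.1)
  f1 <- simulate_family(g, n = 200, seed = 405, seg_type = "lm_ll")
  f2 <- simulate_family(g, n = 200, seed = 405, seg_type = "lm_ll")
  expect_identical(f1, f2)

  # encode/decode round trip per gamete
  set.seed(406)
  hm <- draw_gametes(g, 500)
  codes <- testcross_encode(hm, "lm_ll")
  expect_true(all(codes %in% c(1L, 2L)))
  expect_equal(codes - 1L, unclass(hm)[, ], ignore_attr = TRUE)

  # recoding then direct counting recovers g
  rownames(codes) <- NULL
  colnames(codes) <- paste0("M", 1:4)
  est <- direct_gamete_estimate(codes, paste0("M", 1:4))
  emp <- tabulate(attr(hm, "type"), 8) / 500
  expect_equal(unname(est$g_hat), emp, tolerance = 1e-12)
})

test_that("whole-study simulation matches its configuration and truth", {
  cfg <- study_config(n_lg = 19, markers_per_lg = 8, family_size = 408,
                      seed = 407)
  sim <- simulate_study(cfg)
  expect_equal(length(unique(sim$map$linkage_group)), 19)
  expect_equal(nrow(sim$geno), 408)
  expect_equal(ncol(sim$geno), 19 * 8)
  expect_equal(length(sim$truth$windows), 19 * 2)

  # every stored (r, C) is consistent with its g
  for (w in sim$truth$windows) {
    expect_equal(w$r, recombination_fractions(w$g), tolerance = 1e-12)
    expect_equal(w$C, coincidence_coefficients(w$g), tolerance = 1e-12)
  }

  # single-window study
  sim1 <- simulate_study(study_config(n_lg = 1, markers_per_lg = 4,
                                      lg_lengths = 10, family_size = 50,
                                      seed = 408))
  expect_equal(length(sim1$truth$windows), 1)

  # same seed twice: byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(study_config(n_lg = 2, markers_per_lg = 8,
                              lg_lengths = c(40, 30), family_size = 30,
                              seed = 409), dir = d1)
  simulate_study(study_config(n_lg = 2, markers_per_lg = 8,
                              lg_lengths = c(40, 30), family_size = 30,
                              seed = 409), dir = d2)
  for (f in c("map.tsv", "genotypes.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  # with >9 linkage groups (character sort differs from numeric), the truth
  # windows stay aligned with a scan over the re-read map
  d3 <- tempfile()
  simulate_study(study_config(n_lg = 12, markers_per_lg = 4,
                              lg_lengths = rep(20, 12), family_size = 20,
                              seed = 411), dir = d3)
  map3 <- read_genetic_map(file.path(d3, "map.tsv"))
  truth3 <- read_truth_json(file.path(d3, "truth.json"))
  wins3 <- make_windows(map3)
  expect_equal(vapply(wins3, function(w) w$markers[1], character(1)),
               vapply(truth3$windows, function(w) w$markers[1],
                      character(1)))

  # infeasible truth is rejected with the offending window named
  bad_truth <- function(lg, window, region, length_cM) {
    c(0.5, 0.5, 0.2, rep(0, 5))  # does not sum to 1
  }
  expect_error(simulate_study(study_config(n_lg = 1, markers_per_lg = 4,
                                           lg_lengths = 10,
                                           family_size = 10,
                                           truth = bad_truth, seed = 410)),
               "window 1 of linkage group 1")
})
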