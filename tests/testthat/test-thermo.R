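toy_cond <- thermo_condition(temperature_C = 25, total_strand_M = 8e-6,
                             monovalent_M = 1, mg_mM = 12.5)

test_that("NN tables round-trip through TSV bit-exactly", {
  tab <- default_nn_table()
  expect_identical(nrow(tab$stacks), 16L)
  expect_identical(tab$provenance, "unified-1998")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nn_table(tab, path)
  back <- read_nn_table(path)
  expect_equal(back, tab)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_nn_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("duplex free energy is stack counting on the toy table", {
  tt <- toy_nn_table()
  d <- nn_duplex_thermo(strrep("CAG", 4), tt, toy_cond)
  expect_equal(d$dG, -11)                     # 11 stacks in a 12-mer
  expect_equal(d$dH, -11)
  expect_error(nn_duplex_thermo("A", tt), "at least 2 nt")
  expect_error(nn_duplex_thermo("ACGT", tt,
                                thermo_condition(total_strand_M = -1)),
               ">= 0")
})

test_that("duplex prediction equals an independent hand-summed table lookup", {
  # independent oracle: explicit dinucleotide walk over the same TSV
  raw <- utils::read.delim(system.file("extdata", "nn_unified.tsv",
                                       package = "switchbackdna"),
                           comment.char = "#")
  seq <- strrep("CAG", 4)
  chars <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(chars) - 1)) {
    st <- paste0(chars[i], chars[i + 1])
    row <- raw[raw$kind == "stack" & raw$key == st, ]
    dH <- dH + row$dH; dS <- dS + row$dS
  }
  for (b in chars[c(1, length(chars))]) {
    cls <- if (b %in% c("G", "C")) "GC" else "AT"
    row <- raw[raw$kind == "init" & raw$key == cls, ]
    dH <- dH + row$dH; dS <- dS + row$dS
  }
  got <- nn_duplex_thermo(seq, cond = toy_cond)  # 1 M monovalent: no salt term
  expect_equal(got$dH, dH, tolerance = 1e-12)
  expect_equal(got$dS, dS + 0.368 * 11 * log((1000 + 120 * sqrt(12.5)) / 1000),
               tolerance = 1e-9)
  expect_equal(got$dG, got$dH - 298.15 * got$dS / 1000, tolerance = 1e-12)
})

test_that("every thermo result satisfies the dG/dH/dS/Kd identities", {
  set.seed(31)
  for (s in random_seqs(25, 12)) {
    for (res in list(nn_duplex_thermo(s),
                     switchback_thermo(s, penalty = 1))) {
      TK <- res$condition$temperature_K
      expect_equal(res$dG, res$dH - TK * res$dS / 1000, tolerance = 1e-9)
      expect_equal(res$Kd, exp(res$dG / (1.987e-3 * TK)), tolerance = 1e-9)
    }
  }
})

test_that("switchback model removes junction stacks and adds the penalty", {
  tt <- toy_nn_table()
  s0 <- switchback_thermo(strrep("CAG", 4), table = tt, penalty = 0,
                          cond = toy_cond)
  expect_equal(s0$dG, -10)                    # 2 domains x 5 stacks
  expect_identical(s0$junctions, 1L)
  s5 <- switchback_thermo(strrep("CAG", 4), table = tt, penalty = 0.5,
                          cond = toy_cond)
  expect_equal(s5$dG, -9.5)
  # entropic bookkeeping leaves dH at the stack sum; enthalpic moves dH
  expect_equal(s5$dH, -10)
  s5h <- switchback_thermo(strrep("CAG", 4), table = tt, penalty = 0.5,
                           cond = toy_cond, bookkeeping = "enthalpic")
  expect_equal(s5h$dH, -9.5)
  expect_equal(s5h$dG, s5$dG)
  # three domains eliminate two junction stacks
  s3 <- switchback_thermo(strrep("CAG", 6), domain_layout(n_domains = 3),
                          table = tt, penalty = 0, cond = toy_cond)
  expect_equal(s3$dG, -15)                    # 3 x 5 stacks
  expect_identical(s3$junctions, 2L)
})

test_that("switchback is never more stable than its duplex for penalty >= 0", {
  set.seed(32)
  for (s in random_seqs(40, 12)) {
    d <- nn_duplex_thermo(s)
    for (pen in c(0, 0.5, 1.97)) {
      sb <- switchback_thermo(s, penalty = pen)
      expect_true(sb$dG > d$dG)
    }
    # monotone in the penalty
    expect_true(switchback_thermo(s, penalty = 2)$dG >=
                  switchback_thermo(s, penalty = 1)$dG)
  }
})

test_that("low magnesium flags switchback predictions unreliable", {
  low <- thermo_condition(mg_mM = 5)
  expect_false(switchback_thermo(strrep("CAG", 4), cond = low)$reliable)
  expect_true(switchback_thermo(strrep("CAG", 4))$reliable)
})

test_that("junction-penalty calibration inverts the model", {
  tt <- toy_nn_table()
  cal <- calibrate_junction_penalty(-11, -9.5, strrep("CAG", 4),
                                    table = tt, cond = toy_cond)
  expect_equal(cal$penalty, 0.5)
  expect_equal(cal$junction_cost, 1.5)
  # identical observations: the penalty exactly restores the eliminated
  # stack's free energy (zero net junction cost)
  cal0 <- calibrate_junction_penalty(-11, -11, strrep("CAG", 4),
                                     table = tt, cond = toy_cond)
  expect_equal(cal0$penalty, cal0$eliminated_stack_dG)
  expect_equal(cal0$junction_cost, 0)
  # round-trip: the calibrated penalty reproduces the observed gap
  set.seed(33)
  for (s in random_seqs(10, 12)) {
    d_obs <- nn_duplex_thermo(s)$dG
    gap <- runif(1, 0.5, 3)
    cal <- calibrate_junction_penalty(d_obs, d_obs + gap, s)
    sb <- switchback_thermo(s, penalty = cal$penalty)
    expect_equal(sb$dG - nn_duplex_thermo(s)$dG, gap, tolerance = 1e-9)
  }
})

test_that("free energy / Kd conversion is a closed-form bijection", {
  expect_equal(free_energy_kd_convert(1, "kd_to_dG", 25), 0)
  expect_equal(free_energy_kd_convert(30.7e-9, "kd_to_dG"), -10.248,
               tolerance = 1e-4)
  expect_equal(free_energy_kd_convert(1.3e-9, "kd_to_dG"), -12.12,
               tolerance = 1e-3)
  expect_error(free_energy_kd_convert(-1, "kd_to_dG"), "positive")
  set.seed(34)
  kd <- 10^runif(1e4, -12, 0)
  back <- free_energy_kd_convert(
    free_energy_kd_convert(kd, "kd_to_dG"), "dG_to_kd")
  expect_equal(back, kd, tolerance = 1e-12)
})

test_that("Boltzmann fits recover melt parameters", {
  tc <- seq(15, 90, by = 0.5)
  clean <- 0.05 + 0.9 / (1 + exp((55 - tc) / 2))
  fit <- fit_melt_curve(data.frame(tc, clean), fit_range = c(15, 90))
  expect_true(fit$converged)
  expect_equal(fit$Tm_C, 55, tolerance = 1e-6)
  expect_equal(fit$width, 2, tolerance = 1e-5)
  # fitted value at Tm equals the baseline midpoint
  mid <- fit$lower + (fit$upper - fit$lower) / 2
  at_tm <- fit$lower + (fit$upper - fit$lower) /
    (1 + exp((fit$Tm_C - fit$Tm_C) / fit$width))
  expect_equal(at_tm, mid, tolerance = 1e-6)
  # noisy recovery within 0.2 C
  set.seed(35)
  noisy <- clean + rnorm(length(tc), sd = 0.01)
  nf <- fit_melt_curve(data.frame(tc, noisy), fit_range = c(15, 90))
  expect_true(nf$converged)
  expect_equal(nf$Tm_C, 55, tolerance = 0.2)
  # flat curve is flagged, not an error
  flat <- fit_melt_curve(data.frame(tc, rep(0.5, length(tc))))
  expect_false(flat$converged)
  # too few points in range is flagged
  few <- fit_melt_curve(data.frame(tc, clean), fit_range = c(54, 56))
  expect_false(few$converged)
})

test_that("mismatch rule orders variants control > 1mm > 2mm-sep > 2mm-adj", {
  set.seed(36)
  for (s in random_seqs(15, 12)) {
    v <- make_mismatch_variants(s)
    g <- vapply(v, function(d)
      mismatch_thermo(s, d, structure = "switchback")$dG, numeric(1))
    expect_true(g[["control"]] < g[["1mm"]])
    expect_true(g[["1mm"]] < g[["2mm-sep"]])
    expect_true(g[["2mm-sep"]] < g[["2mm-adj"]])
  }
  # duplex formation is far less affected: each mismatch a fixed increment
  s <- strrep("CAG", 4)
  v <- make_mismatch_variants(s)
  gd <- vapply(v, function(d)
    mismatch_thermo(s, d, structure = "duplex")$dG, numeric(1))
  expect_equal(gd[["2mm-adj"]], gd[["2mm-sep"]], tolerance = 1e-9)
  expect_equal(gd[["2mm-adj"]] - gd[["control"]], 3, tolerance = 1e-9)
})

test_that("nucleotide-to-complex concentration arithmetic", {
  expect_equal(complex_concentration(80e-6, 28), 80e-6 / 28)
  expect_error(complex_concentration(1e-6, 0), "positive")
})
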