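# homodimer-style pool: A is domain-palindromic, B its duplex complement
A_CORE <- "GGATCCGGTACC"
B_CORE <- duplex_complement(A_CORE)

# heterodimer-style strands: X with distinct switchback and duplex partners
X_CORE <- "AAAAAACCCCCC"
Y_CORE <- switchback_complement(X_CORE)
Z_CORE <- duplex_complement(X_CORE)

test_that("species enumeration finds every feasible dimer with its tag", {
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 1e-6, B = 1e-6))
  sp <- enumerate_species(p)
  expect_setequal(sp$species, c("AA", "AB", "BB"))
  expect_identical(sp$relationship[sp$species == "AA"], "switchback")
  expect_identical(sp$relationship[sp$species == "BB"], "switchback")
  expect_identical(sp$relationship[sp$species == "AB"], "duplex")

  p3 <- strand_pool(c(X = X_CORE, Y = Y_CORE, Z = Z_CORE),
                    c(X = 1e-6, Y = 1e-6, Z = 1e-6))
  sp3 <- enumerate_species(p3)
  expect_setequal(sp3$species, c("XY", "XZ"))
  expect_identical(sp3$relationship[sp3$species == "XY"], "switchback")
  expect_identical(sp3$relationship[sp3$species == "XZ"], "duplex")

  lone <- strand_pool(c(S = "ACGTCAACGTCA"), c(S = 1e-6))
  expect_identical(nrow(enumerate_species(lone)), 0L)
})

test_that("absolute preference fills duplexes first, then switchbacks", {
  conc <- function(part, sp) {
    hit <- part$species$concentration[part$species$species == sp]
    if (length(hit)) hit else 0
  }
  # 1:1 -> all strands in the AB duplex
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 5e-6))
  part <- absolute_preference_partition(p)
  expect_equal(conc(part, "AB"), 5e-6)
  expect_equal(conc(part, "AA"), 0)
  expect_equal(conc(part, "BB"), 0)
  # 1:0 -> homodimer switchback only, at half the strand total
  p0 <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 0))
  part0 <- absolute_preference_partition(p0)
  expect_equal(conc(part0, "AA"), 2.5e-6)
  expect_equal(conc(part0, "AB"), 0)
  # 5 uM : 2 uM -> AB 2 uM, AA 1.5 uM, nothing free
  p52 <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 2e-6))
  part52 <- absolute_preference_partition(p52)
  expect_equal(conc(part52, "AB"), 2e-6)
  expect_equal(conc(part52, "AA"), 1.5e-6)
  expect_equal(unname(part52$free["A"]), 0)
  # X with both complements at 1:1:1 -> X goes entirely to the XZ duplex
  p3 <- strand_pool(c(X = X_CORE, Y = Y_CORE, Z = Z_CORE),
                    c(X = 1e-6, Y = 1e-6, Z = 1e-6))
  part3 <- absolute_preference_partition(p3)
  expect_equal(conc(part3, "XZ"), 1e-6)
  expect_equal(conc(part3, "XY"), 0)
  expect_equal(unname(part3$free["Y"]), 1e-6)
  # X with only its switchback complement still assembles (complex XY)
  pxy <- strand_pool(c(X = X_CORE, Y = Y_CORE), c(X = 1e-6, Y = 1e-6))
  partxy <- absolute_preference_partition(pxy)
  expect_equal(conc(partxy, "XY"), 1e-6)
})

test_that("mass conservation holds on every partition", {
  set.seed(41)
  for (i in 1:10) {
    totals <- runif(2, 0.1e-6, 10e-6)
    p <- strand_pool(c(A = A_CORE, B = B_CORE),
                     c(A = totals[1], B = totals[2]))
    expect_lt(mass_balance_residual(absolute_preference_partition(p)), 1e-10)
    expect_lt(mass_balance_residual(
      mass_action_partition(p, c(AA = 1e6, AB = 1e9, BB = 1e6))), 1e-10)
  }
})

test_that("mass action approaches the absolute limit as duplex K grows", {
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 2e-6))
  abs_part <- absolute_preference_partition(p)
  # the limit needs every K large on the concentration scale (so leftover
  # strands fully homodimerize) with the duplex K larger by the 1e6 ratio
  K_homo <- 1e12
  ma <- mass_action_partition(
    p, c(AA = K_homo, AB = K_homo * 1e6, BB = K_homo))
  expect_true(ma$diagnostics$converged)
  for (sp in c("AA", "AB", "BB")) {
    a <- abs_part$species$concentration[abs_part$species$species == sp]
    m <- ma$species$concentration[ma$species$species == sp]
    expect_lt(abs(a - m), 1e-3 * sum(p$concentrations))
  }
})

test_that("equal per-contact energetics give 1:2:1 random-pairing statistics", {
  # the statistical factor 2 on the hetero species is the convention that
  # makes equal-energy pairing match combinatorics
  K <- 1e8
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 5e-6))
  ma <- mass_action_partition(p, c(AA = K, AB = 2 * K, BB = K))
  cc <- setNames(ma$species$concentration, ma$species$species)
  expect_equal(unname(cc["AB"] / cc["AA"]), 2, tolerance = 1e-6)
  expect_equal(unname(cc["AB"] / cc["BB"]), 2, tolerance = 1e-6)
})

test_that("zero association constants leave everything free", {
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 1e-6, B = 2e-6))
  ma <- mass_action_partition(p, c(AA = 0, AB = 0, BB = 0))
  expect_equal(unname(ma$free), c(1e-6, 2e-6))
  expect_equal(sum(ma$species$concentration), 0)
})

test_that("default association constants derive from the NN model", {
  p <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 1e-6, B = 1e-6))
  ma <- mass_action_partition(p)
  expect_true(ma$diagnostics$converged)
  # duplex K dwarfs the switchback K, so the duplex dominates at 1:1
  cc <- setNames(ma$species$concentration, ma$species$species)
  expect_gt(cc["AB"], 100 * (cc["AA"] + cc["BB"]))
})

test_that("titration series peaks at 1:1 and displacement completes at 1.25 eq", {
  grid <- ratio_grid(0:10, 10:0, c("B", "A"), total = 10e-6)
  ts <- titration_series(c(A = A_CORE, B = B_CORE), grid)
  duplex <- ts$summary$AB
  # duplex yield maximal at the 5:5 point, monotone on both flanks
  expect_identical(which.max(duplex), 6L)
  expect_true(all(diff(duplex[1:6]) >= 0))
  expect_true(all(diff(duplex[6:11]) <= 0))
  # expected-yield law: strand fraction in duplex = 2 min(r, 10-r) / 10
  total <- 10e-6
  for (k in seq_len(nrow(grid))) {
    r <- 0:10
    expect_equal(2 * duplex[k] / total,
                 2 * min(r[k], 10 - r[k]) / 10, tolerance = 1e-12)
  }
  # switchback species monotone on either side of the maximum:
  # AA falls as B is added, BB grows once B is in excess
  aa <- ts$summary$AA
  bb <- ts$summary$BB
  expect_true(all(diff(aa) <= 1e-18))
  expect_true(all(diff(bb) >= -1e-18))
  expect_true(all(aa[1:5] > 0) && aa[6] == 0)
  expect_true(all(bb[7:11] > 0) && bb[6] == 0)
  # displacement endpoint: duplex complement at 1.25 equivalents leaves
  # no switchback homodimer
  disp <- strand_pool(c(A = A_CORE, B = B_CORE),
                      c(A = 4e-6, B = 5e-6))
  dd <- absolute_preference_partition(disp)
  cc <- setNames(dd$species$concentration, dd$species$species)
  expect_equal(unname(cc["AA"]), 0)
  expect_equal(unname(cc["AB"]), 4e-6)
  # single-point grid equals a direct partition call
  one <- titration_series(c(A = A_CORE, B = B_CORE),
                          ratio_grid(5, 5, c("A", "B"), total = 10e-6))
  direct <- absolute_preference_partition(
    strand_pool(c(A = A_CORE, B = B_CORE), c(A = 5e-6, B = 5e-6)))
  expect_equal(one$partitions[[1]]$species$concentration,
               direct$species$concentration)
})

test_that("equilibrium output is independent of strand order (path independence)", {
  p1 <- strand_pool(c(A = A_CORE, B = B_CORE), c(A = 3e-6, B = 7e-6))
  p2 <- strand_pool(c(B = B_CORE, A = A_CORE), c(B = 7e-6, A = 3e-6))
  K <- c(AA = 1e6, AB = 1e9, BB = 1e6)
  m1 <- mass_action_partition(p1, K)
  m2 <- mass_action_partition(p2, K)
  cc1 <- setNames(m1$species$concentration, m1$species$species)
  cc2 <- setNames(m2$species$concentration, m2$species$species)
  expect_identical(cc1[c("AA", "AB", "BB")], cc2[c("AA", "AB", "BB")])
  a1 <- absolute_preference_partition(p1)
  a2 <- absolute_preference_partition(p2)
  expect_identical(
    setNames(a1$species$concentration, a1$species$species)[c("AA", "AB", "BB")],
    setNames(a2$species$concentration, a2$species$species)[c("AA", "AB", "BB")])
})
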