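test_that("pairwise mismatch rate equals a naive recount", {
  # tiny hand case
  snp <- data.frame(id = paste0("s", 1:5), chrom = 1, cm = 1:5,
                    pos = 1:5, ref = "A", alt = "G")
  ind <- data.frame(id = c("i", "j"), sex = "M")
  g <- cbind(c(0L, 0L, 2L, NA, 0L), c(0L, 2L, 2L, 0L, 0L))
  panel <- genotype_panel(g, snp, ind, pseudohaploid = TRUE)
  r <- pairwise_mismatch_rate(panel, "i", "j")
  expect_equal(r$n_overlap, 4L)
  expect_equal(r$pmr, 0.25)
  # identical columns -> zero
  panel2 <- genotype_panel(cbind(g[, 1], g[, 1]), snp, ind,
                           pseudohaploid = TRUE)
  expect_equal(pairwise_mismatch_rate(panel2, "i", "j")$pmr, 0)
  # random panels against an independent naive loop
  set.seed(9)
  for (rep in 1:3) {
    n <- 1000
    snp <- data.frame(id = paste0("s", 1:n), chrom = sample(1:4, n, TRUE),
                      cm = runif(n, 0, 100), pos = 1:n, ref = "A", alt = "G")
    gm <- matrix(sample(c(0L, 2L, NA), 2 * n, TRUE), ncol = 2)
    panel <- genotype_panel(gm, snp, data.frame(id = c("i", "j"), sex = "M"),
                            pseudohaploid = TRUE)
    got <- pairwise_mismatch_rate(panel, "i", "j")
    mm <- 0L; nn <- 0L
    for (k in seq_len(n)) {
      if (!is.na(gm[k, 1]) && !is.na(gm[k, 2])) {
        nn <- nn + 1L
        if (gm[k, 1] != gm[k, 2]) mm <- mm + 1L
      }
    }
    expect_equal(got$n_overlap, nn)
    expect_equal(got$pmr, mm / nn)
  }
  # zero overlap -> sentinel
  g0 <- cbind(c(0L, NA), c(NA, 0L))
  snp0 <- data.frame(id = c("a", "b"), chrom = 1, cm = 1:2, pos = 1:2,
                     ref = "A", alt = "G")
  p0 <- genotype_panel(g0, snp0, data.frame(id = c("i", "j"), sex = "M"),
                       pseudohaploid = TRUE)
  expect_equal(pairwise_mismatch_rate(p0, "i", "j")$n_overlap, 0L)
  expect_true(is.na(pairwise_mismatch_rate(p0, "i", "j")$pmr))
})

test_that("PMR normalisation and classification follow the midpoint cutoffs", {
  pairs <- data.frame(pmr = c(0.18, 0.24), pmr_se = c(0.001, 0.001))
  out <- normalize_pmr(pairs, "explicit-baseline", baseline = 0.24)
  expect_equal(out$normalized_pmr, c(0.75, 1.0))
  expect_error(normalize_pmr(data.frame(pmr = 1,
                                        presumed_unrelated = FALSE),
                             "median-of-unrelated"), "config-error")
  expect_equal(classify_degree(0.75, 0.005, 20000), "1st")
  expect_equal(classify_degree(0.99, 0.005, 20000), "unrelated")
  expect_equal(classify_degree(0.52, 0.005, 20000), "identical")
  expect_equal(classify_degree(0.875, 0.005, 20000), "2nd")
  expect_equal(classify_degree(0.9375, 0.004, 20000), "3rd")
  expect_equal(classify_degree(0.75, 0.005, 800), "undetermined")
  # CI spanning a cutoff withholds the call
  expect_equal(classify_degree(0.81, 0.02, 20000), "undetermined")
})

test_that("normalised PMR hits the theoretical levels per relationship class", {
  st <- small_study()
  panel <- st$panel
  b <- st$baseline
  norm <- function(i, j) pairwise_mismatch_rate(panel, i, j)$pmr / b
  # single gene-drop realisations carry IBD-process noise of a few percent
  expect_lt(abs(norm("B1", "B3") - 0.75), 0.05)    # siblings
  expect_lt(abs(norm("B1", "B1s") - 0.75), 0.05)   # parent-child
  expect_lt(abs(norm("B1", "B4") - 0.875), 0.05)   # grandparent
  expect_lt(abs(norm("F0", "W2") - 1.0), 0.05)     # unrelated
  # duplicate observation of one individual behaves as identical twins
  rd2 <- degrade_to_reads(st$geno[, "B1", drop = FALSE],
                          observation_model(1.2), seed = 99)
  cal2 <- pseudohaploid_call(rd2, seed = 100)
  g2 <- cbind(panel$geno, B1dup = cal2[, 1])
  panel2 <- genotype_panel(g2, panel$snp,
                           rbind(panel$ind, data.frame(id = "B1dup",
                                                       sex = "M")),
                           pseudohaploid = TRUE)
  expect_lt(abs(pairwise_mismatch_rate(panel2, "B1", "B1dup")$pmr / b - 0.5),
            0.04)
})

test_that("genotype likelihoods are binomial read-sampling probabilities", {
  gl <- genotype_likelihoods(c(2L, 1L, 0L), c(0L, 1L, 3L), error = 0.01)
  # ordering at a homozygous-looking site
  expect_true(gl[1, 1] > gl[1, 2] && gl[1, 2] > gl[1, 3])
  # het maximal with balanced reads
  expect_true(which.max(gl[2, ]) == 2)
  # hand-computed binomial values
  expect_equal(unname(gl[1, 1]), dbinom(0, 2, 0.01))
  expect_equal(unname(gl[2, 2]), dbinom(1, 2, 0.5))
  expect_equal(unname(gl[3, 3]), dbinom(3, 3, 0.99))
  expect_error(genotype_likelihoods(1L, 1L, error = 0.6), "error")
})

test_that("ML k-coefficients recover canonical relationships", {
  st <- small_study()
  ids <- c("B1", "B1s", "B3", "F0", "W1")
  gls <- genotype_likelihoods(st$sim$reads$ref[, ids],
                              st$sim$reads$alt[, ids], error = 0.01)
  f <- st$freqs$f
  po <- ml_k_coefficients(gls[["B1"]], gls[["B1s"]], f, grid_step = 0.05)
  expect_lt(po$k0, 0.05)
  # compare to the realised relatedness of this gene drop, r = 2 phi
  r_po <- mean(ibd_states(st$gd, "B1", "B1s")) / 2
  expect_lt(abs(po$r - r_po), 0.06)
  sib <- ml_k_coefficients(gls[["B1"]], gls[["B3"]], f, grid_step = 0.05)
  r_sib <- mean(ibd_states(st$gd, "B1", "B3")) / 2
  expect_lt(abs(sib$r - r_sib), 0.06)
  expect_gt(sib$k2, 0.1)
  un <- ml_k_coefficients(gls[["F0"]], gls[["W1"]], f, grid_step = 0.05)
  expect_gt(un$k0, 0.9)
  # simplex constraint and a sane optimum
  for (e in list(po, sib, un)) {
    expect_equal(e$k0 + e$k1 + e$k2, 1, tolerance = 1e-6)
    expect_true(all(c(e$k0, e$k1, e$k2) >= -1e-9))
  }
  # likelihood at the optimum is at least that of forced-unrelated
  co <- paleokin:::ml_site_coeffs(gls[["B1"]], gls[["B1s"]], f)
  keep <- rowSums(gls[["B1"]]) < 2.999 & rowSums(gls[["B1s"]]) < 2.999
  ll_unrel <- sum(log(co[keep, ] %*% c(1, 0, 0)))
  expect_gte(po$loglik, ll_unrel)
  # degenerate input refuses
  empty <- matrix(1, 10, 3)
  out <- ml_k_coefficients(empty, empty, rep(0.5, 10))
  expect_true(is.na(out$k0))
  expect_equal(classify_degree_from_r(NA), "undetermined")
  expect_equal(classify_degree_from_r(0.5), "1st")
  expect_equal(classify_degree_from_r(0.25), "2nd")
  expect_equal(classify_degree_from_r(0.12), "3rd")
  expect_equal(classify_degree_from_r(0.01), "unrelated")
})

test_that("the windowed HMM separates siblings from parent-offspring", {
  st <- small_study()
  sib <- first_degree_type_hmm(st$panel, "B1", "B3", st$baseline)
  po <- first_degree_type_hmm(st$panel, "B1", "B1s", st$baseline)
  expect_equal(sib$type, "sibling")
  expect_equal(po$type, "parent-offspring")
  expect_gt(sib$loglik_margin, 0)
  expect_gt(po$loglik_margin, 0)
  # too few windows -> NA
  tiny_snp <- st$panel$snp[st$panel$snp$chrom == 1 & st$panel$snp$cm < 30, ]
  idx <- match(tiny_snp$id, st$panel$snp$id)
  tiny <- genotype_panel(st$panel$geno[idx, , drop = FALSE], tiny_snp,
                         st$panel$ind, pseudohaploid = TRUE)
  res <- first_degree_type_hmm(tiny, "B1", "B3", st$baseline)
  expect_true(is.na(res$type))
})

test_that("consensus fusion flags conflicts and respects confidence", {
  m1 <- data.frame(id1 = "a", id2 = "b", degree_call = "1st", confidence = 1)
  m2 <- data.frame(id1 = "a", id2 = "b", degree_call = "1st", confidence = 1)
  m3 <- data.frame(id1 = "b", id2 = "a", degree_call = "1st", confidence = 1)
  cons <- consensus_degrees(list(x = m1, y = m2, z = m3))
  expect_equal(cons$consensus, "1st")
  expect_false(cons$conflict)
  # disagreement among determined methods is flagged, both reported
  m4 <- data.frame(id1 = "a", id2 = "b", degree_call = "2nd", confidence = 0.5)
  m5 <- data.frame(id1 = "a", id2 = "b", degree_call = "undetermined",
                   confidence = 1)
  cons2 <- consensus_degrees(list(x = m1, y = m4, z = m5))
  expect_true(cons2$conflict)
  expect_equal(cons2$consensus, "1st")  # higher total weight
  expect_match(cons2$calls, "2nd")
  # all undetermined stays undetermined
  cons3 <- consensus_degrees(list(x = m5))
  expect_equal(cons3$consensus, "undetermined")
})
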