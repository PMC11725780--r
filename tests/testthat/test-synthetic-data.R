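test_that("frequency panels respect range, moments and determinism", {
  f1 <- draw_frequencies(10, beta_shape = c(1, 1), seed = 1)
  expect_true(all(f1$f >= 0.01 & f1$f <= 0.99))
  expect_error(draw_frequencies(0), "invalid-argument")
  expect_error(draw_frequencies(10, beta_shape = c(-1, 1)), "invalid-argument")
  # Beta(0.5, 0.5) mean is 0.5; truncation is symmetric so the mean holds
  f2 <- draw_frequencies(1e5, beta_shape = c(0.5, 0.5), seed = 2)
  expect_equal(mean(f2$f), 0.5, tolerance = 0.01)
  expect_identical(draw_frequencies(500, seed = 3),
                   draw_frequencies(500, seed = 3))
  # map positions nondecreasing within chromosomes
  expect_true(all(tapply(f2$cm, f2$chrom, function(x) !is.unsorted(x))))
})

test_that("pedigree validation catches structural violations", {
  ped <- cao_pedigree()
  expect_silent(validate_pedigree(ped))
  bad <- ped; bad$mother[bad$id == "M0"] <- "B1s"  # descendant as parent
  expect_error(validate_pedigree(bad), "invalid-pedigree")
  bad2 <- ped; bad2$father[bad2$id == "B1"] <- "M0"  # female father
  expect_error(validate_pedigree(bad2), "male id")
  bad3 <- ped; bad3$birth_year[bad3$id == "B1s"] <- 480  # too soon after B1
  expect_error(validate_pedigree(bad3), "born too soon")
  bad4 <- ped; bad4$mt_lineage[bad4$id == "B1"] <- "mtX"
  expect_error(validate_pedigree(bad4), "mt lineage")
})

test_that("gene drop reproduces Mendelian kinship and IBD expectations", {
  st <- small_study()
  gd <- st$gd
  # parent-offspring: always exactly one shared haplotype
  expect_true(all(ibd_states(gd, "B1", "B1s") == 1))
  # full sibs: genome-wide IBD proportions near (1/4, 1/2, 1/4)
  ib <- ibd_states(gd, "B1", "B3")
  expect_lt(abs(mean(ib == 0) - 0.25), 0.06)
  expect_lt(abs(mean(ib == 1) - 0.50), 0.06)
  expect_lt(abs(mean(ib == 2) - 0.25), 0.06)
  # unrelated founders share nothing
  expect_true(all(ibd_states(gd, "F0", "W1") == 0))
  # grandparent-grandchild: IBD0/IBD1 only, about half and half
  ib2 <- ibd_states(gd, "B1", "B4")
  expect_true(all(ib2 %in% 0:1))
  expect_equal(mean(ib2 == 1), 0.5, tolerance = 0.1)
  # every child allele traceable to a parent haplotype
  k <- which(gd$ped$id == "B1")
  par_orgs <- c(gd$o1[, "M0"], gd$o2[, "M0"], gd$o1[, "F0"], gd$o2[, "F0"])
  expect_true(all(gd$o1[, "B1"] %in% par_orgs))
  expect_true(all(gd$o2[, "B1"] %in% par_orgs))
  expect_error(gene_drop(data.frame(id = "a", sex = "M", mother = NA,
                                    father = "a"), st$freqs),
               "invalid-pedigree")
})

test_that("realized kinship matches pedigree expectation across degrees", {
  st <- small_study()
  gd <- st$gd
  phi_real <- function(i, j) mean(ibd_states(gd, i, j)) / 4
  expect_lt(abs(phi_real("B1", "B1s") - 1 / 4), 0.02)   # 1st
  expect_lt(abs(phi_real("B1", "B4") - 1 / 8), 0.03)    # 2nd
  expect_lt(abs(phi_real("B4", "B1s") - 1 / 16), 0.02)  # 3rd
  expect_equal(phi_real("F0", "GW"), 0)
})

test_that("the observation model degrades genotypes as configured", {
  st <- small_study()
  g <- st$geno[1:5000, c("B1", "B3"), drop = FALSE]
  # zero depth -> everything missing
  rd0 <- degrade_to_reads(g, observation_model(0), seed = 1)
  expect_true(all(rd0$ref + rd0$alt == 0))
  cal0 <- pseudohaploid_call(rd0, seed = 1)
  expect_true(all(is.na(cal0)))
  # deep error-free coverage: majority allele equals truth at hom sites
  rd <- degrade_to_reads(g, observation_model(30, 0, 0), seed = 2)
  hom <- g[, 1] %in% c(0L, 2L) & (rd$ref + rd$alt)[, 1] > 0
  maj <- ifelse(rd$alt[, 1] > rd$ref[, 1], 2L, 0L)
  expect_gt(mean(maj[hom] == g[hom, 1]), 0.999)
  # pseudohaploid calls at het sites split ~50/50
  het <- g[, 1] == 1L
  calls <- pseudohaploid_call(rd, seed = 3)[, 1]
  expect_equal(mean(calls[het] == 2L, na.rm = TRUE), 0.5, tolerance = 0.03)
  # damage elevates the configured-direction allele at the configured rate
  rdd <- degrade_to_reads(g, observation_model(20, 0, damage_rate = 0.3),
                          seed = 4)
  ra <- g[, 1] == 0L & rdd$damage_dir == 1L   # true ref, ref->alt damage
  rate <- sum(rdd$alt[ra, 1]) / sum(rdd$ref[ra, 1] + rdd$alt[ra, 1])
  expect_equal(rate, 0.3, tolerance = 0.02)
  # identity preserved with no error and no damage
  rd_id <- degrade_to_reads(g, observation_model(5, 0, 0), seed = 5)
  expect_true(all(rd_id$alt[g == 0L] == 0))
  expect_true(all(rd_id$ref[g == 2L] == 0))
})

test_that("simulated sex-chromosome counts separate XX from XY", {
  m <- simulate_sexchr_counts("M", 1e6, seed = 1)
  f <- simulate_sexchr_counts("F", 1e6, seed = 2)
  expect_gt(m$nY / (m$nX + m$nY), 0.075)
  expect_lt(f$nY / (f$nX + f$nY), 0.016)
  tiny <- simulate_sexchr_counts("M", 10, seed = 3)
  call <- ry_sex(tiny$nY, tiny$nX)
  expect_equal(call$call, "undetermined")
})

test_that("radiocarbon simulation follows the curve-mixture identities", {
  curves <- synthetic_calcurves()
  ped <- cao_pedigree()
  ta <- c(B1 = 15)
  # marine fraction 0: independent of deltaR, equal to terrestrial curve
  d1 <- simulate_c14(ped, ta, c(B1 = 0), deltaR = -500, curves, seed = 1,
                     noise = FALSE)
  d2 <- simulate_c14(ped, ta, c(B1 = 0), deltaR = 300, curves, seed = 1,
                     noise = FALSE)
  expect_equal(d1$c14_age, d2$c14_age)
  t_bp <- 1950 - (475 + 15)
  expect_equal(d1$c14_age, curve_at(curves$terrestrial, t_bp)$mu)
  # marine fraction 1 with deltaR 100: marine curve plus 100
  d3 <- simulate_c14(ped, ta, c(B1 = 1), deltaR = 100, curves, seed = 1,
                     noise = FALSE)
  expect_equal(d3$c14_age, curve_at(curves$marine, t_bp)$mu + 100)
  expect_error(simulate_c14(ped, ta, c(B1 = 1.2), 0, curves),
               "invalid-argument")
})

test_that("fixed seeds make the whole generator reproducible", {
  f <- draw_frequencies(2000, seed = 5)
  ped <- cao_pedigree()
  g1 <- gene_drop(ped, f, seed = 6)
  g2 <- gene_drop(ped, f, seed = 6)
  expect_identical(g1, g2)
  r1 <- degrade_to_reads(genotypes(g1), observation_model(0.5), seed = 7)
  r2 <- degrade_to_reads(genotypes(g2), observation_model(0.5), seed = 7)
  expect_identical(r1, r2)
  expect_identical(pseudohaploid_call(r1, seed = 8),
                   pseudohaploid_call(r2, seed = 8))
})

test_that("pedigree text files round-trip", {
  ped <- cao_pedigree()
  path <- file.path(tempdir(), "ped.tsv")
  write_pedigree_file(ped, path)
  back <- read_pedigree_file(path)
  expect_equal(back$id, ped$id)
  expect_equal(back$mother, ped$mother)
  expect_equal(back$mt_lineage, ped$mt_lineage)
})
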