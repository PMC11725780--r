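test_that("pedigree kinship matches textbook values and degrees", {
  ped <- cao_pedigree()
  phi <- pedigree_kinship(ped)
  expect_equal(phi["B1", "B1s"], 1 / 4)   # parent-child
  expect_equal(phi["B1", "B3"], 1 / 4)    # full sibs
  expect_equal(phi["B1", "B4"], 1 / 8)    # grandparent
  expect_equal(phi["B4", "B1s"], 1 / 16)  # great-grandparent
  expect_equal(phi["F0", "W1"], 0)
  expect_equal(degree_from_phi(c(1 / 4, 1 / 8, 1 / 16, 1 / 64, 0)),
               c("1st", "2nd", "3rd", "unrelated", "unrelated"))
  # half sibs
  hs <- data.frame(id = c("m", "a", "b"), sex = c("F", "M", "M"),
                   mother = c(NA, "m", "m"), father = NA)
  expect_equal(pedigree_kinship(hs)["a", "b"], 1 / 8)
  cyc <- data.frame(id = c("a", "b"), sex = c("F", "M"),
                    mother = c("a", "a")[c(2, 1)], father = NA)
  cyc$mother <- c("b", "a")  # a's mother b, b's mother a
  cyc$sex <- c("F", "F")
  expect_error(pedigree_kinship(cyc), "cycle")
})

test_that("pedigree kinship agrees with the gene-dropping oracle", {
  freqs <- draw_frequencies(20000, seed = 51)
  set.seed(52)
  for (rep in 1:4) {
    # random 3-generation pedigree (non-consanguineous couples)
    ped <- data.frame(id = c("g1", "g2", "p1", "p2", "p3", "c1", "c2"),
                      sex = c("M", "F", "M", "F", "M", "M", "F"),
                      mother = c(NA, NA, "g2", NA, NA, "p2", "p2"),
                      father = c(NA, NA, "g1", NA, NA, sample(c("p1", "p3"), 1),
                                 sample(c("p1", "p3"), 1)),
                      stringsAsFactors = FALSE)
    phi <- pedigree_kinship(ped)
    gd <- gene_drop(ped, freqs, seed = 52 + rep)
    for (pair in list(c("c1", "c2"), c("p1", "c1"), c("g1", "c2"))) {
      realized <- mean(ibd_states(gd, pair[1], pair[2])) / 4
      expect_lt(abs(realized - phi[pair[1], pair[2]]), 0.04)
    }
  }
})

test_that("two-individual enumeration honours age-gap logic", {
  # elder 30y older, equal death dates: parent-offspring with elder as
  # parent is present; sibling also allowed (gap under 45)
  ev <- list(ids = c("E", "Y"), sex = c(E = "F", Y = "M"),
             degrees = data.frame(id1 = "E", id2 = "Y", degree = "1st",
                                  confidence = 1, stringsAsFactors = FALSE),
             birth_interval = list(E = c(440, 450), Y = c(470, 480)))
  res <- enumerate_candidates(ev, max_latent = 2)
  expect_true(res$complete)
  has_po <- any(vapply(res$candidates, function(p) ped_po(p, "Y", "E"), TRUE))
  has_sib <- any(vapply(res$candidates, function(p) ped_sibs(p, "E", "Y"), TRUE))
  has_po_rev <- any(vapply(res$candidates, function(p) ped_po(p, "E", "Y"), TRUE))
  expect_true(has_po)
  expect_true(has_sib)   # 30 y gap still allows siblinghood
  expect_false(has_po_rev)  # the younger cannot be the parent
  # with a gap beyond the sibling plausibility window the pedigree search
  # still allows siblings through shared latent parents only if the age
  # propagation works out; a 60-year gap cannot
  ev2 <- ev
  ev2$birth_interval <- list(E = c(400, 405), Y = c(470, 475))
  res2 <- enumerate_candidates(ev2, max_latent = 2)
  has_sib2 <- any(vapply(res2$candidates, function(p) ped_sibs(p, "E", "Y"), TRUE))
  expect_false(has_sib2)
})

test_that("the published-evidence search contains the reconstructed tree", {
  ev <- burial_group_evidence()
  res <- enumerate_candidates(ev, max_latent = 3, cap = 1e7)
  expect_true(res$complete)
  expect_gt(length(res$candidates), 0)
  is_family_tree <- vapply(res$candidates, function(p)
    ped_sibs(p, "B1", "B3") && ped_sibs(p, "B1", "B2") &&
    ped_po(p, "B1s", "B1") && ped_grandparent(p, "B1", "B4") &&
    ped_po(p, "B3s", "B2"), TRUE)
  expect_true(any(is_family_tree))
  # the alternative placement of B3s (child of an unknown sibling) is also
  # reported, not decided away
  alt_b3s <- vapply(res$candidates, function(p) {
    m <- p$mother[p$id == "B3s"]; f <- p$father[p$id == "B3s"]
    par <- c(m, f)
    par <- par[!is.na(par)]
    any(vapply(par, function(x) !p$sampled[p$id == x] &&
          ped_sibs(p, x, "B1"), TRUE))
  }, TRUE)
  expect_true(any(alt_b3s))
})

test_that("contradictory evidence empties or flags the candidate set", {
  ev <- list(ids = c("A", "B", "C"),
             sex = c(A = "M", B = "F", C = "M"),
             degrees = data.frame(id1 = c("A", "B", "A"),
                                  id2 = c("B", "C", "C"),
                                  degree = c("1st", "1st", "unrelated"),
                                  confidence = 1, stringsAsFactors = FALSE),
             birth_interval = list(A = c(470, 480), B = c(470, 480),
                                   C = c(470, 480)))
  res <- enumerate_candidates(ev, max_latent = 3)
  expect_true(res$complete)
  # A-B 1st and B-C 1st with tight equal dates force sibling-like links,
  # which contradict A-C unrelated; only structures avoiding shared
  # ancestry survive (half-relations through distinct parents)
  for (p in res$candidates) {
    phi <- pedigree_kinship(p)
    expect_equal(degree_from_phi(phi["A", "B"]), "1st")
    expect_equal(degree_from_phi(phi["B", "C"]), "1st")
    expect_equal(degree_from_phi(phi["A", "C"]), "unrelated")
  }
})

test_that("the true pedigree always survives enumeration with correct degrees", {
  set.seed(53)
  for (rep in 1:6) {
    # random small family: couple with 2-3 children, maybe a grandchild
    nk <- sample(2:3, 1)
    ped <- data.frame(id = c("pa", "ma", paste0("k", seq_len(nk))),
                      sex = c("M", "F", sample(c("M", "F"), nk, TRUE)),
                      mother = c(NA, NA, rep("ma", nk)),
                      father = c(NA, NA, rep("pa", nk)),
                      stringsAsFactors = FALSE)
    sampled <- c(paste0("k", seq_len(nk)), if (runif(1) < 0.5) "pa")
    phi <- pedigree_kinship(ped)
    cmb <- utils::combn(sampled, 2)
    degrees <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                          degree = degree_from_phi(phi[cbind(cmb[1, ], cmb[2, ])]),
                          confidence = 1, stringsAsFactors = FALSE)
    ev <- list(ids = sampled,
               sex = stats::setNames(ped$sex[match(sampled, ped$id)], sampled),
               degrees = degrees)
    res <- enumerate_candidates(ev, max_latent = 3)
    # one candidate must induce exactly the true degrees (guaranteed by
    # construction of the final filter); check the true structure appears
    found <- FALSE
    for (p in res$candidates) {
      phi2 <- pedigree_kinship(p)
      if (all(abs(phi2[cbind(cmb[1, ], cmb[2, ])] -
                  phi[cbind(cmb[1, ], cmb[2, ])]) < 1e-9)) found <- TRUE
    }
    expect_true(found)
  }
})

test_that("scoring prefers structures matching all the evidence", {
  ev <- burial_group_evidence()
  res <- enumerate_candidates(ev, max_latent = 3, cap = 1e7)
  sc <- score_candidates(res$candidates, ev)
  expect_equal(nrow(sc), length(res$candidates))
  cands <- attr(sc, "candidates")
  # top-ranked candidate places B2 as a full sibling of B1/B3
  top <- cands[[1]]
  expect_true(ped_sibs(top, "B1", "B2"))
  expect_true(ped_sibs(top, "B1", "B3"))
  expect_true(ped_po(top, "B1s", "B1"))
  # B2-as-parent scores strictly below B2-as-sibling
  sib_scores <- sc$score[vapply(cands, function(p)
    ped_sibs(p, "B1", "B2") && ped_sibs(p, "B1", "B3"), TRUE)]
  par_scores <- sc$score[vapply(cands, function(p)
    ped_po(p, "B1", "B2"), TRUE)]
  if (length(par_scores)) expect_gt(max(sib_scores), max(par_scores))
  # scores are permutation invariant to candidate order
  idx <- rev(seq_along(res$candidates))
  sc2 <- score_candidates(res$candidates[idx], ev)
  expect_equal(sort(sc2$score), sort(sc$score))
})

test_that("generational-gap arithmetic vetoes impossible grandmother claims", {
  # an individual dead at <= 30 cannot have a 12-15 year old grandchild
  # born before her death: grandparent paths need two 12+ year gaps
  ev <- list(ids = c("G", "S"), sex = c(G = "F", S = "F"),
             degrees = data.frame(id1 = "G", id2 = "S", degree = "2nd",
                                  confidence = 1, stringsAsFactors = FALSE),
             birth_interval = list(G = c(470, 475), S = c(485, 488)))
  res <- enumerate_candidates(ev, max_latent = 3)
  grandparent_of_s <- vapply(res$candidates, function(p)
    ped_grandparent(p, "S", "G"), TRUE)
  expect_false(any(grandparent_of_s))
  # avuncular placements remain available
  expect_gt(length(res$candidates), 0)
})

test_that("mt-lineage mismatches on maternal paths veto candidates", {
  # two females, 1st degree, different mt lineages: every 1st-degree
  # relationship between two females runs through a maternal path
  # (mother-daughter, or full sisters via the shared mother), so all
  # candidates are vetoed
  ev <- list(ids = c("A", "B"), sex = c(A = "F", B = "F"),
             degrees = data.frame(id1 = "A", id2 = "B", degree = "1st",
                                  confidence = 1, stringsAsFactors = FALSE),
             mt_lineage = c(A = "mt1", B = "mt2"),
             birth_interval = list(A = c(440, 460), B = c(470, 490)))
  res <- enumerate_candidates(ev, max_latent = 2)
  sc <- score_candidates(res$candidates, ev)
  expect_true(all(sc$vetoed))
  # two males with different labels: father-son has no maternal path and
  # survives; full brothers share the mother and are vetoed
  ev2 <- ev
  ev2$sex <- c(A = "M", B = "M")
  res2 <- enumerate_candidates(ev2, max_latent = 2)
  sc2 <- score_candidates(res2$candidates, ev2)
  cands2 <- attr(sc2, "candidates")
  for (k in seq_len(nrow(sc2))) {
    p <- cands2[[k]]
    if (ped_sibs(p, "A", "B")) expect_true(sc2$vetoed[k])
  }
  surv_po <- vapply(seq_len(nrow(sc2)), function(k)
    !sc2$vetoed[k] && ped_po(cands2[[k]], "B", "A"), TRUE)
  expect_true(any(surv_po))
})
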