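# Shared fixtures: small simulated studies used across test files.
# Built once per test run and memoised in this environment.

.fixture_env <- new.env()

small_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  ped <- cao_pedigree()
  freqs <- draw_frequencies(40000, seed = 11)
  gd <- gene_drop(ped, freqs, seed = 12)
  geno <- genotypes(gd)
  depths <- c(B1 = 1.2, B1s = 1.2, B2 = 1.2, B3 = 1.2, B3s = 1.2, B4 = 1.2,
              F0 = 1.2, W1 = 1.2, W2 = 1.2, GW = 1.2)
  sim <- simulate_reads_panel(geno, depths, seed = 13)
  panel <- panel_from_calls(sim$calls, freqs, ped, sampled_only = FALSE)
  baseline <- stats::median(vapply(
    list(c("F0", "W1"), c("F0", "W2"), c("W1", "W2"), c("GW", "F0")),
    function(p) pairwise_mismatch_rate(panel, p[1], p[2])$pmr, 0))
  .fixture_env$study <- list(ped = ped, freqs = freqs, gd = gd, geno = geno,
                             sim = sim, panel = panel, baseline = baseline)
  .fixture_env$study
}

# pedigree whose proband X is the child of second cousins
second_cousin_pedigree <- function() second_cousin_pedigree_fixture()

# relationship predicates on candidate pedigrees
ped_sibs <- function(p, a, b) {
  m1 <- p$mother[p$id == a]; m2 <- p$mother[p$id == b]
  f1 <- p$father[p$id == a]; f2 <- p$father[p$id == b]
  isTRUE(!is.na(m1) && !is.na(m2) && m1 == m2 &&
         !is.na(f1) && !is.na(f2) && f1 == f2)
}
ped_po <- function(p, ch, pa) {
  r <- p[p$id == ch, ]
  isTRUE((!is.na(r$mother) && r$mother == pa) ||
         (!is.na(r$father) && r$father == pa))
}
ped_grandparent <- function(p, gc, g) {
  pars <- c(p$mother[p$id == gc], p$father[p$id == gc])
  any(vapply(pars[!is.na(pars)], function(x) ped_po(p, x, g), TRUE))
}

# evidence list matching the fixture pedigree's true relationships
burial_group_evidence <- function() {
  list(
    ids = c("B4", "B1", "B2", "B3", "B1s", "B3s"),
    sex = c(B4 = "M", B1 = "M", B2 = "M", B3 = "F", B1s = "M", B3s = "F"),
    degrees = data.frame(
      id1 = c("B1", "B1", "B1", "B1", "B3", "B3", "B3", "B4"),
      id2 = c("B3", "B1s", "B2", "B4", "B4", "B1s", "B3s", "B1s"),
      degree = c("1st", "1st", "1st", "2nd", "2nd", "2nd", "2nd", "3rd"),
      confidence = 1, stringsAsFactors = FALSE),
    mt_lineage = c(B1 = "mtD-1", B1s = "mtD-1", B2 = "mtD-1", B3 = "mtD-1",
                   B3s = "mtD-2"),
    birth_interval = list(B1 = c(455, 495), B2 = c(460, 500),
                          B3 = c(455, 495), B1s = c(475, 505),
                          B3s = c(475, 505), B4 = c(415, 460)),
    first_degree_type = data.frame(
      id1 = c("B1", "B1"), id2 = c("B3", "B1s"),
      type = c("sibling", "parent-offspring"), margin = c(50, 25),
      stringsAsFactors = FALSE))
}
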