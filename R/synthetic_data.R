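#' @title Synthetic pedigree and observation generator
#' @name synthetic_data
#' @description Ground-truth generator for the whole pipeline: a known
#'   pedigree is gene-dropped over a SNP panel, observed at low coverage with
#'   sequencing error and post-trim residual damage, pseudohaploidised, and
#'   paired with synthetic sex-chromosome read counts, isotope records and
#'   radiocarbon determinations.
NULL

#' Validate a pedigree table
#'
#' A pedigree is a data.frame with one row per individual and columns
#' `id`, `sex` ("M"/"F"), `mother`, `father` (ids or NA), `birth_year`
#' (calendar CE), `age_at_death` (years), `mt_lineage`, `sampled` (logical).
#'
#' Checks: acyclicity, mother female / father male, child born more than
#' 12 years after each parent, child mt lineage equal to its mother's.
#'
#' @param ped pedigree data.frame.
#' @return `ped` invisibly; stops with "invalid-pedigree" on violation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "sex", "mother", "father")
  if (!all(need %in% names(ped))) stop("invalid-pedigree: missing columns")
  if (anyDuplicated(ped$id)) stop("invalid-pedigree: duplicate ids")
  ord <- pedigree_order(ped)  # stops on cycles
  for (k in seq_len(nrow(ped))) {
    m <- ped$mother[k]; f <- ped$father[k]
    if (!is.na(m)) {
      if (!m %in% ped$id || ped$sex[ped$id == m] != "F")
        stop("invalid-pedigree: mother of ", ped$id[k], " must be a female id")
      if (!is.null(ped$mt_lineage) &&
          !is.na(ped$mt_lineage[k]) &&
          !is.na(ped$mt_lineage[ped$id == m]) &&
          ped$mt_lineage[k] != ped$mt_lineage[ped$id == m])
        stop("invalid-pedigree: mt lineage of ", ped$id[k],
             " differs from its mother")
    }
    if (!is.na(f) && (!f %in% ped$id || ped$sex[ped$id == f] != "M"))
      stop("invalid-pedigree: father of ", ped$id[k], " must be a male id")
    if (!is.null(ped$birth_year)) {
      for (p in c(m, f)) {
        if (!is.na(p) && !is.na(ped$birth_year[k]) &&
            !is.na(ped$birth_year[ped$id == p]) &&
            ped$birth_year[k] <= ped$birth_year[ped$id == p] + 12)
          stop("invalid-pedigree: ", ped$id[k],
               " born too soon after parent ", p)
      }
    }
  }
  invisible(ped)
}

# Topological order (parents before children); stops on cycles.
pedigree_order <- function(ped) {
  ids <- ped$id
  placed <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      all(c(r$mother, r$father) %in% c(NA, placed))
    }, TRUE)
    if (!any(ready)) stop("invalid-pedigree: cycle detected")
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Four-generation fixture pedigree for the burial-group study design
#'
#' Six sampled individuals (B1, B1s, B2, B3, B3s, B4) plus five latent
#' (unsampled) relatives: B4 is the maternal grandfather of the siblings B1,
#' B2 and B3; B1s is B1's son; B3s is B2's daughter. Maternal lineage labels:
#' mtD-1 for B1, B1s, B2, B3 (and the latent matriline), mtD-2 for B3s.
#' Birth years place the shared entombment of B1, B1s, B2, B3 and B3s at
#' 500 CE with B4 dying decades earlier.
#'
#' @return pedigree data.frame (see [validate_pedigree()]).
#' @export
cao_pedigree <- function() {
  ped <- data.frame(
    id       = c("B4", "GW", "M0", "F0", "B1", "B2", "B3", "W1", "B1s", "W2", "B3s"),
    sex      = c("M", "F", "F", "M", "M", "M", "F", "F", "M", "F", "F"),
    mother   = c(NA, NA, "GW", NA, "M0", "M0", "M0", NA, "W1", NA, "W2"),
    father   = c(NA, NA, "B4", NA, "F0", "F0", "F0", NA, "B1", NA, "B2"),
    birth_year = c(436, 437, 453, 450, 475, 475, 475, 470, 488, 470, 488),
    age_at_death = c(24, 40, 40, 45, 25, 25, 25, 35, 12, 35, 12),
    mt_lineage = c("mtC-1", "mtD-1", "mtD-1", "mtB-1", "mtD-1", "mtD-1",
                   "mtD-1", "mtD-1", "mtD-1", "mtD-2", "mtD-2"),
    sampled = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  ped
}

#' Default mean sequencing depths for the fixture individuals
#'
#' Named after the study's coverage range (0.01x to 1.2x). B2's very low
#' depth reproduces the minimal-overlap regime (a few thousand shared SNPs
#' with every other individual at a 100k panel).
#'
#' @return named numeric vector of mean depths.
#' @export
cao_depths <- function() {
  c(B1 = 1.2, B1s = 0.4, B2 = 0.05, B3 = 0.9, B3s = 0.1, B4 = 1.0)
}

#' Draw a synthetic allele-frequency panel with a genetic map
#'
#' Frequencies are Beta draws truncated to [0.01, 0.99]; map positions are
#' uniform over 22 autosomes whose lengths sum to `total_cm`.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param beta_shape length-2 positive shape parameters of the Beta.
#' @param seed integer seed.
#' @param n_chrom number of chromosomes.
#' @param total_cm total map length in cM.
#' @return data.frame with columns chrom, cm, pos, f (sorted by chrom, cm).
#' @export
draw_frequencies <- function(n_snps, beta_shape = c(1, 1), seed = 1,
                             n_chrom = 22, total_cm = 3545) {
  if (n_snps < 1) stop("invalid-argument: n_snps must be >= 1")
  if (any(beta_shape <= 0)) stop("invalid-argument: shapes must be > 0")
  set.seed(seed)
  # chromosome lengths decline roughly linearly, normalised to total_cm
  raw <- seq(2, 1, length.out = n_chrom)
  chrlen <- raw / sum(raw) * total_cm
  chrom <- sample.int(n_chrom, n_snps, replace = TRUE, prob = chrlen / total_cm)
  cm <- stats::runif(n_snps) * chrlen[chrom]
  f <- pmin(pmax(stats::rbeta(n_snps, beta_shape[1], beta_shape[2]), 0.01), 0.99)
  o <- order(chrom, cm)
  out <- data.frame(chrom = chrom[o], cm = cm[o], f = f[o])
  out$pos <- round(out$cm * 1e6) + 1  # 1 cM ~ 1 Mb physical stand-in
  attr(out, "chrlen_cm") <- chrlen
  out
}

# One meiosis: returns, for each SNP, which parental haplotype (1 or 2) is
# transmitted, with Poisson crossovers (1 per 100 cM) and random start phase.
meiosis_indicator <- function(freqs) {
  n <- nrow(freqs)
  pick <- integer(n)
  for (ch in unique(freqs$chrom)) {
    idx <- which(freqs$chrom == ch)
    len <- max(freqs$cm[idx])
    nx <- stats::rpois(1, len / 100)
    xloc <- sort(stats::runif(nx, 0, len))
    phase <- sample(0:1, 1)
    pick[idx] <- (phase + findInterval(freqs$cm[idx], xloc)) %% 2 + 1
  }
  pick
}

#' Gene-drop diploid genotypes through a pedigree
#'
#' Founders receive Hardy-Weinberg haplotypes from the panel frequencies;
#' non-founders inherit one recombinant haplotype per parent (Poisson
#' crossovers on the cM map, no interference). Founder-haplotype origin
#' labels are recorded per site, giving exact IBD truth.
#'
#' @param ped pedigree data.frame (validated).
#' @param freqs frequency panel from [draw_frequencies()].
#' @param seed integer seed.
#' @return object of class `gene_drop`: haplotype matrices `h1`, `h2`
#'   (SNPs x individuals, alt-allele dosage 0/1), origin-label matrices
#'   `o1`, `o2`, plus `ped` and `freqs`.
#' @export
gene_drop <- function(ped, freqs, seed = 1) {
  validate_pedigree(ped)
  set.seed(seed)
  ord <- pedigree_order(ped)
  L <- nrow(freqs)
  n <- nrow(ped)
  h1 <- h2 <- matrix(0L, L, n, dimnames = list(NULL, ped$id))
  o1 <- o2 <- matrix(0L, L, n, dimnames = list(NULL, ped$id))
  next_founder_hap <- 1L
  for (id in ord) {
    k <- which(ped$id == id)
    m <- ped$mother[k]; f <- ped$father[k]
    for (side in 1:2) {
      p <- if (side == 1) m else f
      if (is.na(p)) {
        hap <- as.integer(stats::runif(L) < freqs$f)
        org <- rep.int(next_founder_hap, L)
        next_founder_hap <- next_founder_hap + 1L
      } else {
        pick <- meiosis_indicator(freqs)
        sw <- pick == 2L
        hap <- h1[, p]; hap[sw] <- h2[sw, p]
        org <- o1[, p]; org[sw] <- o2[sw, p]
      }
      if (side == 1) { h1[, k] <- hap; o1[, k] <- org }
      else           { h2[, k] <- hap; o2[, k] <- org }
    }
  }
  structure(list(h1 = h1, h2 = h2, o1 = o1, o2 = o2,
                 ped = ped, freqs = freqs),
            class = "gene_drop")
}

#' Diploid genotype matrix (alt-allele dosage) from a gene drop
#' @param gd a [gene_drop()] result.
#' @return integer matrix SNPs x individuals with values 0/1/2.
#' @export
genotypes <- function(gd) gd$h1 + gd$h2

#' Realised IBD-sharing state between two individuals
#'
#' Per-site count (0/1/2) of alleles shared identical by descent, from the
#' recorded founder-haplotype origins.
#'
#' @param gd a [gene_drop()] result.
#' @param i,j individual ids.
#' @return integer vector of IBD states per SNP.
#' @export
ibd_states <- function(gd, i, j) {
  a <- cbind(gd$o1[, i], gd$o2[, i])
  b <- cbind(gd$o1[, j], gd$o2[, j])
  s11 <- a[, 1] == b[, 1]; s12 <- a[, 1] == b[, 2]
  s21 <- a[, 2] == b[, 1]; s22 <- a[, 2] == b[, 2]
  # count of disjoint matchings (0, 1 or 2 shared haplotype pairs)
  two <- (s11 & s22) | (s12 & s21)
  one <- !two & (s11 | s12 | s21 | s22)
  as.integer(two) * 2L + as.integer(one)
}

#' Observation model for degraded low-coverage data
#'
#' @param mean_depth expected reads per site (Poisson).
#' @param base_error per-read symmetric miscall probability.
#' @param damage_rate per-read asymmetric (deamination-like) miscall
#'   probability at damage-susceptible sites, on top of `base_error`. This is
#'   a post-trim effective rate at genotyped sites, not the raw terminal
#'   rate.
#' @param missing_rate probability a site is dropped outright.
#' @return list of class `observation_model`.
#' @export
observation_model <- function(mean_depth, base_error = 0.001,
                              damage_rate = 0.003, missing_rate = 0) {
  stopifnot(mean_depth >= 0, base_error >= 0, base_error <= 1,
            damage_rate >= 0, damage_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 damage_rate = damage_rate, missing_rate = missing_rate),
            class = "observation_model")
}

#' Degrade true genotypes to per-site read counts
#'
#' Depth is Poisson per site; each read samples one of the two true alleles,
#' flips symmetrically with `base_error`, and additionally flips in the
#' site's damage direction with `damage_rate`. Each SNP gets a random damage
#' direction (ref-to-alt or alt-to-ref), emulating strand-dependent
#' deamination at C-carrying sites.
#'
#' @param geno integer matrix (SNPs x individuals), dosage 0/1/2.
#' @param model an [observation_model()].
#' @param seed integer seed.
#' @return object of class `read_counts`: matrices `ref`, `alt` and the
#'   per-SNP `damage_dir` (+1 = ref reads misread as alt).
#' @export
degrade_to_reads <- function(geno, model, seed = 1) {
  stopifnot(inherits(model, "observation_model"))
  set.seed(seed)
  L <- nrow(geno); n <- ncol(geno)
  depth <- matrix(stats::rpois(L * n, model$mean_depth), L, n)
  if (model$missing_rate > 0)
    depth[matrix(stats::runif(L * n) < model$missing_rate, L, n)] <- 0L
  # true alt reads before error
  alt_true <- matrix(stats::rbinom(L * n, depth, as.vector(geno) / 2), L, n)
  ref_true <- depth - alt_true
  dmg_dir <- sample(c(1L, -1L), L, replace = TRUE)
  e <- model$base_error
  d <- model$damage_rate
  # flip probabilities by direction
  p_ref_to_alt <- e + ifelse(dmg_dir == 1L, d, 0)
  p_alt_to_ref <- e + ifelse(dmg_dir == -1L, d, 0)
  r2a <- matrix(stats::rbinom(L * n, ref_true, rep(p_ref_to_alt, n)), L, n)
  a2r <- matrix(stats::rbinom(L * n, alt_true, rep(p_alt_to_ref, n)), L, n)
  alt <- alt_true - a2r + r2a
  ref <- ref_true - r2a + a2r
  dimnames(ref) <- dimnames(alt) <- dimnames(geno)
  structure(list(ref = ref, alt = alt, damage_dir = dmg_dir),
            class = "read_counts")
}

#' Pseudohaploid calls from read counts
#'
#' One read is chosen uniformly at random to represent each covered site;
#' uncovered sites are missing.
#'
#' @param reads a [read_counts()] object from [degrade_to_reads()].
#' @param seed integer seed.
#' @return integer matrix (SNPs x individuals) with values 0 (ref), 2 (alt)
#'   or NA.
#' @export
pseudohaploid_call <- function(reads, seed = 1) {
  set.seed(seed)
  depth <- reads$ref + reads$alt
  L <- nrow(depth); n <- ncol(depth)
  p_alt <- ifelse(depth > 0, reads$alt / pmax(depth, 1L), NA_real_)
  call <- matrix(NA_integer_, L, n, dimnames = dimnames(depth))
  cov <- depth > 0
  call[cov] <- ifelse(stats::runif(sum(cov)) < p_alt[cov], 2L, 0L)
  call
}

#' Simulate sex-chromosome read counts
#'
#' Multinomial allocation of reads to autosomes, X and Y with expected
#' shares set by mappable lengths: males carry one X and a Y whose mappable
#' share is scaled by `mappable_fraction_y`; females receive only a small
#' Y-mismapping fraction of their X-derived reads.
#'
#' @param sex "M" or "F".
#' @param n_reads total mapped reads (> 0).
#' @param mappable_fraction_y fraction of the 25-Mb mappable Y retained.
#' @param female_y_mismap mismap rate of X-like reads onto Y for females.
#' @param seed integer seed.
#' @return list with `nX`, `nY`, `nAut`.
#' @export
simulate_sexchr_counts <- function(sex, n_reads, mappable_fraction_y = 1,
                                   female_y_mismap = 0.005, seed = 1) {
  stopifnot(n_reads > 0, sex %in% c("M", "F"))
  set.seed(seed)
  aut <- 2 * 2875  # Mb, two autosome copies
  if (sex == "M") {
    x <- 155; y <- 25 * mappable_fraction_y
  } else {
    x <- 310; y <- 310 * female_y_mismap
  }
  p <- c(aut, x, y) / (aut + x + y)
  cnt <- stats::rmultinom(1, n_reads, p)[, 1]
  list(nAut = cnt[1], nX = cnt[2], nY = cnt[3])
}

#' Simulate radiocarbon determinations for a pedigree
#'
#' Each individual's dated event is its tissue-formation year (birth plus
#' tissue age); the expected determination mixes the terrestrial and marine
#' curves by the marine diet fraction, with the marine component offset by
#' `deltaR`, and adds curve and laboratory noise.
#'
#' @param ped pedigree with `birth_year`.
#' @param tissue_ages named vector, years after birth of the dated tissue.
#' @param marine_fracs named vector of marine diet fractions in [0, 1].
#' @param deltaR local marine reservoir offset (14C yr).
#' @param curves list with `terrestrial` and `marine` [calcurve] objects.
#' @param sigma_lab laboratory sigma (14C yr).
#' @param seed integer seed.
#' @param noise if FALSE, return expected means (no measurement noise).
#' @return data.frame of determinations (lab_id, individual, c14_age, sigma,
#'   tissue_age, marine_frac, marine_sd).
#' @export
simulate_c14 <- function(ped, tissue_ages, marine_fracs, deltaR, curves,
                         sigma_lab = 20, seed = 1, noise = TRUE) {
  if (any(marine_fracs < 0 | marine_fracs > 1))
    stop("invalid-argument: marine_fracs must be in [0,1]")
  set.seed(seed)
  ids <- names(tissue_ages)
  out <- lapply(ids, function(id) {
    by <- ped$birth_year[ped$id == id]
    t_ce <- by + tissue_ages[[id]]
    t_bp <- 1950 - t_ce
    p <- marine_fracs[[id]]
    mx <- mixed_curve(curves$terrestrial, curves$marine, p, deltaR, t_bp)
    mu <- mx$mean
    sd_tot <- sqrt(mx$sigma^2 + sigma_lab^2)
    age <- if (noise) stats::rnorm(1, mu, sd_tot) else mu
    data.frame(lab_id = paste0("SIM-", id), individual = id,
               c14_age = age, sigma = sigma_lab,
               tissue_age = tissue_ages[[id]], marine_frac = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate isotope records by linear diet mixing
#'
#' Enamel d13C is generated from the C4 fraction via the two-endpoint diet
#' mixing (inverse of [percent_c4()]); collagen d15N from the marine fraction
#' against the terrestrial composite (inverse of the noise-free
#' [percent_marine()]); Gaussian noise added on top.
#'
#' @param diet_config data.frame with columns id, p_c4, p_marine (0..1).
#' @param endmembers endmember list, see [default_endmembers()].
#' @param noise_sd measurement noise SD (permil).
#' @param seed integer seed.
#' @return data.frame with id, d13c_en, d13c_col, d15n_col.
#' @export
simulate_isotopes <- function(diet_config, endmembers = default_endmembers(),
                              noise_sd = 0.1, seed = 1) {
  stopifnot(all(diet_config$p_c4 >= 0 & diet_config$p_c4 <= 1),
            all(diet_config$p_marine >= 0 & diet_config$p_marine <= 1))
  set.seed(seed)
  em <- endmembers
  n <- nrow(diet_config)
  diet13 <- em$c3_d13c + diet_config$p_c4 * (em$c4_d13c - em$c3_d13c)
  d13c_en <- diet13 + em$en_diet_spacing + stats::rnorm(n, 0, noise_sd)
  terr <- terrestrial_d15n(em, diet_config$p_c4)
  mar <- em$marine$d15n$marine[1]
  d15n <- terr + diet_config$p_marine * (mar - terr) + stats::rnorm(n, 0, noise_sd)
  c3c <- em$marine$d13c$c3[1]; c4c <- em$marine$d13c$c4[1]
  d13c_col <- c3c + diet_config$p_c4 * (c4c - c3c) + stats::rnorm(n, 0, noise_sd)
  data.frame(id = diet_config$id, d13c_en = d13c_en, d13c_col = d13c_col,
             d15n_col = d15n, stringsAsFactors = FALSE)
}

#' Write a pedigree in the plain one-row-per-individual text format
#' @param ped pedigree data.frame.
#' @param path output file.
#' @export
write_pedigree_file <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree text file written by [write_pedigree_file()]
#' @param path input file.
#' @return validated pedigree data.frame.
#' @export
read_pedigree_file <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ped$mother[ped$mother %in% c("NA", "")] <- NA
  ped$father[ped$father %in% c("NA", "")] <- NA
  validate_pedigree(ped)
  ped
}

#' Build a pseudohaploid genotype panel from simulated calls
#'
#' @param calls matrix from [pseudohaploid_call()].
#' @param freqs frequency panel (provides SNP metadata).
#' @param ped pedigree (provides individual metadata).
#' @param sampled_only keep only sampled individuals.
#' @return a [genotype_panel()].
#' @export
panel_from_calls <- function(calls, freqs, ped, sampled_only = TRUE) {
  keep <- if (sampled_only && !is.null(ped$sampled)) ped$sampled else rep(TRUE, nrow(ped))
  ids <- intersect(ped$id[keep], colnames(calls))
  snp <- data.frame(id = paste0("snp", seq_len(nrow(freqs))),
                    chrom = freqs$chrom, cm = freqs$cm, pos = freqs$pos,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  ind <- data.frame(id = ids, sex = ped$sex[match(ids, ped$id)],
                    stringsAsFactors = FALSE)
  genotype_panel(calls[, ids, drop = FALSE], snp, ind,
                 pseudohaploid = TRUE)
}
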