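#' @title Pairwise relatedness from low-coverage data
#' @name kinship
#' @description Pairwise mismatch rates with window-jackknife errors and
#'   READ-style normalised classification, binomial genotype likelihoods and
#'   maximum-likelihood IBD k-coefficients over the k-simplex, a
#'   sibling-versus-parent-offspring HMM on windowed mismatch counts, and
#'   consensus fusion of per-method degree calls.
NULL

degree_levels <- c("identical", "1st", "2nd", "3rd", "unrelated",
                   "undetermined")

#' Pairwise mismatch rate between two pseudohaploid samples
#'
#' PMR = mismatching shared sites / overlapping sites. The standard error
#' comes from a leave-one-window-out weighted jackknife over map windows.
#'
#' @param panel a pseudohaploid [genotype_panel()], or a plain matrix with a
#'   `snp` attribute unnecessary if `cm`/`chrom` supplied.
#' @param i,j individual ids or column indices.
#' @param window_cm jackknife window length (cM).
#' @return list with `pmr`, `n_overlap`, `pmr_se`.
#' @export
pairwise_mismatch_rate <- function(panel, i, j, window_cm = 10) {
  g1 <- panel$geno[, i]
  g2 <- panel$geno[, j]
  keep <- !is.na(g1) & !is.na(g2)
  n <- sum(keep)
  if (n == 0) return(list(pmr = NA_real_, n_overlap = 0L, pmr_se = NA_real_))
  mm <- g1[keep] != g2[keep]
  pmr <- mean(mm)
  win <- interaction(panel$snp$chrom[keep],
                     floor(panel$snp$cm[keep] / window_cm), drop = TRUE)
  se <- block_jackknife_mean(as.numeric(mm), win)$se
  list(pmr = pmr, n_overlap = n, pmr_se = se)
}

# weighted delete-one-block jackknife of a mean (Busing-style pseudovalues)
block_jackknife_mean <- function(x, block) {
  n <- length(x)
  tot <- sum(x)
  bs <- tapply(x, block, sum)
  bn <- tapply(x, block, length)
  B <- length(bs)
  if (B < 2) return(list(est = tot / n, se = NA_real_, n_blocks = B))
  theta <- tot / n
  theta_del <- (tot - bs) / (n - bn)
  h <- n / bn
  pseudo <- h * theta - (h - 1) * theta_del
  theta_j <- mean(pseudo * bn / n) * B
  v <- sum((pseudo - theta_j)^2 / (h - 1)) / B
  list(est = theta, se = sqrt(v), n_blocks = B)
}

#' Normalise pairwise mismatch rates against an unrelated baseline
#'
#' @param pairs data.frame with at least `pmr` (and optionally
#'   `presumed_unrelated` logical) as produced by [kinship_pairs()].
#' @param method "median-of-unrelated" (median pmr of rows flagged
#'   `presumed_unrelated`, or of all rows when no flag is present) or
#'   "explicit-baseline".
#' @param baseline numeric baseline for the explicit method.
#' @return `pairs` with `normalized_pmr` and `normalized_se` columns and a
#'   `baseline` attribute.
#' @export
normalize_pmr <- function(pairs, method = c("median-of-unrelated",
                                            "explicit-baseline"),
                          baseline = NULL) {
  method <- match.arg(method)
  if (method == "median-of-unrelated") {
    use <- if (!is.null(pairs$presumed_unrelated)) pairs$presumed_unrelated
      else rep(TRUE, nrow(pairs))
    if (!any(use, na.rm = TRUE))
      stop("config-error: no baseline pairs available")
    baseline <- stats::median(pairs$pmr[use], na.rm = TRUE)
  } else if (is.null(baseline)) {
    stop("config-error: explicit baseline not supplied")
  }
  pairs$normalized_pmr <- pairs$pmr / baseline
  if (!is.null(pairs$pmr_se)) pairs$normalized_se <- pairs$pmr_se / baseline
  attr(pairs, "baseline") <- baseline
  pairs
}

#' Classify a relatedness degree from a normalised mismatch rate
#'
#' Cutoffs sit at midpoints between the expected normalised PMR of identical
#' samples (0.5), 1st (0.75), 2nd (0.875), 3rd (0.9375) degree and unrelated
#' (1.0): 0.625, 0.8125, 0.90625, 0.953125. A call is undetermined when the
#' overlap is below `min_overlap` or when the value plus/minus 2 SE spans a
#' cutoff.
#'
#' @param normalized_pmr normalised PMR.
#' @param normalized_se its standard error (may be NA).
#' @param n_overlap overlapping SNP count.
#' @param min_overlap minimum usable overlap (default 2000).
#' @return one of `identical`, `1st`, `2nd`, `3rd`, `unrelated`,
#'   `undetermined`.
#' @export
classify_degree <- function(normalized_pmr, normalized_se = NA,
                            n_overlap = Inf, min_overlap = 2000) {
  cuts <- c(0.625, 0.8125, 0.90625, 0.953125)
  if (is.na(normalized_pmr) || n_overlap < min_overlap) return("undetermined")
  if (!is.na(normalized_se) &&
      any(normalized_pmr - 2 * normalized_se < cuts &
          normalized_pmr + 2 * normalized_se > cuts))
    return("undetermined")
  degree_levels[findInterval(normalized_pmr, cuts) + 1]
}

#' Binomial genotype likelihoods from read counts
#'
#' For genotypes 0/1/2 (alt-allele dosage) the per-read alt probability is
#' `error`, 0.5, `1 - error`; site likelihoods are binomial in the read
#' counts.
#'
#' @param ref,alt integer vectors (or matrices) of per-site read counts.
#' @param error per-read miscall probability in (0, 0.5).
#' @return matrix (sites x 3) of likelihoods for g = 0, 1, 2 when inputs are
#'   vectors; a list of such matrices per column otherwise.
#' @export
genotype_likelihoods <- function(ref, alt, error = 0.01) {
  stopifnot(error > 0, error < 0.5)
  if (is.matrix(ref)) {
    out <- lapply(seq_len(ncol(ref)), function(k)
      genotype_likelihoods(ref[, k], alt[, k], error))
    names(out) <- colnames(ref)
    return(out)
  }
  n <- ref + alt
  cbind(g0 = stats::dbinom(alt, n, error),
        g1 = stats::dbinom(alt, n, 0.5),
        g2 = stats::dbinom(alt, n, 1 - error))
}

# per-site joint genotype-pair probability tables under IBD 0/1/2, collapsed
# against the two genotype likelihood vectors -> per-site coefficients
# (A, B, C) such that site likelihood = k0*A + k1*B + k2*C.
ml_site_coeffs <- function(gl_i, gl_j, f) {
  q <- 1 - f
  hw <- cbind(q^2, 2 * f * q, f^2)
  # IBD0: independent HW
  a_i <- rowSums(gl_i * hw)
  a_j <- rowSums(gl_j * hw)
  A <- a_i * a_j
  # IBD1 table rows (gi): (0,0)=q^3,(0,1)=pq^2 ; (1,*)=pq^2, pq, p^2q ; ...
  B <- gl_i[, 1] * (gl_j[, 1] * q^3 + gl_j[, 2] * f * q^2) +
       gl_i[, 2] * (gl_j[, 1] * f * q^2 + gl_j[, 2] * f * q +
                    gl_j[, 3] * f^2 * q) +
       gl_i[, 3] * (gl_j[, 2] * f^2 * q + gl_j[, 3] * f^3)
  # IBD2: identical genotypes
  C <- rowSums(gl_i * gl_j * hw)
  cbind(A = A, B = B, C = C)
}

#' Maximum-likelihood IBD coefficients (k0, k1, k2) for a pair
#'
#' Maximises the summed log of per-site likelihoods
#' k0 P(data | IBD0) + k1 P(data | IBD1) + k2 P(data | IBD2) over the
#' k-simplex: a coarse simplex grid followed by local refinement. Ties break
#' toward larger k0 (conservative). Sites without reads in both individuals
#' are uninformative and dropped.
#'
#' @param gl_i,gl_j genotype-likelihood matrices (sites x 3).
#' @param f per-site population alt-allele frequencies.
#' @param grid_step coarse simplex grid step.
#' @param min_sites minimum informative sites.
#' @return list with k0, k1, k2, r (= k1/2 + k2), r_over_k0, loglik,
#'   n_sites; all NA when under `min_sites`.
#' @export
ml_k_coefficients <- function(gl_i, gl_j, f, grid_step = 0.02,
                              min_sites = 500) {
  # sites with no reads on either side have uniform likelihoods and are
  # uninformative (A = B = C); drop them
  info <- rowSums(gl_i) < 2.999 & rowSums(gl_j) < 2.999
  co <- ml_site_coeffs(gl_i, gl_j, f)
  keep <- info & is.finite(rowSums(co)) & rowSums(co) > 0
  co <- co[keep, , drop = FALSE]
  if (nrow(co) < min_sites)
    return(list(k0 = NA, k1 = NA, k2 = NA, r = NA, r_over_k0 = NA,
                loglik = NA, n_sites = nrow(co)))
  obj <- function(k) sum(log(co %*% k))
  ks <- seq(0, 1, by = grid_step)
  K <- NULL
  for (k0 in ks) {
    k1 <- ks[ks <= 1 - k0 + 1e-9]
    K <- cbind(K, rbind(k0, k1, pmax(1 - k0 - k1, 0)))
  }
  ll_grid <- numeric(ncol(K))
  for (s in seq(1, ncol(K), by = 50)) {
    cols <- s:min(s + 49, ncol(K))
    ll_grid[cols] <- colSums(log(co %*% K[, cols, drop = FALSE]))
  }
  # ties break toward larger k0 (grid is ordered by ascending k0)
  cand <- which(ll_grid > max(ll_grid) - 1e-9)
  pick <- cand[which.max(K[1, cand])]
  best <- K[, pick]; bestll <- ll_grid[pick]
  # local refinement on the softmax scale
  to_k <- function(z) { e <- exp(c(z, 0)); e / sum(e) }
  z0 <- log(pmax(best, 1e-4) / max(best[3], 1e-4))[1:2]
  opt <- stats::optim(z0, function(z) -obj(to_k(z)), method = "Nelder-Mead",
                      control = list(maxit = 300))
  k_ref <- to_k(opt$par)
  if (-opt$value > bestll) { best <- k_ref; bestll <- -opt$value }
  best <- unname(best); bestll <- unname(bestll)
  r <- best[2] / 2 + best[3]
  list(k0 = best[1], k1 = best[2], k2 = best[3], r = r,
       r_over_k0 = if (best[1] > 0) r / best[1] else Inf,
       loglik = bestll, n_sites = nrow(co))
}

#' Relatedness degree from an estimated relatedness coefficient r
#'
#' Bins r (= k1/2 + k2) at geometric midpoints between the expected values
#' 0.5 (1st), 0.25 (2nd), 0.125 (3rd) and 0 (unrelated); r above ~0.7 with
#' high k2 is called identical. Estimates within `margin` of a cutoff are
#' withheld as undetermined, mirroring the PMR classifier's CI guard.
#'
#' @param r relatedness coefficient.
#' @param k2 IBD2 probability (distinguishes identical from 1st degree).
#' @param margin no-call half-width around each cutoff.
#' @return a degree label.
#' @export
classify_degree_from_r <- function(r, k2 = 0, margin = 0.025) {
  if (is.na(r)) return("undetermined")
  cuts <- c(0.0884, 0.177, 0.354)
  if (any(abs(r - cuts) < margin)) return("undetermined")
  if (r > 0.70 && !is.na(k2) && k2 > 0.7) return("identical")
  if (r > 0.354) return("1st")
  if (r > 0.177) return("2nd")
  if (r > 0.0884) return("3rd")
  "unrelated"
}

#' Sibling versus parent-offspring classification for a 1st-degree pair
#'
#' Windowed mismatch counts feed two models: a parent-offspring model in
#' which every window is IBD1, and a sibling model, a 3-state HMM over IBD
#' 0/1/2 with stationary distribution (1/4, 1/2, 1/4) and distance-dependent
#' switching. Window emission is binomial with state-specific expected
#' mismatch rates derived from the background (unrelated) PMR: b, 3b/4, b/2
#' for IBD 0/1/2.
#'
#' @param panel pseudohaploid [genotype_panel()].
#' @param i,j individual ids.
#' @param background_pmr unrelated-pair mismatch rate (the normalisation
#'   baseline).
#' @param window_cm window length in cM.
#' @param switch_per_cm IBD-state switch intensity of the sibling chain.
#' @param min_windows minimum usable windows.
#' @return list with `type` ("sibling"/"parent-offspring"/NA),
#'   `loglik_margin` (winner minus loser), `ll_sib`, `ll_po`, `n_windows`.
#' @export
first_degree_type_hmm <- function(panel, i, j, background_pmr,
                                  window_cm = 10, switch_per_cm = 0.02,
                                  min_windows = 20) {
  g1 <- panel$geno[, i]; g2 <- panel$geno[, j]
  keep <- !is.na(g1) & !is.na(g2)
  if (!any(keep)) return(list(type = NA, loglik_margin = NA,
                              ll_sib = NA, ll_po = NA, n_windows = 0L))
  mm <- g1[keep] != g2[keep]
  win <- interaction(panel$snp$chrom[keep],
                     floor(panel$snp$cm[keep] / window_cm), drop = TRUE)
  m <- as.vector(tapply(as.numeric(mm), win, sum))
  n <- as.vector(tapply(rep(1, length(mm)), win, sum))
  ok <- n >= 5
  m <- m[ok]; n <- n[ok]
  W <- length(n)
  if (W < min_windows)
    return(list(type = NA, loglik_margin = NA, ll_sib = NA, ll_po = NA,
                n_windows = W))
  b <- background_pmr
  rates <- c(ibd0 = b, ibd1 = 0.75 * b, ibd2 = 0.5 * b)
  emis <- vapply(rates, function(p) stats::dbinom(m, n, p, log = TRUE),
                 numeric(W))
  ll_po <- sum(emis[, "ibd1"])
  # sibling HMM forward pass
  pi0 <- c(0.25, 0.5, 0.25)
  stay <- exp(-switch_per_cm * window_cm)
  Tm <- stay * diag(3) + (1 - stay) * matrix(pi0, 3, 3, byrow = TRUE)
  alpha <- log(pi0) + emis[1, ]
  for (w in 2:W) {
    mx <- max(alpha)
    alpha <- log(as.vector(exp(alpha - mx) %*% Tm)) + mx + emis[w, ]
  }
  ll_sib <- max(alpha) + log(sum(exp(alpha - max(alpha))))
  margin <- abs(ll_sib - ll_po)
  list(type = if (ll_sib >= ll_po) "sibling" else "parent-offspring",
       loglik_margin = margin, ll_sib = ll_sib, ll_po = ll_po,
       n_windows = W)
}

#' All-pairs PMR estimates for a panel
#'
#' @param panel pseudohaploid [genotype_panel()].
#' @param ids individuals to pair (default: all in the panel).
#' @param window_cm jackknife window (cM).
#' @return data.frame with one row per unordered pair: id1, id2, pmr,
#'   n_overlap, pmr_se.
#' @export
kinship_pairs <- function(panel, ids = panel$ind$id, window_cm = 10) {
  cmb <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    r <- pairwise_mismatch_rate(panel, cmb[1, k], cmb[2, k], window_cm)
    data.frame(id1 = cmb[1, k], id2 = cmb[2, k], pmr = r$pmr,
               n_overlap = r$n_overlap, pmr_se = r$pmr_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fuse per-method degree calls into consensus degrees
#'
#' Confidence-weighted majority vote over the non-undetermined calls per
#' pair; disagreement among determined methods is flagged, never silently
#' resolved.
#'
#' @param estimates_by_method named list of data.frames, each with id1, id2,
#'   degree_call and optionally confidence (default 1).
#' @return data.frame with id1, id2, consensus, conflict (logical), and the
#'   per-method calls pasted in `calls`.
#' @export
consensus_degrees <- function(estimates_by_method) {
  stopifnot(length(estimates_by_method) >= 1)
  all_pairs <- unique(do.call(rbind, lapply(estimates_by_method, function(d)
    data.frame(id1 = pmin(d$id1, d$id2), id2 = pmax(d$id1, d$id2),
               stringsAsFactors = FALSE))))
  rows <- lapply(seq_len(nrow(all_pairs)), function(k) {
    i <- all_pairs$id1[k]; j <- all_pairs$id2[k]
    calls <- character(0); wts <- numeric(0)
    for (mname in names(estimates_by_method)) {
      d <- estimates_by_method[[mname]]
      hit <- (d$id1 == i & d$id2 == j) | (d$id1 == j & d$id2 == i)
      if (any(hit)) {
        calls <- c(calls, d$degree_call[hit][1])
        wts <- c(wts, if (!is.null(d$confidence)) d$confidence[hit][1] else 1)
      }
    }
    det <- calls != "undetermined" & !is.na(calls)
    if (!any(det)) {
      cons <- "undetermined"; conflict <- FALSE
    } else {
      tab <- tapply(wts[det], calls[det], sum)
      cons <- names(tab)[which.max(tab)]
      conflict <- length(tab) > 1
    }
    data.frame(id1 = i, id2 = j, consensus = cons, conflict = conflict,
               calls = paste(calls, collapse = "|"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
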