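#' @title Runs of homozygosity and parental relatedness
#' @name roh
#' @description A two-state (autozygous / non-autozygous) genotype HMM over
#'   windowed heterozygote counts, Viterbi segmentation into ROH, and the
#'   mapping from summed long-ROH length to a parental-relatedness class.
#'   This is a genotype-level substitute for haplotype-copying ROH callers,
#'   intended for diploid (or high-quality imputed) genotypes.
NULL

# forward-backward + Viterbi for a 2-state chain with binomial emissions
roh_hmm_decode <- function(het, n, p_het, p_auto, switch_prob) {
  W <- length(n)
  logT <- log(matrix(c(1 - switch_prob, switch_prob,
                       switch_prob, 1 - switch_prob), 2, 2, byrow = TRUE))
  emis <- cbind(stats::dbinom(het, n, p_het, log = TRUE),     # non-auto
                stats::dbinom(het, n, p_auto, log = TRUE))    # autozygous
  prior <- log(c(0.95, 0.05))
  # Viterbi
  delta <- prior + emis[1, ]
  back <- matrix(0L, W, 2)
  for (w in seq_len(W)[-1]) {
    cand <- delta + logT  # cand[s_prev, s]
    back[w, ] <- apply(cand, 2, which.max)
    delta <- apply(cand, 2, max) + emis[w, ]
  }
  path <- integer(W)
  path[W] <- which.max(delta)
  if (W > 1) for (w in (W - 1):1) path[w] <- back[w + 1, path[w + 1]]
  # posterior (forward-backward)
  fwd <- matrix(0, W, 2)
  fwd[1, ] <- prior + emis[1, ]
  for (w in seq_len(W)[-1]) {
    mx <- max(fwd[w - 1, ])
    fwd[w, ] <- log(exp(fwd[w - 1, ] - mx) %*% exp(logT)) + mx + emis[w, ]
  }
  bwd <- matrix(0, W, 2)
  if (W > 1) for (w in (W - 1):1) {
    mx <- max(bwd[w + 1, ] + emis[w + 1, ])
    bwd[w, ] <- log(exp(logT) %*% exp(bwd[w + 1, ] + emis[w + 1, ] - mx)) + mx
  }
  post <- fwd + bwd
  post <- exp(post - apply(post, 1, max))
  post <- post[, 2] / rowSums(post)
  list(path = path, post_auto = post)
}

#' Call runs of homozygosity from diploid genotypes
#'
#' Genotypes are windowed on the genetic map; per-window heterozygote counts
#' are emitted by a binomial whose rate is the panel heterozygosity in the
#' non-autozygous state and a small residual rate in the autozygous state.
#' Viterbi segments of consecutive autozygous windows become ROH.
#'
#' @param geno integer vector of diploid genotypes (0/1/2, NA missing) for
#'   one individual.
#' @param map data.frame with `chrom` and `cm` per site.
#' @param window_cm window length in cM (>= 0.5).
#' @param p_het expected heterozygosity per genotyped site outside ROH;
#'   estimated from the data when NULL.
#' @param auto_factor residual heterozygosity inside ROH as a fraction of
#'   `p_het` (genotyping error driven).
#' @param switch_prob per-window state-switch probability.
#' @return data.frame of segments: chrom, start_cm, end_cm, length_cm,
#'   mean_post (posterior mean autozygosity over the segment's windows).
#' @export
call_roh <- function(geno, map, window_cm = 1, p_het = NULL,
                     auto_factor = 0.05, switch_prob = 0.01) {
  if (window_cm < 0.5) stop("window_cm must be >= 0.5")
  ok <- !is.na(geno)
  if (is.null(p_het)) p_het <- max(mean(geno[ok] == 1), 1e-4)
  segs <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch & ok)
    if (length(idx) == 0) next
    w <- floor(map$cm[idx] / window_cm)
    wu <- sort(unique(w))
    het <- as.vector(tapply(geno[idx] == 1, w, sum)[as.character(wu)])
    n <- as.vector(tapply(rep(1, length(idx)), w, sum)[as.character(wu)])
    if (mean(n) * p_het < 1)
      stop("coverage too sparse: expected het calls per window < 1 ",
           "(widen window_cm or supply denser genotypes)")
    dec <- roh_hmm_decode(het, n, p_het, max(p_het * auto_factor, 1e-5),
                          switch_prob)
    runs <- rle(dec$path == 2)
    pos <- cumsum(c(0, runs$lengths))
    for (r in which(runs$values)) {
      wi <- (pos[r] + 1):pos[r + 1]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch,
        start_cm = wu[min(wi)] * window_cm,
        end_cm = (wu[max(wi)] + 1) * window_cm,
        mean_post = mean(dec$post_auto[wi]))
    }
  }
  if (length(segs) == 0)
    return(data.frame(chrom = integer(0), start_cm = numeric(0),
                      end_cm = numeric(0), length_cm = numeric(0),
                      mean_post = numeric(0)))
  out <- do.call(rbind, segs)
  out$length_cm <- out$end_cm - out$start_cm
  out[, c("chrom", "start_cm", "end_cm", "length_cm", "mean_post")]
}

#' Parental-relatedness class from summed long ROH
#'
#' Sums segments longer than `long_threshold` and maps the sum to bands
#' centred on the inbreeding expectation F x L for offspring of related
#' parents (L = genome length): below 10 cM parents unrelated (beyond 3rd
#' cousins), 10-35 about 6th degree, 35-110 about 5th degree (second
#' cousins), 110-220 about 4th degree, above 220 3rd degree or closer.
#' Sums within 2% of a band boundary are flagged and report both classes.
#'
#' @param segments data.frame from [call_roh()].
#' @param long_threshold minimum segment length (cM) counted (default 20).
#' @return list with `sum_long_cm`, `class`, `boundary_flag`, and
#'   `alternatives` when flagged.
#' @export
parental_degree_from_roh <- function(segments, long_threshold = 20) {
  s <- sum(segments$length_cm[segments$length_cm > long_threshold])
  bounds <- c(10, 35, 110, 220)
  classes <- c("unrelated (beyond 3rd cousins)", "~6th degree",
               "5th degree (second cousins)", "~4th degree",
               "3rd degree or closer")
  cls <- classes[findInterval(s, bounds) + 1]
  near <- which(abs(s - bounds) <= 0.02 * bounds)
  if (length(near)) {
    alt <- unique(c(classes[near[1]], classes[near[1] + 1]))
    return(list(sum_long_cm = s, class = cls, boundary_flag = TRUE,
                alternatives = alt))
  }
  list(sum_long_cm = s, class = cls, boundary_flag = FALSE,
       alternatives = cls)
}
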