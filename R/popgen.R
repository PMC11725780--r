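#' @title f-statistics and distance trees
#' @name popgen
#' @description Outgroup-f3 and f4 statistics on per-group allele
#'   frequencies with a weighted block jackknife, the 1/f3 distance
#'   transform, and neighbor-joining tree construction (via ape) rooted on
#'   an outgroup.
NULL

#' Per-group allele frequencies with jackknife blocks
#'
#' @param freq matrix (SNPs x groups) of alt-allele frequencies in [0, 1]
#'   (single pseudohaploid samples contribute 0/1), NA for missing.
#' @param chrom per-SNP chromosome labels.
#' @param pos per-SNP physical positions (bp); used to cut 5-Mb blocks.
#' @param block_size_bp block length (default 5e6).
#' @return list of class `group_freqs` with `freq` and per-SNP `block` ids.
#' @export
group_frequencies <- function(freq, chrom, pos, block_size_bp = 5e6) {
  stopifnot(nrow(freq) == length(chrom), length(chrom) == length(pos))
  block <- as.integer(interaction(chrom, floor(pos / block_size_bp),
                                  drop = TRUE))
  structure(list(freq = as.matrix(freq), block = block),
            class = "group_freqs")
}

f_jackknife <- function(term, block) {
  keep <- is.finite(term)
  term <- term[keep]; block <- block[keep]
  n_snps <- length(term)
  if (n_snps == 0) stop("no usable sites")
  jk <- block_jackknife_mean(term, factor(block))
  z <- if (is.na(jk$se) || jk$se == 0) NA_real_ else jk$est / jk$se
  list(value = jk$est, se = jk$se, z = z, n_blocks = jk$n_blocks,
       n_snps = n_snps)
}

#' Outgroup f3 statistic f3(O; A, B)
#'
#' Mean over SNPs of (a - o)(b - o); SE and Z from the weighted block
#' jackknife. Sites missing in any of the three groups are dropped.
#'
#' @param gf a [group_frequencies()] object.
#' @param O,A,B group names (columns of the frequency matrix).
#' @return list with value, se, z, n_blocks, n_snps.
#' @export
outgroup_f3 <- function(gf, O, A, B) {
  o <- gf$freq[, O]; a <- gf$freq[, A]; b <- gf$freq[, B]
  f_jackknife((a - o) * (b - o), gf$block)
}

#' f4 statistic f4(A, B; C, D)
#'
#' Mean over SNPs of (a - b)(c - d) with jackknife SE.
#'
#' @param gf a [group_frequencies()] object.
#' @param A,B,C,D group names.
#' @return list with value, se, z, n_blocks, n_snps.
#' @export
f4 <- function(gf, A, B, C, D) {
  a <- gf$freq[, A]; b <- gf$freq[, B]
  c_ <- gf$freq[, C]; d <- gf$freq[, D]
  f_jackknife((a - b) * (c_ - d), gf$block)
}

#' Distance matrix from pairwise outgroup-f3 values
#'
#' d(i, j) = 1 / f3(O; i, j); diagonal zero by convention.
#'
#' @param f3mat symmetric matrix of pairwise outgroup-f3 values (diagonal
#'   ignored).
#' @return symmetric distance matrix with zero diagonal.
#' @export
f3_distance_matrix <- function(f3mat) {
  f3mat <- as.matrix(f3mat)
  d <- f3mat
  diag(d) <- NA
  bad <- which(d <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive f3 for pair ", rownames(f3mat)[bad[1, 1]], " - ",
         colnames(f3mat)[bad[1, 2]])
  d <- 1 / f3mat
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix, rooted on an outgroup
#'
#' Standard NJ agglomeration with branch lengths, rooted on the outgroup
#' edge.
#'
#' @param d square symmetric distance matrix with labels (n >= 3).
#' @param outgroup taxon label used to root the tree; NULL for unrooted.
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (!is.null(outgroup)) tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  tr
}

#' Write a tree in newick format
#' @param tree an ape phylo object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
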