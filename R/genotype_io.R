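#' @title EIGENSTRAT genotype input/output
#' @name genotype_io
#' @description Readers/writers for the geno/snp/ind triplet used by the
#'   standard ancient-DNA toolchain, plus panel intersection on shared
#'   non-missing SNPs. Genotypes are held as an integer matrix (SNPs x
#'   individuals) coded 0/1/2 copies of the alt allele with NA for missing
#'   (9 on disk). Pseudohaploid panels carry only 0/2/NA.
NULL

#' Create a genotype panel object
#'
#' @param geno integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @param snp data.frame with columns id, chrom, cm, pos, ref, alt.
#' @param ind data.frame with columns id, sex (one row per individual).
#' @param pseudohaploid logical flag; if TRUE, no value 1 may appear.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, snp, ind, pseudohaploid = FALSE) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(snp), ncol(geno) == nrow(ind))
  if (anyDuplicated(snp$id)) stop("duplicate SNP ids")
  if (pseudohaploid && any(geno == 1, na.rm = TRUE))
    stop("pseudohaploid panel contains heterozygous calls")
  colnames(geno) <- ind$id
  rownames(geno) <- snp$id
  structure(list(geno = geno, snp = snp, ind = ind,
                 pseudohaploid = pseudohaploid),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d SNPs x %d individuals (%s)\n",
              nrow(x$geno), ncol(x$geno),
              if (x$pseudohaploid) "pseudohaploid" else "diploid"))
  invisible(x)
}

#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' Accepts plain or gzipped files (`.gz` suffix detected automatically).
#' Genetic positions in the .snp file are stored in Morgans on disk and
#' converted to cM in memory.
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind` (or their .gz versions) must exist.
#' @param pseudohaploid logical, mark the panel pseudohaploid.
#' @return a [genotype_panel()].
#' @export
read_eigenstrat <- function(prefix, pseudohaploid = FALSE) {
  find1 <- function(ext) {
    for (p in paste0(prefix, ext, c("", ".gz"))) if (file.exists(p)) return(p)
    stop("missing file: ", prefix, ext)
  }
  gl <- readLines(find1(".geno"))
  sn <- read.table(find1(".snp"), header = FALSE, stringsAsFactors = FALSE)
  colnames(sn)[1:6] <- c("id", "chrom", "gpos", "pos", "ref", "alt")
  ind <- read.table(find1(".ind"), header = FALSE, stringsAsFactors = FALSE)
  colnames(ind)[1:2] <- c("id", "sex")
  if (length(gl) != nrow(sn))
    stop("format-error: geno has ", length(gl), " rows but snp has ", nrow(sn))
  widths <- nchar(gl)
  if (length(unique(widths)) > 1)
    stop("format-error: ragged geno rows (first at line ",
         which(widths != widths[1])[1], ")")
  if (widths[1] != nrow(ind))
    stop("format-error: geno row width ", widths[1],
         " does not match ", nrow(ind), " individuals")
  chars <- matrix(unlist(strsplit(gl, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(gl), byrow = TRUE)
  bad <- matrix(!(chars %in% c("0", "1", "2", "9")), nrow = nrow(chars))
  if (any(bad)) {
    line <- which(apply(bad, 1, any))[1]
    stop("format-error: unknown genotype character at line ", line)
  }
  g <- matrix(as.integer(chars), nrow = nrow(chars))
  g[g == 9L] <- NA_integer_
  snp <- data.frame(id = sn$id, chrom = sn$chrom, cm = sn$gpos * 100,
                    pos = sn$pos, ref = sn$ref, alt = sn$alt,
                    stringsAsFactors = FALSE)
  genotype_panel(g, snp, ind[, c("id", "sex")], pseudohaploid = pseudohaploid)
}

#' Write a genotype panel as an EIGENSTRAT triplet
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(panel, prefix) {
  g <- panel$geno
  g[is.na(g)] <- 9L
  rows <- apply(g, 1, paste, collapse = "")
  writeLines(rows, paste0(prefix, ".geno"))
  sn <- panel$snp
  write.table(
    data.frame(sn$id, sn$chrom, format(sn$cm / 100, digits = 10), sn$pos,
               sn$ref, sn$alt),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(panel$ind$id, panel$ind$sex, "pop1"),
              paste0(prefix, ".ind"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Intersect two panels on shared non-missing SNPs
#'
#' Joins by SNP id and keeps only sites non-missing in both target columns.
#'
#' @param a,b [genotype_panel()] objects.
#' @param ind_a,ind_b individual id (or column index) in each panel; defaults
#'   to the first individual.
#' @return list with `a`, `b` (genotype vectors on the shared sites), `snp`
#'   (their metadata) and `n_overlap`.
#' @export
intersect_panels <- function(a, b, ind_a = 1, ind_b = 1) {
  shared <- intersect(a$snp$id, b$snp$id)
  ia <- match(shared, a$snp$id)
  ib <- match(shared, b$snp$id)
  ga <- a$geno[ia, ind_a]
  gb <- b$geno[ib, ind_b]
  keep <- !is.na(ga) & !is.na(gb)
  if (!any(keep)) warning("empty SNP intersection")
  list(a = ga[keep], b = gb[keep], snp = a$snp[ia[keep], , drop = FALSE],
       n_overlap = sum(keep))
}
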