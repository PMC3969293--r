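# Readers and writers for PLINK binary genotype triplets (bed/bim/fam)
# and the GCTA binary GRM format (grm.bin / grm.N.bin / grm.id).
#
# bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
# ceiling(N/4) bytes per SNP, two bits per individual:
#   00 = two copies of allele 1, 10 = heterozygote,
#   11 = zero copies of allele 1, 01 = missing.
# Dosages here count allele 1 (the A1 column of the bim file).

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' @param genotypes A [genotype_matrix()].
#' @param prefix Output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @param chr,pos Optional chromosome and base-pair position per SNP
#'   (defaults: chromosome 1, positions 1, 2, ...).
#' @param phenotype Optional phenotype for the fam file (default -9).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, chr = NULL, pos = NULL,
                        phenotype = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  x <- genotypes$dosages
  n <- nrow(x); m <- ncol(x)
  chr <- chr %||% rep(1L, m)
  pos <- pos %||% seq_len(m)
  fam <- data.frame(fid = genotypes$ids, iid = genotypes$ids,
                    pat = 0L, mat = 0L, sex = 0L,
                    pheno = phenotype %||% rep(-9, n))
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(chr = chr, snp = genotypes$snp_ids, cm = 0L, pos = pos,
                    a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # 2-bit codes indexed by dosage 0,1,2 and NA
  code <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L      # 01 missing
    out[!is.na(d) & d == 2] <- 0L # 00 hom A1
    out[!is.na(d) & d == 1] <- 2L # 10 het
    out[!is.na(d) & d == 0] <- 3L # 11 hom A2
    out
  }
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  shift <- c(1L, 4L, 16L, 64L)
  pad <- 4 * nb - n
  for (j in seq_len(m)) {
    codes <- c(code(x[, j]), rep(0L, pad))
    bytes <- colSums(matrix(codes * shift, nrow = 4))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triplet
#'
#' @param prefix Path prefix of the triplet.
#' @return A [genotype_matrix()] with `bim` and `fam` data frames
#'   attached as attributes.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"),
                           colClasses = c("character", "character", NA, NA,
                                          NA, NA))
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "snp", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c(NA, "character", NA, NA,
                                          "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, .BED_MAGIC)) {
    stop("not a SNP-major PLINK bed file")
  }
  raw <- readBin(con, "raw", nb * m)
  if (length(raw) != nb * m) stop("truncated bed file")
  b <- as.integer(raw)
  # expand each byte into its 4 two-bit codes (little-endian within byte)
  codes <- rbind(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                 bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))
  dim(codes) <- c(4 * nb, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  g <- genotype_matrix(dosage, ids = fam$iid, snp_ids = bim$snp)
  attr(g, "fam") <- fam
  attr(g, "bim") <- bim
  g
}

#' Write a GRM in the GCTA binary format
#'
#' Writes `prefix.grm.bin` (float32 lower triangle including the
#' diagonal, row by row), `prefix.grm.N.bin` (per-cell SNP counts, same
#' order) and `prefix.grm.id` (two-column id file).
#'
#' @param grm A `grm` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- grm$A[idx]
  nsnp <- grm$n_snps[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nsnp), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$ids, grm$ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GCTA binary GRM
#'
#' @param prefix Path prefix of the `grm.bin`/`grm.N.bin`/`grm.id` files.
#' @return A `grm` object.
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  nn <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", nn, size = 4)
  nsnp <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", nn, size = 4)
  A <- matrix(0, n, n)
  NS <- matrix(0, n, n)
  A[lower.tri(A, diag = TRUE)] <- NA # fill row-wise below
  k <- 1L
  for (i in seq_len(n)) {
    A[i, 1:i] <- vals[k:(k + i - 1)]
    NS[i, 1:i] <- nsnp[k:(k + i - 1)]
    k <- k + i
  }
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  NS[upper.tri(NS)] <- t(NS)[upper.tri(NS)]
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, ids = ids, n_snps = NS, m = max(NS)),
            class = "grm")
}
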