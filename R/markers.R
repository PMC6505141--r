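#' Simulate a synthetic founder-haplotype pool
#'
#' Generates a pool of phased 0/1 haplotypes at M biallelic markers placed on
#' a genetic map, to be assigned to pedigree founders and dropped through a
#' descent realization. This is a synthetic stand-in for a reference haplotype
#' panel: allele frequencies are drawn from a symmetric Beta(0.5, 0.5)
#' spectrum truncated at `maf_min`, marker positions are uniform within
#' chromosomes with marker counts proportional to genetic length, and local
#' linkage disequilibrium is induced by a first-order Markov (Gaussian-copula
#' Ornstein-Uhlenbeck) latent process along each chromosome: the latent
#' correlation between two markers separated by d cM is `ld^d`, so `ld` is
#' the correlation at 1 cM, `ld = 0` gives independent markers, and LD decays
#' with genetic distance rather than marker index — denser panels add
#' increasingly redundant markers, as in real data. Marginal allele
#' frequencies stay exact.
#'
#' @param map a [genetic_map()].
#' @param M number of markers (>= 1).
#' @param n_haplotypes number of pool haplotypes (>= 2); must be at least the
#'   number of founder haplotype labels of any descent realization the pool
#'   is used with.
#' @param seed integer seed.
#' @param maf_min minimum minor allele frequency (< 0.5).
#' @param ld latent correlation between markers 1 cM apart, in [0, 1).
#' @return an object of class `haplotype_pool` with fields `markers` (data
#'   frame: `chrom`, `pos_cM`, `p`) and `haplotypes` (`n_haplotypes` x M 0/1
#'   matrix), plus provenance parameters.
#' @examples
#' pool <- simulate_founder_haplotypes(default_genetic_map(), M = 100,
#'                                     n_haplotypes = 20, seed = 1)
#' dim(pool$haplotypes)
#' @export
simulate_founder_haplotypes <- function(map, M, n_haplotypes, seed,
                                        maf_min = 0.05, ld = 0.5) {
  stopifnot(inherits(map, "genetic_map"), M >= 1, n_haplotypes >= 2)
  if (maf_min >= 0.5) stop("maf_min must be below 0.5")
  if (ld < 0 || ld >= 1) stop("ld must lie in [0, 1)")
  set.seed(as.integer(seed))
  # markers per chromosome, proportional to genetic length
  w <- map$length_cm / sum(map$length_cm)
  cnt <- floor(M * w)
  rem <- M - sum(cnt)
  if (rem > 0) {
    extra <- order(M * w - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  chrom <- rep(map$chrom, cnt)
  pos <- unlist(lapply(seq_len(nrow(map)), function(c) {
    sort(runif(cnt[c], 0, map$length_cm[c]))
  }), use.names = FALSE)
  # truncated symmetric Beta allele-frequency spectrum
  p <- numeric(M)
  todo <- seq_len(M)
  while (length(todo)) {
    cand <- rbeta(length(todo), 0.5, 0.5)
    ok <- pmin(cand, 1 - cand) >= maf_min
    p[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  # Gaussian-copula AR(1) latents per chromosome -> 0/1 alleles
  H <- matrix(0L, n_haplotypes, M)
  col0 <- 0L
  for (c in seq_len(nrow(map))) {
    mc <- cnt[c]
    if (mc == 0L) next
    Z <- matrix(rnorm(n_haplotypes * mc), n_haplotypes, mc)
    if (ld > 0 && mc > 1L) {
      pc <- pos[col0 + seq_len(mc)]
      for (j in 2:mc) {
        r <- ld^(pc[j] - pc[j - 1L])
        Z[, j] <- r * Z[, j - 1L] + sqrt(1 - r^2) * Z[, j]
      }
    }
    thr <- qnorm(p[col0 + seq_len(mc)])
    H[, col0 + seq_len(mc)] <-
      (Z < matrix(thr, n_haplotypes, mc, byrow = TRUE)) + 0L
    col0 <- col0 + mc
  }
  structure(list(markers = data.frame(chrom = chrom, pos_cM = pos, p = p,
                                      stringsAsFactors = FALSE),
                 haplotypes = H,
                 provenance = list(source = "synthetic", M = M,
                                   n_haplotypes = n_haplotypes,
                                   maf_min = maf_min, ld = ld,
                                   seed = as.integer(seed))),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool>", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "markers |", x$provenance$source, "\n")
  invisible(x)
}

#' Drop marker genotypes through a descent realization
#'
#' Deterministically populates marker genotypes down the pedigree: the allele
#' carried by an individual's haplotype at a marker is the allele of the pool
#' haplotype assigned to the founder label covering that position. Pool rows
#' are assigned to the sorted global founder haplotype labels in order. No
#' genotyping error is introduced, so IBD segments are IBS-identical.
#'
#' @param dr a [simulate_descent()] result.
#' @param pool a [simulate_founder_haplotypes()] pool with at least as many
#'   haplotypes as there are founder haplotype labels in `dr`.
#' @return an object of class `genotype_matrix`: `dosage` (N x M 0/1/2 matrix
#'   over analyzed individuals), `markers`, `ids`, `blocks`.
#' @export
drop_genotypes <- function(dr, pool) {
  stopifnot(inherits(dr, "descent_realization"),
            inherits(pool, "haplotype_pool"))
  flab <- founder_labels(dr)
  if (nrow(pool$haplotypes) < length(flab))
    stop("pool has ", nrow(pool$haplotypes), " haplotypes but the descent ",
         "realization has ", length(flab), " founder haplotype labels")
  if (!all(pool$markers$chrom %in% dr$map$chrom))
    stop("marker chromosome not in the genetic map")
  chr_idx <- match(pool$markers$chrom, dr$map$chrom)
  if (any(pool$markers$pos_cM < 0 |
          pool$markers$pos_cM > dr$map$length_cm[chr_idx]))
    stop("marker position outside map chromosome length")
  row_of <- integer(max(flab)); row_of[flab] <- seq_along(flab)
  nc <- nrow(dr$map)
  na <- length(dr$analyzed)
  M <- nrow(pool$markers)
  mk_cols <- split(seq_len(M), chr_idx)
  dosage <- matrix(0L, na * dr$m, M)
  for (b in seq_len(dr$m)) {
    blk <- dr$blocks[[b]]
    offs <- cumsum(c(0L, blk$counts))
    lab_off <- (b - 1L) * 2L * dr$n
    for (ii in seq_along(dr$analyzed)) {
      i <- dr$analyzed[ii]
      row <- (b - 1L) * na + ii
      for (h in 0:1) {
        for (cs in names(mk_cols)) {
          c <- as.integer(cs)
          cols <- mk_cols[[cs]]
          k <- (2L * (i - 1L) + h) * nc + c
          sl <- offs[k] + seq_len(blk$counts[k])
          seg <- findInterval(pool$markers$pos_cM[cols], blk$ends[sl],
                              left.open = FALSE) + 1L
          seg[seg > length(sl)] <- length(sl)  # pos == chromosome end
          lab <- blk$labels[sl][seg] + lab_off
          alle <- pool$haplotypes[cbind(row_of[lab], cols)]
          dosage[row, cols] <- dosage[row, cols] + alle
        }
      }
    }
  }
  structure(list(dosage = dosage, markers = pool$markers,
                 ids = block_ids(dr$ped$label[dr$analyzed], dr$m),
                 blocks = rep(seq_len(dr$m), each = na)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers\n")
  invisible(x)
}

#' Classic genomic relationship matrix (2 Phi-hat-c)
#'
#' The standardized-dosage cross-product average over markers,
#' entry(j,k) = (1/M) sum_m (x_jm - 2 p_m)(x_km - 2 p_m) / (2 p_m (1 - p_m)),
#' computed within pedigree blocks (entries between blocks are set to 0,
#' matching a per-cluster analysis). Allele frequencies are treated as known.
#' The classic GRM is an unbiased but noisy marker-based estimator of twice
#' the realized kinship; `constrain_diagonal` replaces the diagonal (twice the
#' estimated self-kinship) with exactly 1.
#'
#' @param geno a [drop_genotypes()] genotype matrix.
#' @param freqs known reference allele frequencies (defaults to the pool
#'   frequencies carried in `geno$markers$p`); must lie strictly in (0, 1).
#' @param constrain_diagonal set diagonal entries to 1.
#' @return a [kinship_matrix] of kind `"grm_classic"`.
#' @export
classic_grm <- function(geno, freqs = geno$markers$p,
                        constrain_diagonal = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  M <- ncol(geno$dosage)
  if (length(freqs) != M) stop("one frequency per marker required")
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  S <- sweep(geno$dosage, 2L, 2 * freqs)
  S <- sweep(S, 2L, sqrt(2 * freqs * (1 - freqs)), "/")
  N <- nrow(S)
  G <- matrix(0, N, N)
  for (ix in split(seq_len(N), geno$blocks)) {
    G[ix, ix] <- tcrossprod(S[ix, , drop = FALSE]) / M
  }
  if (constrain_diagonal) diag(G) <- 1
  new_kinship_matrix(G, ids = geno$ids, kind = "grm_classic",
                     blocks = geno$blocks)
}

#' Plugin slot for alternative GRM estimators
#'
#' Applies a user-supplied estimator with the same signature as
#' [classic_grm()] (for example an LD-weighted GRM) and tags the result as
#' kind `"grm_plugin"`. No default implementation is shipped.
#'
#' @param geno a `genotype_matrix`.
#' @param estimator `function(geno, freqs, constrain_diagonal)` returning an
#'   N x N matrix or a `kinship_matrix`.
#' @inheritParams classic_grm
#' @export
grm_plugin <- function(geno, estimator, freqs = geno$markers$p,
                       constrain_diagonal = FALSE) {
  if (!is.function(estimator)) stop("no GRM plugin estimator registered")
  out <- estimator(geno, freqs, constrain_diagonal)
  mat <- if (inherits(out, "kinship_matrix")) out$matrix else as.matrix(out)
  new_kinship_matrix(mat, ids = geno$ids, kind = "grm_plugin",
                     blocks = geno$blocks)
}

#' Genotype import/export
#'
#' `write_dosage_tsv`/`read_dosage_tsv` store the dosage matrix with marker
#' metadata as tab-separated text (markers in columns, a header of marker
#' names `chrom:pos`, one row per individual with its id). `write_vcf` writes
#' an unphased GT-only VCF; `read_vcf_genotypes` reads one back (requires the
#' vcfR package).
#'
#' @param geno a `genotype_matrix`.
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  hdr <- paste0(geno$markers$chrom, ":", format(geno$markers$pos_cM,
                                                digits = 10, trim = TRUE))
  tab <- data.frame(id = geno$ids, block = geno$blocks, geno$dosage,
                    check.names = FALSE)
  names(tab) <- c("id", "block", hdr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#p=", paste(format(geno$markers$p, digits = 10),
                                 collapse = ",")), con)
  write.table(tab, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  p <- as.numeric(strsplit(sub("^#p=", "", lines[1L]), ",")[[1L]])
  tab <- read.table(text = lines[-1L], header = TRUE, sep = "\t",
                    check.names = FALSE)
  mk <- do.call(rbind, strsplit(names(tab)[-(1:2)], ":", fixed = TRUE))
  structure(list(dosage = as.matrix(tab[, -(1:2), drop = FALSE]),
                 markers = data.frame(chrom = mk[, 1L],
                                      pos_cM = as.numeric(mk[, 2L]), p = p,
                                      stringsAsFactors = FALSE),
                 ids = as.character(tab$id), blocks = as.integer(tab$block)),
            class = "genotype_matrix")
}

#' @rdname write_dosage_tsv
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##kinherit_p=",
                      paste(format(geno$markers$p, digits = 10),
                            collapse = ","))), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$ids), collapse = "\t"), con)
  gt <- c("0/0", "0/1", "1/1")[t(geno$dosage) + 1L]
  gt <- matrix(gt, ncol(geno$dosage), nrow(geno$dosage))
  # positions in cM scaled to integer bp-like coordinates
  pos_int <- as.integer(round(geno$markers$pos_cM * 1e4)) + 1L
  body <- cbind(geno$markers$chrom, pos_int,
                paste0("m", seq_len(ncol(geno$dosage))), "A", "G", ".", ".",
                ".", "GT", gt)
  write.table(body, con, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dosage <- t(apply(gt, 2L, function(col) {
    vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), integer(1))
  }))
  meta <- grep("^##kinherit_p=", v@meta, value = TRUE)
  p <- if (length(meta))
    as.numeric(strsplit(sub("^##kinherit_p=", "", meta), ",")[[1L]])
  else rep(NA_real_, ncol(dosage))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  structure(list(dosage = dosage,
                 markers = data.frame(chrom = fix$CHROM,
                                      pos_cM = (as.numeric(fix$POS) - 1) / 1e4,
                                      p = p, stringsAsFactors = FALSE),
                 ids = rownames(dosage),
                 blocks = rep(1L, nrow(dosage))),
            class = "genotype_matrix")
}
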