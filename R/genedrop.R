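#' Genetic maps
#'
#' A genetic map is a table of chromosomes with their genetic lengths in
#' centimorgans. The default map has the 22 human autosomes with sex-averaged
#' human-like lengths (total 3539 cM, chromosome 22 = 74 cM), which is what
#' genome-wide and chromosome-22 realized kinship are measured against.
#'
#' @param chrom chromosome names.
#' @param length_cm genetic lengths in centimorgans (> 0).
#' @return a `genetic_map` data frame with columns `chrom`, `length_cm`.
#' @examples
#' map <- default_genetic_map()
#' sum(map$length_cm)
#' @export
genetic_map <- function(chrom, length_cm) {
  stopifnot(length(chrom) == length(length_cm), all(length_cm > 0))
  map <- data.frame(chrom = as.character(chrom),
                    length_cm = as.numeric(length_cm),
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname genetic_map
#' @export
default_genetic_map <- function() {
  genetic_map(chrom = as.character(1:22),
              length_cm = c(286, 269, 223, 214, 204, 192, 187, 168, 166,
                            181, 158, 175, 126, 119, 141, 134, 128, 117,
                            107, 108, 62, 74))
}

#' @rdname genetic_map
#' @param path two-column whitespace-delimited text file (chromosome, cM).
#' @examples
#' read_genetic_map(system.file("extdata", "autosome_map.txt",
#'                              package = "kinherit"))
#' @export
read_genetic_map <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("map file needs two columns: chromosome, cM")
  genetic_map(tab[[1L]], tab[[2L]])
}

#' Simulate genome-wide descent (gene-drop) in pedigrees
#'
#' Drops founder genomes through `m` independent copies of a pedigree along a
#' genetic map. Each meiosis places crossovers as a homogeneous Poisson
#' process at 1 event per 100 cM (Haldane model, no interference) and starts
#' each chromosome from a uniformly chosen parental haplotype. Founder
#' haplotypes each carry a globally unique label, and every simulated
#' haplotype is a mosaic of founder labels tiling each chromosome.
#'
#' Reproducibility: per-pedigree RNG streams are derived deterministically
#' from the master `seed` and the pedigree index, so block b's realization
#' depends only on (seed, b).
#'
#' @param ped a [build_pedigree()] pedigree.
#' @param map a [genetic_map()]; default [default_genetic_map()].
#' @param m number of independent pedigree copies.
#' @param seed master integer seed (required).
#' @return an object of class `descent_realization`.
#' @examples
#' ped <- build_pedigree("sibpair")
#' dr <- simulate_descent(ped, m = 2, seed = 1)
#' realized_kinship(dr)$matrix
#' @export
simulate_descent <- function(ped, map = default_genetic_map(), m = 1L,
                             seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "genetic_map"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  m <- as.integer(m)
  blocks <- vector("list", m)
  for (b in seq_len(m)) {
    set.seed(derive_seed(seed, 1L, b))
    blocks[[b]] <- gd_simulate_block(ped$father, ped$mother, map$length_cm)
  }
  structure(list(blocks = blocks, ped = ped, map = map, m = m,
                 n = nrow(ped), analyzed = which(ped$analyzed),
                 seed = as.integer(seed)),
            class = "descent_realization")
}

#' @export
print.descent_realization <- function(x, ...) {
  cat("<descent_realization>", attr(x$ped, "structure") %||% "custom",
      "x", x$m, "| map:", nrow(x$map), "chromosomes,",
      sum(x$map$length_cm), "cM | seed:", x$seed, "\n")
  invisible(x)
}

#' Realized kinship matrix from a descent realization
#'
#' Realized kinship phi(i,j) is the proportion of the (selected) genome, in
#' genetic distance, shared identical by descent: the average over the four
#' ordered haplotype pairs of the shared-label length divided by the total
#' selected map length. The diagonal is (1 + self-sharing)/2, so exactly 1
#' for outbred individuals. The returned matrix is 2 phi, block-diagonal over
#' the independent pedigrees, over the analyzed individuals.
#'
#' @param dr a [simulate_descent()] result.
#' @param chromosomes chromosome names to restrict to (default: all map
#'   chromosomes, i.e. genome-wide 2 Phi; a subset yields 2 Phi*).
#' @return a [kinship_matrix] of kind `"realized_2phi"` or
#'   `"realized_2phi_chr"`.
#' @export
realized_kinship <- function(dr, chromosomes = NULL) {
  stopifnot(inherits(dr, "descent_realization"))
  all_chr <- dr$map$chrom
  chromosomes <- chromosomes %||% all_chr
  if (!length(chromosomes)) stop("chromosome subset must be nonempty")
  chr_idx <- match(as.character(chromosomes), all_chr)
  if (anyNA(chr_idx)) stop("unknown chromosome in subset")
  kind <- if (length(chr_idx) == length(all_chr)) "realized_2phi"
          else "realized_2phi_chr"
  na <- length(dr$analyzed)
  big <- matrix(0, na * dr$m, na * dr$m)
  for (b in seq_len(dr$m)) {
    phi <- gd_block_kinship(dr$blocks[[b]], dr$n, dr$map$length_cm,
                            as.integer(chr_idx), as.integer(dr$analyzed))
    ix <- (b - 1L) * na + seq_len(na)
    big[ix, ix] <- 2 * phi
  }
  new_kinship_matrix(big, ids = block_ids(dr$ped$label[dr$analyzed], dr$m),
                     kind = kind, blocks = rep(seq_len(dr$m), each = na))
}

#' Export descent segments as a BED-like table
#'
#' One row per IBD segment: pedigree block, individual label, haplotype (1/2),
#' chromosome, start and end in cM (0-based, half-open), and the founder
#' haplotype label carried (globally unique across blocks).
#'
#' @param dr a `descent_realization`.
#' @return a data frame with columns `block`, `individual`, `haplotype`,
#'   `chrom`, `start_cM`, `end_cM`, `founder_label`.
#' @export
descent_segments <- function(dr) {
  nc <- nrow(dr$map)
  out <- vector("list", dr$m)
  for (b in seq_len(dr$m)) {
    blk <- dr$blocks[[b]]
    counts <- blk$counts
    hap_chr <- expand.grid(chrom = seq_len(nc), hap = 1:2,
                           ind = seq_len(dr$n))[, 3:1]
    ind <- rep(hap_chr$ind, counts)
    hap <- rep(hap_chr$hap, counts)
    chr <- rep(hap_chr$chrom, counts)
    ends <- blk$ends
    first <- !duplicated(data.frame(ind, hap, chr))
    starts <- c(0, ends[-length(ends)])
    starts[first] <- 0
    out[[b]] <- data.frame(block = b,
                           individual = dr$ped$label[ind],
                           haplotype = hap,
                           chrom = dr$map$chrom[chr],
                           start_cM = starts,
                           end_cM = ends,
                           founder_label = blk$labels + (b - 1L) * 2L * dr$n)
  }
  do.call(rbind, out)
}

#' Global founder haplotype labels of a descent realization
#'
#' Two labels per founder per pedigree copy; these are the labels a
#' [haplotype pool][simulate_founder_haplotypes()] must cover for genotype
#' drop-down.
#'
#' @param dr a `descent_realization`.
#' @return sorted integer vector of founder haplotype labels.
#' @export
founder_labels <- function(dr) {
  fo <- which(dr$ped$father == 0L)
  local_lab <- as.vector(rbind(2L * fo - 1L, 2L * fo))
  sort(as.vector(outer(local_lab, (seq_len(dr$m) - 1L) * 2L * dr$n, "+")))
}
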