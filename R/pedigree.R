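#' Build a pedigree
#'
#' Constructs one of the canonical pedigree structures used in the simulation
#' studies, or reads an arbitrary pedigree from a FAM-style file. Individuals
#' are stored in an order in which parents precede their children; founders
#' have both parent entries equal to 0. The `analyzed` flag marks the
#' individuals that are phenotyped/genotyped and enter kinship matrices and
#' trait vectors; ancestors that exist only to define the relationships (e.g.
#' in cousinships) are part of the structure but not of the analyzed set.
#'
#' Canonical structures:
#' \describe{
#'   \item{`sibpair`}{two full sibs (2 founder parents, 2 analyzed sibs).}
#'   \item{`sibship`}{`size` full sibs of one founder couple; the sibs are the
#'     analyzed set.}
#'   \item{`three_generation_14`}{a grandparental couple, their three children
#'     with founder spouses, and six grandchildren: 14 members, all analyzed.}
#'   \item{`cleopatra_14`}{an inbred 14-member structure: two founder couples,
#'     two intermarried sib pairs whose children are double first cousins, and
#'     a final inbred mating between two of those cousins. All 14 analyzed.}
#'   \item{`cousinship`}{`size` individuals that are pairwise `degree`-th
#'     cousins, descending from a single ancestral couple through distinct
#'     lineages (one analyzed individual per lineage). Ancestors and married-in
#'     founder spouses are structure only.}
#' }
#'
#' The `three_generation_14` and `cleopatra_14` topologies are documented
#' defaults; any exact topology can be supplied via `file`.
#'
#' @param structure one of `"sibpair"`, `"sibship"`, `"three_generation_14"`,
#'   `"cleopatra_14"`, `"cousinship"`. Ignored when `file` is given.
#' @param size sibship size (>= 2) or number of analyzed cousins (>= 2).
#' @param degree cousinship degree, 1, 2 or 3 (first/second/third cousins).
#' @param file path to a FAM-style pedigree file, see [read_fam()].
#' @return an object of class `pedigree`: a data frame with columns `label`,
#'   `father`, `mother` (integer indices, 0 = founder) and `analyzed`, plus a
#'   `structure` attribute.
#' @examples
#' ped <- build_pedigree("sibship", size = 14)
#' sum(ped$analyzed)
#' @export
build_pedigree <- function(structure = c("sibpair", "sibship",
                                         "three_generation_14",
                                         "cleopatra_14", "cousinship"),
                           size = NULL, degree = NULL, file = NULL) {
  if (!is.null(file)) {
    peds <- read_fam(file)
    if (length(peds) != 1L)
      stop("pedigree file defines ", length(peds),
           " families; expected exactly one")
    return(peds[[1L]])
  }
  structure <- match.arg(structure)
  ped <- switch(structure,
    sibpair = make_sibship(2L, "sibpair"),
    sibship = {
      if (is.null(size) || size < 2) stop("sibship requires size >= 2")
      make_sibship(as.integer(size), "sibship")
    },
    three_generation_14 = make_three_generation_14(),
    cleopatra_14 = make_cleopatra_14(),
    cousinship = {
      if (is.null(degree) || !degree %in% 1:3)
        stop("cousinship degree must be 1, 2 or 3")
      if (is.null(size) || size < 2) stop("cousinship requires size >= 2")
      make_cousinship(as.integer(degree), as.integer(size))
    })
  validate_pedigree(ped)
}

new_pedigree <- function(label, father, mother, analyzed, structure) {
  ped <- data.frame(label = as.character(label),
                    father = as.integer(father),
                    mother = as.integer(mother),
                    analyzed = as.logical(analyzed),
                    stringsAsFactors = FALSE)
  attr(ped, "structure") <- structure
  class(ped) <- c("pedigree", "data.frame")
  ped
}

make_sibship <- function(k, label) {
  n <- k + 2L
  new_pedigree(label = seq_len(n),
               father = c(0L, 0L, rep(1L, k)),
               mother = c(0L, 0L, rep(2L, k)),
               analyzed = c(FALSE, FALSE, rep(TRUE, k)),
               structure = label)
}

make_three_generation_14 <- function() {
  # 1-2 grandparents; 3-5 their children; 6-8 married-in spouses;
  # 9-14 grandchildren (two per couple).
  new_pedigree(label = 1:14,
               father = c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L,
                          3L, 3L, 4L, 4L, 5L, 5L),
               mother = c(0L, 0L, 2L, 2L, 2L, 0L, 0L, 0L,
                          6L, 6L, 7L, 7L, 8L, 8L),
               analyzed = rep(TRUE, 14),
               structure = "three_generation_14")
}

make_cleopatra_14 <- function() {
  # Two founder couples (1-2, 3-4); sibs 5,6 and 7,8 intermarry; their
  # children 9-12 are double first cousins; 9 x 11 is the inbred mating.
  new_pedigree(label = 1:14,
               father = c(0L, 0L, 0L, 0L, 1L, 1L, 3L, 3L,
                          5L, 5L, 6L, 6L, 9L, 9L),
               mother = c(0L, 0L, 0L, 0L, 2L, 2L, 4L, 4L,
                          7L, 7L, 8L, 8L, 11L, 11L),
               analyzed = rep(TRUE, 14),
               structure = "cleopatra_14")
}

make_cousinship <- function(degree, size) {
  # Top couple 1,2 with `size` children; each lineage chains `degree`
  # generations of matings with founder spouses; the analyzed individuals sit
  # at generation degree+1, one per lineage, hence pairwise degree-th cousins
  # with kinship (1/4)^(degree+1).
  father <- c(0L, 0L)
  mother <- c(0L, 0L)
  analyzed <- c(FALSE, FALSE)
  nid <- 2L
  for (lin in seq_len(size)) {
    pa <- 1L; ma <- 2L
    for (gen in seq_len(degree)) {
      nid <- nid + 1L; child <- nid
      father[child] <- pa; mother[child] <- ma; analyzed[child] <- FALSE
      nid <- nid + 1L; spouse <- nid
      father[spouse] <- 0L; mother[spouse] <- 0L; analyzed[spouse] <- FALSE
      pa <- child; ma <- spouse
    }
    nid <- nid + 1L
    father[nid] <- pa; mother[nid] <- ma; analyzed[nid] <- TRUE
  }
  ped <- new_pedigree(seq_len(nid), father, mother, analyzed, "cousinship")
  attr(ped, "degree") <- degree
  ped
}

validate_pedigree <- function(ped) {
  n <- nrow(ped)
  f <- ped$father; m <- ped$mother
  if (any((f == 0L) != (m == 0L)))
    stop("each individual must have zero or two recorded parents")
  if (any(f < 0L | f > n | m < 0L | m > n))
    stop("parent index out of range")
  nonf <- which(f > 0L)
  if (any(f[nonf] >= nonf) || any(m[nonf] >= nonf))
    stop("parents must precede children")  # read_fam reorders; builders comply
  if (!any(ped$analyzed)) stop("pedigree has no analyzed individuals")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> structure:", attr(x, "structure") %||% "custom",
      "| n =", nrow(x),
      "| founders =", sum(x$father == 0L),
      "| analyzed =", sum(x$analyzed), "\n")
  invisible(x)
}

#' Read and write FAM-style pedigree files
#'
#' Whitespace-delimited text with columns `family`, `id`, `father`, `mother`
#' (0 denotes a founder parent), optionally followed by `sex` and `phenotype`
#' columns as in PLINK FAM files. When a phenotype column is present,
#' individuals with phenotype 0 or -9 are treated as not analyzed; otherwise
#' all individuals are analyzed. Individuals are reordered topologically if
#' needed so that parents precede children.
#'
#' @param path file path.
#' @return `read_fam`: a named list of `pedigree` objects, one per family.
#' @examples
#' fam <- system.file("extdata", "three_generation_14.fam",
#'                    package = "kinherit")
#' read_fam(fam)[[1]]
#' @export
read_fam <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("FAM file needs at least 4 columns")
  names(tab)[1:4] <- c("family", "id", "father", "mother")
  out <- lapply(split(tab, tab$family), fam_to_pedigree)
  out[order(names(out))]
}

fam_to_pedigree <- function(fam) {
  id <- as.character(fam$id)
  if (anyDuplicated(id)) stop("duplicated individual ids within a family")
  fa <- as.character(fam$father); mo <- as.character(fam$mother)
  analyzed <- if (ncol(fam) >= 6L) !(fam[[6L]] %in% c(0, -9)) else
    rep(TRUE, nrow(fam))
  fi <- match(fa, id); fi[fa == "0"] <- 0L
  mi <- match(mo, id); mi[mo == "0"] <- 0L
  if (anyNA(fi) || anyNA(mi)) stop("parent id not found in family")
  ord <- topo_order(fi, mi)
  rk <- match(seq_along(id), ord)
  remap <- function(p, ord) {
    po <- p[ord]
    ifelse(po == 0L, 0L, rk[pmax(po, 1L)])
  }
  new_pedigree(label = id[ord], father = remap(fi, ord),
               mother = remap(mi, ord),
               analyzed = analyzed[ord], structure = "custom")
}

topo_order <- function(father, mother) {
  n <- length(father)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (father == 0L | placed[pmax(father, 1L)]) &
                   (mother == 0L | placed[pmax(mother, 1L)]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) != n) stop("pedigree parentage graph contains a cycle")
  ord
}

#' @rdname read_fam
#' @param ped a `pedigree` object.
#' @param family family id written in the first column.
#' @return `write_fam`: the path, invisibly.
#' @export
write_fam <- function(ped, path, family = "FAM1") {
  par_lab <- function(p) ifelse(p == 0L, "0", ped$label[pmax(p, 1L)])
  tab <- data.frame(family = family, id = ped$label,
                    father = par_lab(ped$father),
                    mother = par_lab(ped$mother),
                    sex = 0L,
                    phenotype = ifelse(ped$analyzed, 1L, 0L))
  write.table(tab, path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Pedigree kinship matrix (2 Psi)
#'
#' Computes twice the pedigree kinship matrix over the analyzed individuals by
#' the standard recursion over individuals ordered with parents first:
#' psi(i,i) = (1 + psi(f,m))/2 and psi(i,j) = (psi(f,j) + psi(m,j))/2 for j
#' preceding i, with founders unrelated and outbred. Pedigree kinship is the
#' expectation of realized kinship over descent, so for outbred pedigrees the
#' result has unit diagonal and off-diagonals in [0, 1].
#'
#' @param ped a `pedigree`.
#' @return a [kinship_matrix] of kind `"pedigree_2psi"` over the analyzed set.
#' @examples
#' ped <- build_pedigree("sibpair")
#' pedigree_kinship(ped)$matrix
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  psi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (f == 0L) {
      psi[i, i] <- 0.5
    } else {
      j <- seq_len(i - 1L)
      psi[i, j] <- psi[j, i] <- 0.5 * (psi[f, j] + psi[m, j])
      psi[i, i] <- 0.5 * (1 + psi[f, m])
    }
  }
  keep <- which(ped$analyzed)
  new_kinship_matrix(2 * psi[keep, keep, drop = FALSE],
                     ids = ped$label[keep],
                     kind = "pedigree_2psi",
                     blocks = rep(1L, length(keep)))
}

#' Kinship coefficient between two individuals
#'
#' Convenience accessor: the pedigree kinship coefficient psi (not doubled)
#' between two analyzed individuals.
#'
#' @param ped a `pedigree`.
#' @param i,j individual labels.
#' @export
kinship_coefficient <- function(ped, i, j) {
  km <- pedigree_kinship(ped)
  ii <- match(as.character(i), km$ids); jj <- match(as.character(j), km$ids)
  if (anyNA(c(ii, jj))) stop("individual not in the analyzed set")
  km$matrix[ii, jj] / 2
}
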