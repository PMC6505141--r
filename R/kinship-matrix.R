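#' Kinship / genetic correlation matrix container
#'
#' A symmetric N x N genetic correlation matrix tagged with the kinship
#' measure it carries and with its block partition over mutually independent
#' pedigrees (entries between different blocks are structurally zero). All
#' model fitting and asymptotic computations in the package operate per block.
#'
#' Kinds: `"pedigree_2psi"` (twice pedigree kinship), `"realized_2phi"`
#' (twice genome-wide realized kinship), `"realized_2phi_chr"` (twice realized
#' kinship on a chromosome subset), `"grm_classic"` (classic marker-based
#' GRM), `"grm_plugin"` (user-supplied estimator).
#'
#' @param matrix numeric symmetric matrix.
#' @param ids character ids for rows/columns.
#' @param kind one of the kind tags above.
#' @param blocks integer vector assigning each row to a pedigree block;
#'   must be constant within contiguous runs.
#' @return an object of class `kinship_matrix` with fields `matrix`, `ids`,
#'   `kind`, `blocks`.
#' @export
new_kinship_matrix <- function(matrix, ids, kind, blocks) {
  kinds <- c("pedigree_2psi", "realized_2phi", "realized_2phi_chr",
             "grm_classic", "grm_plugin")
  kind <- match.arg(kind, kinds)
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  stopifnot(ncol(matrix) == n, length(ids) == n, length(blocks) == n)
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("kinship matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, ids = as.character(ids), kind = kind,
                 blocks = as.integer(blocks)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix>", x$kind, "| N =", nrow(x$matrix),
      "| blocks =", length(unique(x$blocks)), "\n")
  invisible(x)
}

#' @export
dim.kinship_matrix <- function(x) dim(x$matrix)

block_indices <- function(km) split(seq_along(km$blocks), km$blocks)

#' Extract the per-block submatrices of a kinship matrix
#' @param km a `kinship_matrix`.
#' @return a list of numeric matrices, one per pedigree block.
#' @export
kinship_blocks <- function(km) {
  lapply(block_indices(km), function(ix) km$matrix[ix, ix, drop = FALSE])
}

#' Replicate a single-pedigree kinship matrix over m independent pedigrees
#'
#' The pedigree kinship matrix is the same for every pedigree of a given
#' structure, so a sample of m independent pedigrees has a block-diagonal
#' matrix with m identical blocks.
#'
#' @param km a single-block `kinship_matrix`.
#' @param m number of independent pedigrees.
#' @export
rep_kinship <- function(km, m) {
  stopifnot(inherits(km, "kinship_matrix"))
  if (m == 1L) return(km)
  nb <- nrow(km$matrix)
  big <- matrix(0, nb * m, nb * m)
  for (b in seq_len(m)) {
    ix <- (b - 1L) * nb + seq_len(nb)
    big[ix, ix] <- km$matrix
  }
  new_kinship_matrix(big, ids = block_ids(km$ids, m), kind = km$kind,
                     blocks = rep(seq_len(m), each = nb))
}

block_ids <- function(ids, m) {
  if (m == 1L) return(ids)
  as.vector(vapply(seq_len(m), function(b) paste0("P", b, "_", ids),
                   character(length(ids))))
}

#' Read and write kinship matrices as TSV
#'
#' Plain-text format: an optional leading comment `#kind=<kind>` (and
#' `#blocks=` comma-separated block sizes), a header row of ids, then N rows
#' of N numeric fields.
#'
#' @param km a `kinship_matrix`.
#' @param path file path.
#' @export
write_kinship <- function(km, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind=", km$kind), con)
  writeLines(paste0("#blocks=", paste(tabulate(km$blocks), collapse = ",")),
             con)
  writeLines(paste(km$ids, collapse = "\t"), con)
  write.table(format(km$matrix, digits = 17, trim = TRUE, scientific = TRUE),
              con, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kind <- sub("^#kind=", "", grep("^#kind=", meta, value = TRUE))
  if (!length(kind)) kind <- "pedigree_2psi"
  ids <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  mat <- as.matrix(read.table(text = body[-1L], sep = "\t"))
  bl <- grep("^#blocks=", meta, value = TRUE)
  blocks <- if (length(bl)) {
    sizes <- as.integer(strsplit(sub("^#blocks=", "", bl), ",")[[1L]])
    rep(seq_along(sizes), sizes)
  } else rep(1L, length(ids))
  new_kinship_matrix(mat, ids, kind, blocks)
}
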