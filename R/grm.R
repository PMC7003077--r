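#' VanRaden genomic relationship matrix
#'
#' `G = (X - 2p)(X - 2p)' / (2 * sum(p_s (1 - p_s)))` on a complete
#' (typically mean-imputed) dosage matrix, with allele frequencies `p`
#' estimated as half the observed column means.
#'
#' @param dosages Individuals x SNPs numeric matrix without missing cells
#'   (see [mean_impute()]).
#' @param p Optional per-SNP alternate allele frequencies; estimated as
#'   half the column means when omitted.
#' @return A `relationship_matrix`: list with the symmetric matrix `G`,
#'   `ids`, `method = "vanraden"` and `n_snps` used.
#' @examples
#' X <- rbind(a = c(0, 1, 2, 0), b = c(2, 1, 0, 2))
#' vanraden_grm(X)$G
#' @export
vanraden_grm <- function(dosages, p = NULL) {
  stopifnot(is.matrix(dosages))
  if (anyNA(dosages)) stop("dosages contain missing cells; mean-impute first")
  if (is.null(p)) p <- colMeans(dosages) / 2
  if (length(p) != ncol(dosages)) stop("p must have one entry per SNP")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero VanRaden denominator")
  xc <- sweep(dosages, 2, 2 * p)
  G <- tcrossprod(xc) / denom
  new_relationship_matrix(G, rownames(dosages), "vanraden",
                          n_snps = ncol(dosages))
}

#' Depth-adjusted (KGD) genomic relationship matrix from allele reads
#'
#' Works directly on naive genotype calls from low-coverage reads, with no
#' imputation. Each off-diagonal element is the centred cross-product over
#' the SNPs covered in *both* individuals, scaled by `2 * sum(p_s q_s)` over
#' that same subset; it is unbiased at any depth because read errors are
#' independent between individuals and `E[call | genotype] = genotype`.
#' The diagonal requires a depth correction: a true heterozygote read at
#' depth `d` is called homozygous with probability `2^(1-d)`, inflating the
#' naive self cross-product by exactly `2^(1-d)` per heterozygous site.
#' Under Hardy-Weinberg proportions the expected inflation per covered SNP
#' is `2 p_s q_s 2^(1-d)`, which is subtracted cell-wise so that the
#' expected diagonal equals `1 + F` under the binomial read-sampling model.
#'
#' @param reads A `read_matrix`.
#' @return A `relationship_matrix` with `method = "kgd"`, per-pair SNP
#'   counts in `n_snps_pair`, and `NA` (flagged, with a warning) for pairs
#'   sharing no covered SNPs.
#' @export
kgd_grm <- function(reads) {
  stopifnot(inherits(reads, "read_matrix"))
  x <- naive_calls(reads)
  depth <- reads$ref + reads$alt
  if (any(rowSums(depth > 0) == 0))
    stop("individual(s) with no covered SNPs: ",
         paste(head(reads$ids[rowSums(depth > 0) == 0]), collapse = ", "))
  p <- attr(x, "p")
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic in the naive calls")
  x <- x[, poly, drop = FALSE]
  depth <- depth[, poly, drop = FALSE]
  p <- p[poly]
  w <- 2 * p * (1 - p)

  covered <- (depth > 0) * 1
  xc <- sweep(x, 2, 2 * p)
  xc[is.na(xc)] <- 0
  num <- tcrossprod(xc)
  den <- tcrossprod(sweep(covered, 2, w, "*"), covered)
  npair <- tcrossprod(covered)

  # diagonal depth correction: subtract 2*p*q*2^(1-d) per covered cell
  infl <- covered * sweep(2^(1 - depth), 2, w, "*")
  diag(num) <- diag(num) - rowSums(infl)

  G <- num / den
  no_shared <- npair == 0
  if (any(no_shared)) {
    warning(sum(no_shared & upper.tri(no_shared)),
            " pair(s) share no covered SNPs; entries flagged NA")
    G[no_shared] <- NA_real_
  }
  out <- new_relationship_matrix(G, reads$ids, "kgd", n_snps = sum(poly))
  out$n_snps_pair <- npair
  out
}

new_relationship_matrix <- function(G, ids, method, n_snps) {
  if (is.null(ids)) ids <- sprintf("I%03d", seq_len(nrow(G)))
  G <- (G + t(G)) / 2   # enforce exact symmetry against rounding
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, ids = ids, method = method, n_snps = n_snps),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  off <- x$G[upper.tri(x$G)]
  cat(sprintf(
    "<relationship_matrix> %s, %d individuals, %d SNPs; mean diag %.3f, mean off-diag %.3f\n",
    x$method, length(x$ids), x$n_snps, mean(diag(x$G), na.rm = TRUE),
    mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Replace flagged missing relationship entries by zero
#'
#' Model fitting needs a complete matrix; pairs that shared no covered SNPs
#' carry no information and are set to the unrelated expectation 0, with a
#' warning stating how many entries were replaced.
#'
#' @param grm A `relationship_matrix`.
#' @return The completed `relationship_matrix`.
#' @export
complete_grm <- function(grm) {
  stopifnot(inherits(grm, "relationship_matrix"))
  n_na <- sum(is.na(grm$G))
  if (n_na > 0) {
    warning("replacing ", n_na, " flagged missing relationship entries by 0")
    grm$G[is.na(grm$G)] <- 0
  }
  grm
}

# Subset a relationship matrix to (and in the order of) the given ids.
grm_subset <- function(grm, ids) {
  miss <- setdiff(ids, grm$ids)
  if (length(miss))
    stop("identifiers absent from relationship matrix: ",
         paste(head(miss), collapse = ", "))
  idx <- match(ids, grm$ids)
  new_relationship_matrix(grm$G[idx, idx, drop = FALSE], ids, grm$method,
                          grm$n_snps)
}
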