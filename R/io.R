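# Readers and writers for the standard formats: VCF with GT/AD/DP for
# genotypes, tab-delimited tables for phenotypes, relationship matrices
# and reports.

#' Write allele read counts as VCF
#'
#' One sample per maternal parent; FORMAT fields GT (naive call), AD
#' (ref,alt read counts) and DP (total depth). Zero-depth genotypes are
#' emitted as `./.` with `AD = 0,0`. Plain-text VCF 4.2.
#'
#' @param reads A `read_matrix`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf_reads <- function(reads, path) {
  stopifnot(inherits(reads, "read_matrix"))
  info <- reads$snp_info
  n <- nrow(reads$ref)
  m <- ncol(reads$ref)
  gt <- matrix("./.", m, n)
  x <- t(naive_calls(reads))            # SNPs x individuals
  gt[!is.na(x) & x == 0] <- "0/0"
  gt[!is.na(x) & x == 1] <- "0/1"
  gt[!is.na(x) & x == 2] <- "1/1"
  ad <- matrix(paste0(t(reads$ref), ",", t(reads$alt)), m, n)
  dp <- t(reads$ref + reads$alt)
  cells <- matrix(paste0(gt, ":", ad, ":", dp), m, n)
  body <- paste(info$chrom, info$pos, info$id, info$ref, info$alt, ".",
                "PASS", ".", "GT:AD:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=forageGS",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Naive genotype call">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", reads$ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read allele read counts from a VCF
#'
#' Parses GT/AD/DP FORMAT fields (via the vcfR parser). AD is preferred;
#' records carrying only GT/DP cannot attribute reads to alleles and are
#' excluded from the read matrix with a logged count, as are
#' non-biallelic records. `./.` genotypes map to depth 0.
#'
#' @param path VCF path (plain text or gzipped).
#' @return A `read_matrix`; counts of skipped records are attached as
#'   attribute `skipped`.
#' @export
read_vcf_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1
  n_multi <- sum(!biallelic)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad)) stop("VCF lacks an AD FORMAT field: ", path)
  has_ad <- rowSums(!is.na(ad)) > 0
  keep <- biallelic & has_ad
  n_noad <- sum(biallelic & !has_ad)
  if (!any(keep)) stop("no usable biallelic records with AD in ", path)
  ad <- ad[keep, , drop = FALSE]
  split_counts <- function(k) {
    out <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(ad), "0,0", ad), ",",
                                 fixed = TRUE),
                        function(z) if (length(z) >= k) z[k] else "0",
                        character(1))))
    out[is.na(out)] <- 0L
    matrix(out, nrow(ad), ncol(ad))
  }
  refm <- t(split_counts(1))
  altm <- t(split_counts(2))
  ids <- colnames(ad)
  rownames(refm) <- rownames(altm) <- ids
  fix <- fix[keep, , drop = FALSE]
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                   fix$ID)
  colnames(refm) <- colnames(altm) <- snp_id
  out <- new_read_matrix(refm, altm,
                         data.frame(chrom = fix$CHROM,
                                    pos = as.integer(fix$POS), id = snp_id,
                                    ref = fix$REF, alt = fix$ALT,
                                    stringsAsFactors = FALSE))
  attr(out, "skipped") <- c(non_biallelic = n_multi, no_ad = n_noad)
  out
}

#' Trial table and matrix I/O
#'
#' Tab-delimited readers/writers: trial tables carry the header `family,
#' population, location, replicate, row, column`, then one column per
#' trait; relationship matrices are square with identifiers in the first
#' row and column.
#'
#' @param data Trial table.
#' @param path File path.
#' @return The written path (writers, invisibly) or the parsed object
#'   (readers).
#' @export
write_trial_table <- function(data, path) {
  req <- c("family", "population", "location", "replicate", "row", "column")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  keep <- c(req, setdiff(names(data), c(req, "fam_loc", "rep_id", "row_id",
                                        "col_id")))
  write.table(data[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param column_map Optional named character vector renaming file columns
#'   to the canonical schema, e.g. `c(family = "FamID")`.
#' @export
read_trial_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (canon in names(column_map)) {
      i <- match(column_map[[canon]], names(d))
      if (is.na(i)) stop("mapped column not in file: ", column_map[[canon]])
      names(d)[i] <- canon
    }
  req <- c("family", "population", "location", "replicate", "row", "column")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname write_trial_table
#' @param grm A `relationship_matrix`.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "relationship_matrix"))
  m <- cbind(id = grm$ids, as.data.frame(grm$G, check.names = FALSE))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param method Method tag recorded on the matrix read back.
#' @export
read_grm <- function(path, method = "supplied") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  G <- as.matrix(d[, -1, drop = FALSE])
  if (nrow(G) != ncol(G)) stop("relationship matrix is not square: ", path)
  new_relationship_matrix(G, ids, method, n_snps = NA_integer_)
}

#' Derived nutritive traits
#'
#' Appends crude protein `CP = 6.25 * N` (nitrogen-to-protein conversion)
#' and the grass tetany ratio `K / (Mg + Ca)` when the input traits are
#' present. Plots with `Mg + Ca = 0` get a flagged `NA` ratio. Ratios
#' above 2.2 indicate elevated hypomagnesaemia risk; the count of such
#' plots is attached as attribute `n_tetany_risk`.
#'
#' @param data Trial table with trait columns `N` and/or `K`, `Mg`, `Ca`.
#' @return The table with `CP` / `tetany_ratio` columns appended.
#' @export
derive_traits <- function(data) {
  if ("N" %in% names(data)) data$CP <- 6.25 * data$N
  if (all(c("K", "Mg", "Ca") %in% names(data))) {
    denom <- data$Mg + data$Ca
    bad <- !is.na(denom) & denom == 0
    if (any(bad)) warning(sum(bad), " plot(s) with Mg + Ca = 0; ",
                          "tetany ratio flagged NA")
    data$tetany_ratio <- ifelse(bad, NA_real_, data$K / denom)
    attr(data, "n_tetany_risk") <-
      sum(data$tetany_ratio > 2.2, na.rm = TRUE)
  }
  data
}
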