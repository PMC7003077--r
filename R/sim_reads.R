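#' Simulate GBS allele reads for a founder set
#'
#' Read depth per genotype follows a zero-inflated, zero-truncated Poisson:
#' with probability `missing_rate` the genotype gets zero reads; otherwise
#' depth is drawn from a zero-truncated Poisson whose mean equals
#' `mean_depth`. Given depth `d`, alternate-allele reads are binomial with
#' success probability `g/2` for true dosage `g`, which reproduces the
#' characteristic low-coverage artefact: a heterozygote is observed as
#' homozygous with probability `2^(1-d)`.
#'
#' @param founders A [founder_set][simulate_population_set()].
#' @param mean_depth Mean of the nonzero depth distribution (reads).
#' @param missing_rate Probability of a zero-read (missing) genotype.
#' @param seed Integer seed; defaults to the read-stage stream of the
#'   founder configuration.
#' @return A `read_matrix`: list with integer matrices `ref` and `alt`
#'   (parents x SNPs), `snp_info` and `ids`.
#' @examples
#' f <- simulate_population_set(sim_config(n_populations = 1,
#'   families_per_population = 5, n_snps = 30, seed = 2))
#' r <- simulate_gbs_reads(f, mean_depth = 3, missing_rate = 0.2)
#' mean(r$ref + r$alt == 0)
#' @export
simulate_gbs_reads <- function(founders,
                               mean_depth = founders$config$mean_depth,
                               missing_rate = founders$config$missing_rate,
                               seed = NULL) {
  stopifnot(inherits(founders, "founder_set"))
  if (mean_depth <= 0) stop("mean_depth: must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate: must lie in [0, 1)")
  if (is.null(seed)) seed <- stage_seed(founders$config$seed, "reads")
  set.seed(seed)

  g <- founders$genotypes
  n <- nrow(g); m <- ncol(g); ncell <- n * m
  depth <- integer(ncell)
  covered <- runif(ncell) >= missing_rate
  depth[covered] <- rztpois(sum(covered), ztpois_lambda(mean_depth))
  alt <- integer(ncell)
  idx <- which(depth > 0L)
  alt[idx] <- rbinom(length(idx), depth[idx], as.vector(g)[idx] / 2)
  ref <- depth - alt
  dn <- dimnames(g)
  new_read_matrix(matrix(as.integer(ref), n, m, dimnames = dn),
                  matrix(as.integer(alt), n, m, dimnames = dn),
                  founders$snp_info)
}

new_read_matrix <- function(ref, alt, snp_info) {
  stopifnot(all(dim(ref) == dim(alt)), all(ref >= 0), all(alt >= 0),
            nrow(snp_info) == ncol(ref))
  ids <- rownames(ref)
  if (is.null(ids)) {
    ids <- sprintf("I%03d", seq_len(nrow(ref)))
    rownames(ref) <- rownames(alt) <- ids
  }
  if (anyDuplicated(ids)) stop("individual identifiers must be unique")
  if (anyDuplicated(snp_info$id)) stop("SNP identifiers must be unique")
  structure(list(ref = ref, alt = alt, snp_info = snp_info, ids = ids),
            class = "read_matrix")
}

#' @export
print.read_matrix <- function(x, ...) {
  d <- x$ref + x$alt
  cat("<read_matrix>", nrow(x$ref), "individuals x", ncol(x$ref), "SNPs;",
      sprintf("missing %.1f%%, mean nonzero depth %.2f\n",
              100 * mean(d == 0), mean(d[d > 0])))
  invisible(x)
}

# Mean of a zero-truncated Poisson with rate lambda is lambda/(1-exp(-lambda));
# invert numerically to hit a requested mean (> 1).
ztpois_lambda <- function(mean_depth) {
  if (mean_depth <= 1) return(1e-8)  # degenerate: essentially all depth-1
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_depth,
                 c(1e-8, mean_depth + 10))$root
}

rztpois <- function(n, lambda) {
  if (lambda < 1e-6) return(rep(1L, n))
  x <- rpois(n, lambda)
  while (any(z <- x == 0L)) x[z] <- rpois(sum(z), lambda)
  x
}
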