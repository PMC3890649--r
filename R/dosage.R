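# Maximum-likelihood allele dosage estimation from clone counts.
#
# Model: sequencing n clones of a polyploid locus is a multinomial draw in
# which each clone carries allele i with probability dosage_i / ploidy.
# Dosages are integer copy numbers summing to the ploidy; the estimate is
# the exhaustive-enumeration argmax of the multinomial log-likelihood.

#' Multinomial log-likelihood of an allele dosage
#'
#' Computes `sum_i counts_i * log(dosage_i / ploidy)` (the multinomial
#' log-likelihood with the constant combinatorial term dropped), with the
#' convention `0 * log(0) = 0`.  A dosage of zero for an observed allele
#' yields `-Inf`.
#'
#' @param counts Non-negative integer vector of clone counts per allele.
#' @param dosage Integer vector of copy numbers, same length as `counts`,
#'   summing to `ploidy`.
#' @param ploidy Total copy number (4 for a tetraploid).
#' @return The log-likelihood (natural log).
#' @export
#' @examples
#' dosage_loglik(c(15, 1), c(3, 1), ploidy = 4)
dosage_loglik <- function(counts, dosage, ploidy = 4L) {
  if (length(counts) != length(dosage))
    stop("counts and dosage must have the same length")
  if (any(counts < 0) || any(dosage < 0)) stop("negative entries")
  if (sum(dosage) != ploidy) stop("dosage must sum to the ploidy")
  if (any(counts > 0 & dosage == 0)) return(-Inf)
  use <- counts > 0
  sum(counts[use] * log(dosage[use] / ploidy))
}

# All integer vectors of length k with entries >= mn summing to total.
dosage_compositions <- function(total, k, mn) {
  if (k == 1L) {
    if (total >= mn) return(matrix(total, nrow = 1L)) else
      return(matrix(integer(0), ncol = 1L))
  }
  out <- list()
  for (d in mn:(total - mn * (k - 1L))) {
    rest <- dosage_compositions(total - d, k - 1L, mn)
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(d, rest)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = k)
}

#' Maximum-likelihood allele dosage from clone counts
#'
#' Enumerates every integer dosage vector with entries of at least
#' `min_copies` summing to the ploidy and returns the one maximising the
#' multinomial log-likelihood of the observed clone counts.  Ties are
#' reported via `ml_unique = FALSE` together with all co-maximal vectors.
#'
#' @param counts Named (or unnamed) non-negative integer vector of clone
#'   counts; at least one clone in total.
#' @param ploidy Total copy number (default 4).
#' @param min_copies Minimum copies per observed allele (default 1: every
#'   sequenced allele exists at least once; set 0 to allow absent alleles).
#' @return An object of class `dosage_estimate`: a list with `dosage`
#'   (named integer vector), `log_likelihood`, `ml_unique`, and
#'   `alternatives` (all candidate vectors with their log-likelihoods and
#'   the likelihood ratio to the maximum).
#' @export
#' @examples
#' estimate_dosage(c(a1 = 15, a2 = 1), ploidy = 4)   # 3 + 1 copies
#' estimate_dosage(c(b1 = 10, b2 = 2), ploidy = 4)   # 3 + 1 copies
estimate_dosage <- function(counts, ploidy = 4L, min_copies = 1L) {
  k <- length(counts)
  if (sum(counts) < 1L) stop("need at least one clone")
  if (any(counts < 0)) stop("clone counts must be non-negative")
  if (k * min_copies > ploidy)
    stop("infeasible: ", k, " alleles with >= ", min_copies,
         " copies each exceed ploidy ", ploidy)
  labs <- if (!is.null(names(counts))) names(counts) else
    paste0("allele", seq_len(k))
  cand <- dosage_compositions(ploidy, k, as.integer(min_copies))
  ll <- apply(cand, 1L, dosage_loglik, counts = counts, ploidy = ploidy)
  best <- max(ll)
  top <- which(ll == best)
  alternatives <- data.frame(cand)
  names(alternatives) <- labs
  alternatives$log_likelihood <- ll
  alternatives$lr_to_best <- exp(ll - best)
  alternatives <- alternatives[order(-ll), , drop = FALSE]
  rownames(alternatives) <- NULL
  dos <- as.integer(cand[top[1L], ])
  names(dos) <- labs
  structure(list(dosage = dos, log_likelihood = best,
                 ml_unique = length(top) == 1L,
                 alternatives = alternatives),
            class = "dosage_estimate")
}

#' @export
print.dosage_estimate <- function(x, ...) {
  cat("<dosage_estimate> ML copies:",
      paste(names(x$dosage), x$dosage, sep = "=", collapse = ", "),
      sprintf("(logLik %.4f%s)\n", x$log_likelihood,
              if (x$ml_unique) "" else ", tied"))
  invisible(x)
}
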