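#' Round half away from zero
#'
#' Rounding convention used for all printed percentages: ties are rounded away
#' from zero (so 0.25 -> 0.3 at one decimal), unlike [base::round()], which
#' rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.25, 1) # 0.3
#' round_half_away(11.5, 0) # 12
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalized mutual information between two partitions
#'
#' Used to score recovery of planted community structure. Uses the symmetric
#' normalisation 2 I(X;Y) / (H(X) + H(Y)). Two identical trivial partitions
#' (single cluster or all singletons in both) score 1.
#'
#' @param a,b Vectors of cluster labels over the same items (any type that can
#'   be tabulated; order must correspond).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
nmi <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * p_j[col(pij)[nz]])))
  if (hx + hy == 0) {
    return(1) # both partitions trivial and identical in structure
  }
  max(0, min(1, 2 * mi / (hx + hy)))
}

#' Build a canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors of VCF fields.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# normalise gene symbols for matching: strip whitespace, uppercase
norm_gene <- function(x) toupper(trimws(x))

# deterministic RNG scope: all stochastic nsnet code routes through this
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_nsnet <- function(msg, ...) {
  abort(paste0(sprintf(msg, ...)), class = "nsnet_error")
}
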