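# internal helpers shared across modules

#' @importFrom stats median rnorm runif rgamma rbinom var sd quantile
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural ordering rank for chromosome names
#'
#' Orders `chr1 < chr2 < ... < chr10 < ... < chrX < chrY`; names without a
#' numeric part sort after numeric chromosomes, alphabetically.
#' @param chrom character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(stripped))
  num[stripped %in% c("X", "x")] <- 23L
  num[stripped %in% c("Y", "y")] <- 24L
  num[stripped %in% c("M", "MT", "m", "mt")] <- 25L
  # non-numeric leftovers sort last, alphabetically
  extra <- is.na(num)
  if (any(extra)) {
    lev <- sort(unique(stripped[extra]))
    num[extra] <- 1000L + match(stripped[extra], lev)
  }
  num
}

order_genomic <- function(chrom, start) order(chrom_rank(chrom), start)

#' Dirichlet random compositions
#' @param n number of rows.
#' @param alpha concentration vector (length K).
#' @return n x K matrix of compositions, rows summing to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Largest-remainder apportionment of n units to fractions
#'
#' Deterministic: floors of `n * frac`, remaining units to the largest
#' fractional remainders, ties broken by position.
#' @param n total count.
#' @param frac fractions summing to 1.
#' @return integer vector summing to n.
#' @keywords internal
largest_remainder <- function(n, frac) {
  raw <- n * frac
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
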