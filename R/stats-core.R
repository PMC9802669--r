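# Exact-test primitives shared by the methylome, DMR, expression and
# integration stages. All tails are computed from stats:: d/p functions;
# the test suite checks them against independent choose()-based enumeration.

#' Upper-tail binomial probability P(X >= m)
#'
#' The methylcytosine caller's null: out of `n` aligned reads, `m` support
#' methylation, and an unmethylated cytosine yields a spurious methylation
#' call with probability `error_rate` (bisulfite non-conversion plus
#' sequencing error).
#'
#' @param m integer vector, methylation-supporting read counts (>= 0).
#' @param n integer vector, total read counts (>= m).
#' @param error_rate scalar in [0, 1): null probability of a methylated call.
#' @return numeric vector of P(X >= m) under Binomial(n, error_rate).
#' @examples
#' binom_upper_tail(0, 10, 0.01)  # 1
#' binom_upper_tail(9, 10, 0.01)  # ~9.3e-17
#' @export
binom_upper_tail <- function(m, n, error_rate) {
  if (length(error_rate) != 1L || error_rate < 0 || error_rate >= 1)
    stop("error_rate must be a single value in [0, 1)")
  if (any(m < 0) || any(n < 0) || any(m > n))
    stop("need 0 <= m <= n")
  stats::pbinom(m - 1L, n, error_rate, lower.tail = FALSE)
}

#' Two-sided Fisher exact test for 2x2 read-count tables
#'
#' Conditional on the margins, the first group's methylated count follows a
#' hypergeometric distribution; the two-sided p-value sums the probabilities
#' of all tables at fixed margins that are no more probable than the
#' observed one (the same convention as [stats::fisher.test()]). Vectorised
#' over tables.
#'
#' @param ma,ua methylated/unmethylated pooled counts, group A.
#' @param mb,ub methylated/unmethylated pooled counts, group B.
#' @return numeric vector of two-sided p-values in (0, 1].
#' @export
fisher_test_2x2 <- function(ma, ua, mb, ub) {
  if (any(c(ma, ua, mb, ub) < 0)) stop("counts must be non-negative")
  n <- length(ma)
  stopifnot(length(ua) == n, length(mb) == n, length(ub) == n)
  na <- ma + ua
  nb <- mb + ub
  K  <- ma + mb
  tot <- na + nb
  p <- numeric(n)
  dh <- stats::dhyper; ph <- stats::phyper
  relerr <- 1 + 1e-7
  for (i in seq_len(n)) {
    if (tot[i] == 0L || K[i] == 0L || K[i] == tot[i] || na[i] == 0L || nb[i] == 0L) {
      p[i] <- 1
      next
    }
    Ki <- K[i]; wi <- tot[i] - K[i]; ni <- na[i]; x <- ma[i]
    lo <- max(0L, Ki - nb[i]); hi <- min(Ki, ni)
    dob <- dh(x, Ki, wi, ni)
    # mode of the hypergeometric pmf
    md <- floor((ni + 1) * (Ki + 1) / (tot[i] + 2))
    md <- min(max(md, lo), hi)
    if (x < md) {
      # smallest y in [md, hi] with d(y) <= dob; pmf decreasing on that flank
      if (dh(hi, Ki, wi, ni) > dob * relerr) {
        p[i] <- ph(x, Ki, wi, ni)
      } else {
        a <- md; b <- hi
        while (a < b) {
          mid <- (a + b) %/% 2
          if (dh(mid, Ki, wi, ni) <= dob * relerr) b <- mid else a <- mid + 1L
        }
        p[i] <- ph(x, Ki, wi, ni) + ph(a - 1L, Ki, wi, ni, lower.tail = FALSE)
      }
    } else if (x > md) {
      # largest y in [lo, md] with d(y) <= dob; pmf increasing on that flank
      if (dh(lo, Ki, wi, ni) > dob * relerr) {
        p[i] <- ph(x - 1L, Ki, wi, ni, lower.tail = FALSE)
      } else {
        a <- lo; b <- md
        while (a < b) {
          mid <- (a + b + 1L) %/% 2
          if (dh(mid, Ki, wi, ni) <= dob * relerr) a <- mid else b <- mid - 1L
        }
        p[i] <- ph(x - 1L, Ki, wi, ni, lower.tail = FALSE) + ph(a, Ki, wi, ni)
      }
    } else {
      p[i] <- 1
    }
    if (p[i] > 1) p[i] <- 1
  }
  p
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Over-representation tail used for DEG enrichment in DMR-associated genes
#' and for term enrichment: from `N` background genes of which `K` carry the
#' property, a draw of `n` genes contains `k` or more carriers.
#'
#' @param k observed overlap count.
#' @param K property-carrying genes in the background.
#' @param N background size.
#' @param n drawn set size.
#' @return P(X >= k), vectorised.
#' @export
hyper_upper_tail <- function(k, K, N, n) {
  if (any(K > N) || any(n > N)) stop("need K <= N and n <= N")
  if (any(k < 0)) stop("k must be non-negative")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Exact two-sided binomial test p-value, vectorised, without enumerating the
# full support: conditional on x ~ Binomial(size, prob), sums both tails of
# outcomes no more probable than x. The off-tail cutoff is located by binary
# search on the monotone flank of the unimodal pmf.
binom_two_sided <- function(x, size, prob) {
  n <- length(x)
  stopifnot(length(size) == n)
  if (length(prob) == 1L) prob <- rep(prob, n)
  relerr <- 1 + 1e-7
  out <- numeric(n)
  for (i in seq_len(n)) {
    ni <- size[i]; p <- prob[i]; xi <- x[i]
    if (ni == 0L) { out[i] <- 1; next }
    dob <- stats::dbinom(xi, ni, p)
    mode <- floor((ni + 1) * p)
    if (xi < mode) {
      # find smallest y in [mode, ni] with d(y) <= dob (d decreasing there)
      lo <- mode; hi <- ni
      if (stats::dbinom(hi, ni, p) > dob * relerr) {
        out[i] <- stats::pbinom(xi, ni, p)
      } else {
        while (lo < hi) {
          mid <- (lo + hi) %/% 2
          if (stats::dbinom(mid, ni, p) <= dob * relerr) hi <- mid else lo <- mid + 1L
        }
        out[i] <- stats::pbinom(xi, ni, p) +
          stats::pbinom(lo - 1L, ni, p, lower.tail = FALSE)
      }
    } else if (xi > mode) {
      # find largest y in [0, mode] with d(y) <= dob (d increasing there)
      lo <- 0L; hi <- mode
      if (stats::dbinom(lo, ni, p) > dob * relerr) {
        out[i] <- stats::pbinom(xi - 1L, ni, p, lower.tail = FALSE)
      } else {
        while (lo < hi) {
          mid <- (lo + hi + 1L) %/% 2
          if (stats::dbinom(mid, ni, p) <= dob * relerr) lo <- mid else hi <- mid - 1L
        }
        out[i] <- stats::pbinom(xi - 1L, ni, p, lower.tail = FALSE) +
          stats::pbinom(lo, ni, p)
      }
    } else {
      out[i] <- 1
    }
    if (out[i] > 1) out[i] <- 1
  }
  out
}
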