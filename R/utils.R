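#' @useDynLib caqtlkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rnorm runif rbinom rpois rbeta rnbinom rlnorm
#' @importFrom stats optim optimize pchisq pf p.adjust cor fisher.test
#' @importFrom stats binom.test prcomp lm anova sd var median quantile complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta-binomial random draws
#'
#' @param n number of draws
#' @param size trial counts (recycled)
#' @param prob mean success probability
#' @param theta overdispersion; the binomial is recovered as `theta -> 0`
#' @return integer vector of successes
#' @keywords internal
rbetabinom <- function(n, size, prob, theta) {
  if (theta < 1e-8) return(rbinom(n, size, prob))
  p <- rbeta(n, prob / theta, (1 - prob) / theta)
  rbinom(n, size, p)
}

# Interval overlap on 0-based half-open intervals via IRanges.
# Returns a data.table(query = i, subject = j) of overlapping index pairs.
# maxgap = -1 (IRanges convention): adjacency does not count as overlap.
overlap_pairs <- function(start1, end1, start2, end2, maxgap = -1L) {
  q <- IRanges::IRanges(start = start1 + 1L, end = end1)  # 1-based closed
  s <- IRanges::IRanges(start = start2 + 1L, end = end2)
  hits <- IRanges::findOverlaps(q, s, maxgap = maxgap)
  data.table(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# stable child seed: offsets below 2^31 derived from a user seed
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

bh_adjust <- function(p) p.adjust(p, method = "BH")

# Map new p-values onto a reference set's BH q-value scale: each new p
# receives the q-value of the smallest reference p-value >= it (1 beyond the
# largest).  Used to place permuted lead p-values on the observed q scale so
# that the empirical FDR compares like with like; BH q-values computed
# within a pure-null permuted set are not comparable to q-values from a
# signal-carrying set.
bh_map <- function(p_ref) {
  ord <- order(p_ref)
  p_sorted <- p_ref[ord]
  q_sorted <- bh_adjust(p_ref)[ord]
  function(p_new) {
    idx <- findInterval(p_new, p_sorted, left.open = TRUE) + 1L
    out <- rep(1, length(p_new))
    inside <- idx <= length(q_sorted)
    out[inside] <- q_sorted[idx[inside]]
    out
  }
}

stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
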