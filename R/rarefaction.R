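# Rarefaction: subsample every sample to a common read depth so that
# observed richness is comparable across samples.

#' Rarefy a count table to equal sequencing depth
#'
#' Subsamples each sample's reads to `depth` without replacement
#' (multivariate hypergeometric, via [vegan::rrarefy()]), so each retained
#' sample sums exactly to `depth` and no taxon exceeds its original count.
#' Samples with fewer than `depth` total reads are dropped with a warning;
#' taxa left with zero reads table-wide are removed.
#'
#' @param x A [count_table] or counts matrix.
#' @param depth Target reads per sample; defaults to the minimum positive
#'   sample total ("equal sequencing depth" with no stated depth).
#' @param seed Integer seed.
#' @param method `"hypergeometric"` (without replacement, default: the
#'   draw-from-what-was-sequenced semantics appropriate for real read
#'   counts) or `"multinomial"` (with replacement, for simulation work).
#' @return Rarefied object of the same class as `x`, with attributes
#'   `depth`, `seed`, `dropped_samples` and `dropped_taxa`.
#' @examples
#' m <- matrix(c(100, 50, 0, 30), nrow = 2)
#' rarefy_table(m, depth = 30, seed = 1)
#' @export
rarefy_table <- function(x, depth = NULL, seed = 1,
                         method = c("hypergeometric", "multinomial")) {
  method <- match.arg(method)
  m <- as_count_matrix(x)
  tot <- colSums(m)
  if (is.null(depth)) {
    if (all(tot == 0)) abort_param("cannot rarefy an all-zero table")
    depth <- min(tot[tot > 0])
  }
  assert_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  shallow <- tot < depth
  if (all(shallow)) {
    abort_param("depth exceeds every sample's total read count")
  }
  if (any(shallow)) {
    warning(
      sprintf("dropping %d sample(s) shallower than depth %d: %s",
              sum(shallow), depth, toString(colnames(m)[shallow]))
    )
    m <- m[, !shallow, drop = FALSE]
    tot <- tot[!shallow]
  }
  sub <- with_seed(seed, {
    if (method == "hypergeometric") {
      # vegan warns whenever the smallest positive count exceeds 1, which
      # is always the case for read counts; that heuristic is muffled
      withCallingHandlers(
        t(vegan::rrarefy(t(m), depth)),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
    } else {
      apply(m, 2, function(col) {
        as.vector(stats::rmultinom(1, depth, col / sum(col)))
      })
    }
  })
  dimnames(sub) <- dimnames(m)
  lost_taxa <- rownames(sub)[rowSums(sub) == 0]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  out <- if (inherits(x, "count_table")) replace_counts(x, sub) else sub
  attr(out, "depth") <- depth
  attr(out, "seed") <- seed
  attr(out, "dropped_samples") <- if (exists("shallow")) {
    colnames(as_count_matrix(x))[shallow]
  } else character()
  attr(out, "dropped_taxa") <- lost_taxa
  out
}
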