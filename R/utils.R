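#' Largest-remainder apportionment of an integer total
#'
#' Distributes `total` units over categories proportionally to `weights`,
#' using the largest-remainder (Hamilton) method so the counts sum exactly
#' to `total`. Ties in the remainders are broken by lower index.
#'
#' @param weights Non-negative numeric weights (need not sum to 1).
#' @param total Integer total to apportion.
#' @return Integer vector, same length as `weights`, summing to `total`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  if (length(weights) == 0L) return(integer(0))
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    if (total > 0) out[seq_len(length(weights))] <- diff(floor(
      seq(0, total, length.out = length(weights) + 1L)))
    return(out)
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Count for a single proportion of n, largest-remainder over {p, 1-p}.
lr_count <- function(p, n) largest_remainder(c(p, 1 - p), n)[1L]

#' Derive a stage seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed so a single
#' `--seed` reproduces the whole pipeline. Kept below 2^31 - 1.
#'
#' @param seed Root integer seed.
#' @param stage Integer stage index (>= 0).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stage)) %% 2147483646) + 1L
}

# round() uses banker's rounding; marginal checks want half-away-from-zero,
# matching how printed tables are typically rounded.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# number of decimal digits in a printed value, e.g. 9.1 -> 1, 12.83 -> 2
printed_digits <- function(x) {
  s <- sub("0+$", "", sub(".*\\.", "", format(x, scientific = FALSE)))
  if (!grepl("\\.", format(x, scientific = FALSE))) 0L else nchar(s)
}
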