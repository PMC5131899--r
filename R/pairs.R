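#' Linear index of an unordered region pair
#'
#' Maps an unordered region pair `(i, j)` with `i < j` onto a 1-based linear
#' index over the strict upper triangle of the region-by-region matrix, in
#' row-major order: `(1,2) -> 1`, `(1,3) -> 2`, ..., `(n-1, n) -> n(n-1)/2`.
#'
#' @param i,j Region indices, `1 <= i < j <= n_regions`. Vectorised.
#' @param n_regions Total number of regions.
#'
#' @return Integer vector of pair indices.
#' @seealso [pair_unindex()] for the inverse.
#' @export
#' @examples
#' pair_index(1, 2, 90)    # 1
#' pair_index(89, 90, 90)  # 4005
pair_index <- function(i, j, n_regions) {
  n_regions <- check_count(n_regions, "n_regions", min = 2)
  if (any(i < 1) || any(j > n_regions) || any(i >= j)) {
    plv_abort("pair indices must satisfy 1 <= i < j <= n_regions")
  }
  as.integer((i - 1) * (2 * n_regions - i) / 2 + (j - i))
}

#' Inverse of [pair_index()]
#'
#' @param pair Linear pair index (1-based). Vectorised.
#' @param n_regions Total number of regions.
#'
#' @return A tibble with columns `pair`, `i`, `j`.
#' @export
#' @examples
#' pair_unindex(4005, 90)
pair_unindex <- function(pair, n_regions) {
  n_regions <- check_count(n_regions, "n_regions", min = 2)
  n_pairs <- n_regions * (n_regions - 1) / 2
  if (any(pair < 1) || any(pair > n_pairs)) {
    plv_abort("pair index out of range")
  }
  # row i is the largest i with offset(i) < pair, offset(i) = (i-1)(2n-i)/2
  pair <- as.integer(pair)
  i <- vapply(pair, function(p) {
    lo <- 1L
    hi <- n_regions - 1L
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if ((mid - 1) * (2 * n_regions - mid) / 2 < p) lo <- mid else hi <- mid - 1L
    }
    lo
  }, integer(1))
  j <- as.integer(pair - (i - 1) * (2 * n_regions - i) / 2 + i)
  tibble::tibble(pair = pair, i = i, j = j)
}

# All pairs of n regions as a tibble, in pair_index order.
all_pairs <- function(n_regions) {
  pair_unindex(seq_len(n_regions * (n_regions - 1) / 2), n_regions)
}
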