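#' Bit-packed haplotype sequences
#'
#' A haplotype of `s` biallelic markers is stored as a packed bit vector over
#' GF(2): marker `k` (1-based in all user-facing reports) occupies bit
#' `k - 1`, least-significant-bit first within bytes, so a byte holds one
#' 8-marker chunk. 0 encodes the wild (ancestral) allele and 1 the derived
#' allele. All bits beyond marker `s` are zero (canonical padding), which
#' makes bitwise equality of the raw vectors equivalent to equality of the
#' haplotypes.
#'
#' @param bits logical or 0/1 integer vector of marker states.
#' @return An object of class `bitseq`: a raw vector with attribute `s`.
#' @examples
#' h <- bitseq(c(1, 0, 1, 1, 0))
#' as_bits(h)
#' @export
bitseq <- function(bits) {
  bits <- as.logical(bits)
  if (anyNA(bits)) stop("missing marker states are not supported")
  s <- length(bits)
  pad <- (-s) %% 8L
  x <- packBits(c(bits, logical(pad)), type = "raw")
  attr(x, "s") <- s
  class(x) <- "bitseq"
  x
}

#' @rdname bitseq
#' @param x a `bitseq`.
#' @export
as_bits <- function(x) {
  s <- n_markers(x)
  as.integer(rawToBits(unclass(x)))[seq_len(s)]
}

#' @rdname bitseq
#' @export
n_markers <- function(x) attr(x, "s")

#' @export
print.bitseq <- function(x, ...) {
  s <- n_markers(x)
  b <- as_bits(x)
  cat("<bitseq> ", s, " markers: ",
      paste(utils::head(b, 64L), collapse = ""),
      if (s > 64L) "..." else "", "\n", sep = "")
  invisible(x)
}

# raw mask with the first s bits set; used to re-canonicalize padding
pad_mask <- function(s) {
  nb <- (s + 7L) %/% 8L
  packBits(c(rep(TRUE, s), rep(FALSE, nb * 8L - s)), type = "raw")
}

new_bitseq_raw <- function(r, s) {
  attr(r, "s") <- s
  class(r) <- "bitseq"
  r
}

check_same_s <- function(a, b) {
  if (!identical(n_markers(a), n_markers(b)))
    stop("sequences have different marker counts (", n_markers(a), " vs ",
         n_markers(b), ")")
}

#' GF(2) arithmetic on packed haplotypes
#'
#' `seq_xor` is addition over GF(2) (elementwise exclusive or); its set bits
#' mark the markers at which the two haplotypes differ, i.e. markers with an
#' odd number of mutations between them under a model without back
#' mutations. `seq_and` is GF(2) multiplication; applied to the haplotypes
#' of the leaves below an internal vertex it yields that vertex's haplotype
#' (0 is absorbing: an ancestor cannot carry the derived allele if any
#' descendant carries the wild one). Both operate on whole packed words.
#'
#' @param a,b `bitseq` objects with equal marker counts.
#' @return A `bitseq`.
#' @export
seq_xor <- function(a, b) {
  check_same_s(a, b)
  new_bitseq_raw(xor(unclass(a), unclass(b)), n_markers(a))
}

#' @rdname seq_xor
#' @export
seq_and <- function(a, b) {
  check_same_s(a, b)
  new_bitseq_raw(unclass(a) & unclass(b), n_markers(a))
}

#' @rdname seq_xor
#' @param x a `bitseq`.
#' @export
seq_popcount <- function(x) .popcount_raw(unclass(x))

#' Haplotype pseudometrics
#'
#' `hamming_distance` counts the markers at which two haplotypes differ
#' (popcount of their GF(2) sum). `left_distance` is 0 when the first
#' marker agrees and 1 otherwise. Neither is required to separate distinct
#' haplotypes, hence "pseudometric": `left_distance` in particular is blind
#' to every marker but the first, which is exactly what makes trees built
#' under it (with an infinite bias) consistent for that marker.
#'
#' @param a,b `bitseq` objects with equal marker counts.
#' @return A nonnegative integer.
#' @export
hamming_distance <- function(a, b) {
  check_same_s(a, b)
  .popcount_raw(xor(unclass(a), unclass(b)))
}

#' @rdname hamming_distance
#' @export
left_distance <- function(a, b) {
  check_same_s(a, b)
  if (n_markers(a) < 1L) stop("left_distance needs at least one marker")
  as.integer((as.integer(unclass(a)[1L]) %% 2L) != (as.integer(unclass(b)[1L]) %% 2L))
}

#' Biased haplotype distance
#'
#' Scales a base pseudometric by the bias `c0`: `d_ab = c0 * d(a, b)`, with
#' the conventions `d = 0` always yielding 0 (so `0 * Inf = 0`) and
#' `c0 = Inf, d > 0` yielding `Inf`. `c0 = Inf` with the left-marker
#' distance reproduces hard aggregation by first-marker allele: the pairing
#' weight is 1 for equal first markers and 0 otherwise.
#'
#' @param m a [metric()].
#' @param a,b `bitseq` objects.
#' @return Extended nonnegative real.
#' @export
biased_distance <- function(m, a, b) {
  d <- m$fun(a, b)
  if (d == 0) return(0)
  if (m$c0 == 0) return(0)
  m$c0 * d
}

#' Metric specification for tree building
#'
#' @param kind one of `"hamming"`, `"left"`, `"custom"`.
#' @param c0 bias in `[0, Inf]` applied multiplicatively to distances.
#' @param fun for `kind = "custom"`, a function `(a, b) -> distance`.
#' @return An object of class `arg_metric`.
#' @export
metric <- function(kind = c("hamming", "left", "custom"), c0 = 1, fun = NULL) {
  kind <- match.arg(kind)
  if (!(is.numeric(c0) && length(c0) == 1L && !is.na(c0) && c0 >= 0))
    stop("c0 must be a single value in [0, Inf]")
  fun <- switch(kind,
    hamming = hamming_distance,
    left = left_distance,
    custom = {
      if (!is.function(fun)) stop("kind = 'custom' requires fun")
      fun
    })
  structure(list(kind = kind, c0 = c0, fun = fun), class = "arg_metric")
}

#' Masked mutation detection on an edge
#'
#' `(parent XOR child) AND mask`: the set bits are the markers, restricted
#' to the masked window, that mutate on the edge between the two
#' haplotypes.
#'
#' @param parent,child,mask `bitseq` objects with equal marker counts.
#' @return A `bitseq`.
#' @export
masked_xor <- function(parent, child, mask) {
  check_same_s(parent, child)
  check_same_s(parent, mask)
  new_bitseq_raw(xor(unclass(parent), unclass(child)) & unclass(mask),
                 n_markers(parent))
}

#' Interval mask over marker positions
#'
#' Builds the GF(2) mask whose bit `k` is set iff `positions[k]` lies in the
#' interval set `iv` (half-open intervals). An empty interval set yields the
#' zero mask.
#'
#' @param positions sorted marker positions (bp).
#' @param iv an interval set, see [iset()].
#' @return A `bitseq` over `length(positions)` markers.
#' @export
interval_mask <- function(positions, iv) {
  bitseq(iset_contains(iv, positions))
}
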