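#' Marker index / position conversion
#'
#' `idx_to_pos` returns the physical position (bp) of a 1-based marker
#' index. `pos_to_idx` is its pseudoinverse,
#' `sup{ i in 1..s : idx_to_pos(i) <= p }`, i.e. the index of the rightmost
#' marker at or left of `p`; positions strictly left of the first marker
#' return the sentinel `0`. It is implemented as interpolation-sequential
#' search: a first-order least-squares fit of index on position, computed
#' once per sample, provides the initial guess which is then corrected by a
#' local scan. The fit is valid because the position vector never changes
#' over a genealogy's lifetime.
#'
#' @param sample an [arg_sample()].
#' @param i 1-based marker indices.
#' @param p positions in `[0, seq_length)`.
#' @return Positions, or marker indices (0 allowed as sentinel).
#' @export
idx_to_pos <- function(sample, i) {
  s <- sample$s
  if (any(i < 1L | i > s)) stop("marker index out of range 1..", s)
  sample$positions[i]
}

#' @rdname idx_to_pos
#' @export
pos_to_idx <- function(sample, p) {
  if (any(p < 0 | p >= sample$seq_length))
    stop("position outside [0, seq_length)")
  pos <- sample$positions
  s <- sample$s
  fit <- sample$posfit
  out <- integer(length(p))
  for (j in seq_along(p)) {
    pj <- p[j]
    g <- as.integer(round(fit[1L] + fit[2L] * pj))
    if (g < 0L) g <- 0L
    if (g > s) g <- s
    # sequential correction to the exact sup
    while (g > 0L && pos[g] > pj) g <- g - 1L
    while (g < s && pos[g + 1L] <= pj) g <- g + 1L
    out[j] <- g
  }
  out
}

# least-squares fit of index ~ position, done once at sample construction
posfit_coefficients <- function(positions) {
  s <- length(positions)
  if (s == 1L) return(c(1, 0))
  mp <- mean(positions)
  mi <- mean(seq_len(s))
  vp <- sum((positions - mp)^2)
  if (vp == 0) return(c(mi, 0))
  b <- sum((positions - mp) * (seq_len(s) - mi)) / vp
  c(mi - b * mp, b)
}
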