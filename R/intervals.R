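#' Finite unions of half-open genomic intervals
#'
#' Ancestral material and recombination masks are finite unions of disjoint
#' half-open intervals `[a, b)` on the nonnegative real line (bp
#' coordinates, 0-based). The canonical form is sorted, strictly disjoint
#' (no overlap and no shared endpoint: touching intervals are merged) and
#' free of empty members. Endpoint arithmetic is exact; no tolerance
#' merging is ever applied.
#'
#' An interval set is stored as a flat numeric vector
#' `c(a1, b1, a2, b2, ...)` of class `iset`.
#'
#' @param starts,ends interval endpoints; recycled pairwise.
#' @return An `iset` in canonical form.
#' @examples
#' iset(c(0, 7), c(5, 10))
#' iset_closure(iset(c(0, 7), c(5, 10)))
#' @export
iset <- function(starts = numeric(0), ends = numeric(0)) {
  if (length(starts) != length(ends)) stop("starts and ends differ in length")
  if (any(is.na(starts)) || any(is.na(ends))) stop("NA interval endpoint")
  if (any(starts < 0)) stop("negative interval endpoint")
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(structure(numeric(0), class = "iset"))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # sweep-merge overlapping or touching intervals
  ra <- starts[1L]; rb <- ends[1L]
  oa <- numeric(0); ob <- numeric(0)
  if (length(starts) > 1L) {
    for (i in 2L:length(starts)) {
      if (starts[i] <= rb) {
        rb <- max(rb, ends[i])
      } else {
        oa <- c(oa, ra); ob <- c(ob, rb)
        ra <- starts[i]; rb <- ends[i]
      }
    }
  }
  oa <- c(oa, ra); ob <- c(ob, rb)
  structure(as.numeric(rbind(oa, ob)), class = "iset")
}

iset_raw <- function(v) structure(as.numeric(v), class = "iset")

#' @rdname iset
#' @export
iset_empty <- function() structure(numeric(0), class = "iset")

#' @export
print.iset <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<iset> empty\n")
  } else {
    a <- x[c(TRUE, FALSE)]; b <- x[c(FALSE, TRUE)]
    cat("<iset> ", paste0("[", format(a, trim = TRUE), ", ",
                          format(b, trim = TRUE), ")", collapse = " U "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname iset
#' @param x an object.
#' @export
is_iset <- function(x) inherits(x, "iset")

iset_check <- function(x) {
  v <- unclass(x)
  nv <- length(v)
  if (nv %% 2L != 0L) stop("non-canonical interval set: odd length")
  if (nv == 0L) return(invisible(x))
  if (anyNA(v) || is.unsorted(v) ||
      any(v[seq.int(1L, nv, 2L)] >= v[seq.int(2L, nv, 2L)]))
    stop("non-canonical interval set")
  invisible(x)
}

iset_starts <- function(x) {
  v <- unclass(x)
  if (length(v) == 0L) return(numeric(0))
  v[seq(1L, length(v), by = 2L)]
}
iset_ends <- function(x) {
  v <- unclass(x)
  if (length(v) == 0L) return(numeric(0))
  v[seq(2L, length(v), by = 2L)]
}

#' Interval-set algebra
#'
#' Union, intersection, complement within `[0, Inf)`, and closure (the
#' single interval from the leftmost to the rightmost endpoint). All
#' results are canonical; inputs must be canonical `iset` objects.
#'
#' @param a,b `iset` objects.
#' @return An `iset`.
#' @export
iset_union <- function(a, b) {
  iset_check(a); iset_check(b)
  iset(c(iset_starts(a), iset_starts(b)), c(iset_ends(a), iset_ends(b)))
}

#' @rdname iset_union
#' @export
iset_intersect <- function(a, b) {
  iset_check(a); iset_check(b)
  if (length(a) == 0L || length(b) == 0L) return(iset_empty())
  as_ <- iset_starts(a); ae <- iset_ends(a)
  bs <- iset_starts(b); be <- iset_ends(b)
  oa <- numeric(0); ob <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= length(as_) && j <= length(bs)) {
    lo <- max(as_[i], bs[j]); hi <- min(ae[i], be[j])
    if (lo < hi) { oa <- c(oa, lo); ob <- c(ob, hi) }
    if (ae[i] < be[j]) i <- i + 1L else j <- j + 1L
  }
  iset(oa, ob)
}

#' @rdname iset_union
#' @export
iset_complement <- function(a) {
  iset_check(a)
  if (length(a) == 0L) return(iset_raw(c(0, Inf)))
  as_ <- iset_starts(a); ae <- iset_ends(a)
  starts <- c(0, ae)
  ends <- c(as_, Inf)
  iset(starts, ends)
}

#' @rdname iset_union
#' @export
iset_diff <- function(a, b) iset_intersect(a, iset_complement(b))

#' @rdname iset_union
#' @export
iset_closure <- function(a) {
  iset_check(a)
  if (length(a) == 0L) return(iset_empty())
  iset_raw(c(unclass(a)[1L], unclass(a)[length(unclass(a))]))
}

#' @rdname iset_union
#' @param p numeric vector of positions.
#' @export
iset_contains <- function(a, p) {
  v <- unclass(a)
  if (length(v) == 0L) return(rep(FALSE, length(p)))
  findInterval(p, v, rightmost.closed = FALSE) %% 2L == 1L
}

#' @rdname iset_union
#' @export
iset_length <- function(a) {
  if (length(unclass(a)) == 0L) return(0)
  sum(iset_ends(a) - iset_starts(a))
}

#' @rdname iset_union
#' @export
iset_is_empty <- function(a) length(unclass(a)) == 0L

# convenience: single half-open interval
iv <- function(a, b) iset(a, b)
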