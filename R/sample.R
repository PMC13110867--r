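#' Haplotype sample
#'
#' Bundles `n` phased, polarized biallelic haplotypes with their marker
#' positions and the demographic parameters governing inference. The
#' global mutation rate is `mu = 4 * Ne * mu_prime * seq_length`, with `Ne`
#' the diploid effective population size and `mu_prime` the per-locus
#' (per-bp, per-generation) diploid mutation rate. Positions are 0-based
#' bp in `[0, seq_length)` and strictly increasing; the wild (ancestral)
#' allele is 0 and the derived allele 1.
#'
#' @param haplotypes an `n x s` 0/1 matrix (rows = haplotypes) or a list of
#'   [bitseq()] objects with equal marker counts.
#' @param positions strictly increasing marker positions (bp, may be
#'   fractional).
#' @param seq_length total sequence length `l` in bp.
#' @param Ne diploid effective population size.
#' @param mu_prime per-locus diploid mutation rate.
#' @param names optional haplotype names.
#' @return An object of class `arg_sample`.
#' @export
arg_sample <- function(haplotypes, positions, seq_length, Ne = 1e4,
                       mu_prime = 1e-8, names = NULL) {
  if (is.matrix(haplotypes)) {
    haplotypes <- lapply(seq_len(nrow(haplotypes)),
                         function(i) bitseq(haplotypes[i, ]))
  }
  if (!is.list(haplotypes) || length(haplotypes) < 1L)
    stop("haplotypes must be a matrix or a non-empty list of bitseq")
  s <- n_markers(haplotypes[[1L]])
  if (!all(vapply(haplotypes, n_markers, integer(1)) == s))
    stop("all haplotypes must have the same number of markers")
  positions <- as.numeric(positions)
  if (length(positions) != s)
    stop("positions length (", length(positions), ") != marker count (", s, ")")
  if (s > 0L && (any(diff(positions) <= 0) || positions[1L] < 0 ||
                 positions[s] >= seq_length))
    stop("positions must be strictly increasing within [0, seq_length)")
  if (!(Ne > 0) || !(mu_prime > 0) || !(seq_length > 0))
    stop("Ne, mu_prime and seq_length must be positive")
  structure(list(
    haplotypes = haplotypes,
    n = length(haplotypes),
    s = s,
    positions = positions,
    seq_length = as.numeric(seq_length),
    Ne = Ne,
    mu_prime = mu_prime,
    mu = 4 * Ne * mu_prime * seq_length,
    names = names %||% paste0("h", seq_along(haplotypes)),
    posfit = posfit_coefficients(positions)
  ), class = "arg_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.arg_sample <- function(x, ...) {
  cat("<arg_sample> ", x$n, " haplotypes x ", x$s, " markers over ",
      format(x$seq_length, big.mark = ","), " bp\n", sep = "")
  cat("  Ne = ", format(x$Ne, big.mark = ","), ", mu' = ", x$mu_prime,
      ", global mu = ", signif(x$mu, 5), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.arg_sample <- function(x, ...) {
  m <- do.call(rbind, lapply(x$haplotypes, as_bits))
  rownames(m) <- x$names
  m
}

#' @export
summary.arg_sample <- function(object, ...) {
  m <- as.matrix(object)
  freq <- colMeans(m)
  out <- list(n = object$n, s = object$s, seq_length = object$seq_length,
              derived_freq = freq,
              singletons = sum(colSums(m) == 1L),
              mu = object$mu)
  class(out) <- "summary.arg_sample"
  out
}

#' @export
print.summary.arg_sample <- function(x, ...) {
  cat("Haplotype sample: n =", x$n, ", s =", x$s, "markers, l =",
      format(x$seq_length, big.mark = ","), "bp\n")
  cat("Global mutation rate mu =", signif(x$mu, 5), "\n")
  cat("Singleton markers:", x$singletons, "\n")
  cat("Mean derived allele frequency:", signif(mean(x$derived_freq), 4), "\n")
  invisible(x)
}

#' Read a sample from a whitespace-delimited text matrix
#'
#' Plain-text fixture format: a header line `# positions: p1 p2 ...` and
#' `# seq_length: l`, then one row of 0/1 characters per haplotype.
#' Used for small bundled datasets.
#'
#' @param path file path.
#' @param Ne,mu_prime demographic parameters passed to [arg_sample()].
#' @return An [arg_sample()].
#' @export
read_sample_text <- function(path, Ne = 1e4, mu_prime = 1e-8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^#", lines, value = TRUE)
  pos_line <- sub("^#\\s*positions:\\s*", "", grep("^#\\s*positions:", hdr, value = TRUE))
  len_line <- sub("^#\\s*seq_length:\\s*", "", grep("^#\\s*seq_length:", hdr, value = TRUE))
  if (length(pos_line) != 1L || length(len_line) != 1L)
    stop("text sample needs '# positions:' and '# seq_length:' headers")
  positions <- as.numeric(strsplit(trimws(pos_line), "\\s+")[[1L]])
  seq_length <- as.numeric(len_line)
  rows <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(rows, function(r) {
    as.integer(strsplit(gsub("\\s", "", r), "")[[1L]])
  }))
  arg_sample(m, positions, seq_length, Ne = Ne, mu_prime = mu_prime)
}

#' @rdname read_sample_text
#' @param sample an [arg_sample()].
#' @export
write_sample_text <- function(sample, path) {
  m <- as.matrix(sample)
  lines <- c(
    paste("# positions:", paste(format(sample$positions, digits = 17, trim = TRUE,
                                       scientific = FALSE), collapse = " ")),
    paste("# seq_length:", format(sample$seq_length, digits = 17, scientific = FALSE)),
    apply(m, 1L, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
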