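#' Read a phased VCF into a haplotype sample
#'
#' Accepts biallelic, fully phased records with the ancestral allele
#' equal to REF (the package's polarization convention): each diploid
#' sample contributes two haploid leaf sequences. Records that are not
#' biallelic SNVs are rejected with counts reported in the error;
#' unphased or missing genotypes name the offending record. POS is
#' 1-based in the file and converted to the package's 0-based
#' coordinates.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param seq_length total sequence length; defaults to the contig length
#'   declared in the header, or `max(POS) + 1` when absent.
#' @param Ne,mu_prime demographic parameters for [arg_sample()].
#' @return An [arg_sample()] with `2 * n_samples` haplotypes.
#' @export
read_vcf <- function(path, seq_length = NULL, Ne = 1e4, mu_prime = 1e-8) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bad <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L | alt == "."
  if (any(bad))
    stop(sum(bad), " record(s) are not biallelic SNVs (first at POS ",
         fix[which(bad)[1L], "POS"], "); only biallelic sites are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  unph <- matrix(grepl("/", gt), nrow = nrow(gt), dimnames = dimnames(gt))
  if (any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1L, ]
    stop("unphased genotype at record POS ", fix[w[1L], "POS"],
         ", sample ", colnames(gt)[w[2L]])
  }
  miss <- matrix(is.na(gt) | grepl("\\.", gt), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  if (any(miss)) {
    w <- which(miss, arr.ind = TRUE)[1L, ]
    stop("missing genotype at record POS ", fix[w[1L], "POS"],
         "; missing data are not supported")
  }
  halves <- strsplit(gt, "|", fixed = TRUE)
  ploidy <- unique(lengths(halves))
  if (length(ploidy) != 1L)
    stop("inconsistent ploidy across genotypes")
  s <- nrow(gt); nsam <- ncol(gt)
  haps <- matrix(0L, nrow = nsam * ploidy, ncol = s)
  for (j in seq_len(nsam)) for (k in seq_len(s)) {
    al <- as.integer(halves[[k + (j - 1L) * s]])
    haps[(j - 1L) * ploidy + seq_len(ploidy), k] <- al
  }
  pos <- as.numeric(fix[, "POS"]) - 1
  if (is.null(seq_length)) {
    meta <- v@meta
    m <- regmatches(meta, regexpr("length=[0-9]+", meta))
    seq_length <- if (length(m) > 0L) as.numeric(sub("length=", "", m[1L]))
    else max(pos) + 1
  }
  nm <- paste0(rep(colnames(gt), each = ploidy), "_", seq_len(ploidy))
  arg_sample(haps, pos, seq_length, Ne = Ne, mu_prime = mu_prime, names = nm)
}

#' Write a sample as a minimal phased VCF
#'
#' Pairs consecutive haplotypes into diploid phased genotypes (REF = the
#' ancestral allele, encoded A/T). Positions must be integer-valued; the
#' file is uncompressed text. Intended for round-trip fixtures, not as a
#' general-purpose VCF writer.
#'
#' @param sample an [arg_sample()] with an even number of haplotypes.
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path, chrom = "1") {
  if (sample$n %% 2L != 0L)
    stop("write_vcf pairs haplotypes into diploids: n must be even")
  pos <- sample$positions
  if (any(pos != floor(pos)))
    stop("write_vcf requires integer-valued positions")
  m <- as.matrix(sample)
  nd <- sample$n %/% 2L
  snames <- paste0("s", seq_len(nd))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom,
                   as.integer(sample$seq_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", snames), collapse = "\t"))
  rows <- vapply(seq_len(sample$s), function(k) {
    gts <- vapply(seq_len(nd), function(j) {
      paste0(m[2L * j - 1L, k], "|", m[2L * j, k])
    }, character(1))
    paste(c(chrom, as.integer(pos[k]) + 1L, ".", "A", "T", ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
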