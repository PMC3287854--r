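#' Default minor-allele-frequency spectrum
#'
#' Bin-probability table for non-private variants, chosen so that together
#' with the default private fraction of 0.384 the generated spectrum has
#' roughly 74% of variants at MAF <= 0.01, 12.8% at MAF >= 0.05, and a median
#' MAF near 0.002 (about three minor-allele copies in a sample of 697
#' diploids) -- a spectrum heavily dominated by rare variation, as produced by
#' permissive exome variant calling.
#'
#' @return Data frame with columns `lower`, `upper` (half-open MAF bin
#'   `(lower, upper]`) and `prob` (bin probability, summing to 1 over
#'   non-private variants).
#' @export
default_maf_spectrum <- function() {
  data.frame(
    lower = c(0,     0.0025, 0.005, 0.01, 0.02,  0.05, 0.10, 0.25),
    upper = c(0.0025, 0.005, 0.01,  0.02, 0.05,  0.10, 0.25, 0.50),
    prob  = c(0.250,  0.180, 0.148, 0.100, 0.114, 0.100, 0.080, 0.028)
  )
}

#' Sample target minor allele frequencies from a spectrum
#'
#' Each variant is private (exactly one minor-allele copy in the panel, MAF
#' `1/(2 n)`) with probability `private_fraction`; otherwise a bin is drawn
#' from `spectrum` and a copy count is drawn uniformly among the achievable
#' counts in that bin, so realized MAFs are exact copy-number fractions.
#'
#' @param n_snps Number of variants to draw.
#' @param n_individuals Diploid panel size the MAFs refer to.
#' @param spectrum Bin-probability table as from [default_maf_spectrum()].
#' @param private_fraction Probability a variant is private (default 0.384).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_snps` of target MAFs in `(0, 0.5]`.
#' @examples
#' mafs <- sample_maf_spectrum(1000, 697, seed = 1)
#' mean(mafs <= 0.01)   # about 0.74
#' @export
sample_maf_spectrum <- function(n_snps, n_individuals,
                                spectrum = default_maf_spectrum(),
                                private_fraction = 0.384, seed = 1L) {
  stopifnot(n_individuals > 0)
  if (any(spectrum$prob < 0)) stop("spectrum bin probabilities must be >= 0")
  if (abs(sum(spectrum$prob) - 1) > 1e-8)
    stop("spectrum bin probabilities must sum to 1")
  if (private_fraction < 0 || private_fraction > 1)
    stop("private_fraction must lie in [0, 1]")
  if (n_snps == 0L) return(numeric(0))
  two_n <- 2L * n_individuals
  set.seed(seed)
  private <- stats::runif(n_snps) < private_fraction
  maf <- numeric(n_snps)
  maf[private] <- 1 / two_n
  n_rest <- sum(!private)
  if (n_rest > 0L) {
    bin <- sample.int(nrow(spectrum), n_rest, replace = TRUE,
                      prob = spectrum$prob)
    # achievable copy counts in (lower, upper], never fewer than 2 copies
    k_lo <- pmax(floor(spectrum$lower[bin] * two_n) + 1L, 2L)
    k_hi <- pmax(floor(spectrum$upper[bin] * two_n), k_lo)
    k <- k_lo + floor(stats::runif(n_rest) * (k_hi - k_lo + 1L))
    maf[!private] <- pmin(k / two_n, 0.5)
  }
  maf
}

#' Observed minor allele frequency of each marker
#'
#' Counts minor-allele copies per marker and divides by twice the number of
#' individuals, folding so the result never exceeds 0.5. A single
#' heterozygote among 697 individuals gives 1/1394 = 0.000717 (0.07%).
#'
#' @param g A `genotype_matrix` (or a bare individuals-by-markers dosage
#'   matrix with values 0/1/2).
#' @return Numeric vector of per-marker MAFs in `[0, 0.5]`.
#' @export
compute_maf <- function(g) {
  dosage <- if (inherits(g, "genotype_matrix")) g$dosage else g
  n <- nrow(dosage)
  stopifnot(n > 0)
  f <- colSums(dosage) / (2 * n)
  unname(pmin(f, 1 - f))
}

#' Binned summary of a MAF spectrum
#'
#' Bins follow the uneven convention used for rare-variant spectra: 0.5%
#' intervals below MAF 0.01, 1% intervals from 0.01 to 0.05, and 5% intervals
#' above. Bins are half-open, closed on the lower edge. The median is taken
#' over markers with nonzero MAF.
#'
#' @param mafs Numeric vector of MAFs in `[0, 0.5]`.
#' @return List with `bins` (data frame: `lower`, `upper`, `count`) and
#'   `median_maf` (median over nonzero MAFs; `NA` if none).
#' @export
spectrum_summary <- function(mafs) {
  breaks <- c(0, 0.005, 0.01, 2:5 / 100, seq(10L, 50L, by = 5L) / 100)
  nz <- mafs[mafs > 0]
  # lower-closed half-open bins [l, u)
  idx <- findInterval(nz, breaks, left.open = FALSE, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  list(
    bins = data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
                      count = counts),
    median_maf = if (length(nz)) stats::median(nz) else NA_real_
  )
}
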