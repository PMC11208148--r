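#' @include bulk-rates.R
NULL

#' Expected breadth of coverage at a given mean coverage
#'
#' Under approximately random read placement, the fraction of a genome covered
#' by at least one read at mean coverage c is well described by
#' \eqn{1 - e^{-0.883 c}}; a genome truly present in a metagenome should show
#' an observed breadth close to this curve, while spurious recruitment of
#' conserved regions gives much lower breadth at the same coverage.
#'
#' @param coverage mean fold-coverage, >= 0.
#' @param k decay constant (default 0.883).
#' @return expected breadth in [0, 1).
#' @examples
#' expectedBreadth(1)    # 0.5864
#' @export
expectedBreadth <- function(coverage, k = 0.883) {
    if (any(!is.finite(coverage)) || any(coverage < 0))
        stop("coverage must be finite and >= 0")
    -expm1(-k * coverage)
}

#' Call genome presence from coverage and breadth
#'
#' A genome is called present when its observed breadth reaches at least a
#' fraction \code{theta} of the breadth expected at its mean coverage (and the
#' coverage is non-zero).
#'
#' @param meanCoverage mean fold-coverage.
#' @param observedBreadth fraction of genome covered >= 1x, in [0, 1].
#' @param theta ratio threshold in (0, 1], default 0.95.
#' @return logical vector of presence calls.
#' @examples
#' detectPresence(1, 0.57)   # TRUE: 0.57 >= 0.95 * 0.586
#' detectPresence(1, 0.30)   # FALSE
#' @export
detectPresence <- function(meanCoverage, observedBreadth, theta = 0.95) {
    if (length(theta) != 1L || theta <= 0 || theta > 1)
        stop("theta must be a single value in (0, 1]")
    if (any(observedBreadth < 0) || any(observedBreadth > 1))
        stop("observed breadth must lie in [0, 1]")
    meanCoverage > 0 &
        observedBreadth >= theta * expectedBreadth(meanCoverage)
}

#' Coverage summary from a per-position depth profile
#'
#' @param depths non-empty vector of per-position read depths.
#' @return list with \code{mean_coverage} and \code{observed_breadth}
#'   (fraction of positions with depth >= 1).
#' @examples
#' breadthFromDepth(c(0, 0, 2, 3))   # coverage 1.25, breadth 0.5
#' @export
breadthFromDepth <- function(depths) {
    if (length(depths) == 0L)
        stop("depth profile must be non-empty")
    if (any(!is.finite(depths)) || any(depths < 0))
        stop("depths must be finite and >= 0")
    list(mean_coverage = mean(depths),
         observed_breadth = mean(depths >= 1))
}

#' Transform qPCR nifH copy numbers for mapping
#'
#' Adds a pseudocount of 1 to the copy numbers, log10-transforms them and
#' flags all samples with a raw count of zero as filtered (their transformed
#' value is set to NA; filtering before or after the transform is equivalent
#' since log10(0 + 1) = 0).
#'
#' @param counts non-negative nifH copy numbers, copies per litre.
#' @param sampleId optional sample identifiers.
#' @return data.frame with \code{sample_id}, \code{nifh_copies},
#'   \code{filtered} and \code{log_value}.
#' @examples
#' qpcrTransform(c(0, 9, 99))
#' @export
qpcrTransform <- function(counts, sampleId = NULL) {
    if (any(!is.finite(counts)) || any(counts < 0))
        stop("qPCR counts must be finite and >= 0")
    if (is.null(sampleId))
        sampleId <- paste0("S", seq_along(counts))
    filtered <- counts == 0
    data.frame(sample_id = sampleId, nifh_copies = counts,
               filtered = filtered,
               log_value = ifelse(filtered, NA_real_, log10(counts + 1)),
               stringsAsFactors = FALSE)
}

#' Simulate a uniform read-placement depth profile
#'
#' Lander--Waterman-style sanity simulator: n = coverage * G / L reads of
#' length L are placed with uniformly random start positions on a linear
#' genome of length G, and the per-position depth profile is returned. Used
#' to check that observed breadth behaves like \code{\link{expectedBreadth}}.
#'
#' @param genomeLength genome length in bp.
#' @param readLength read length in bp.
#' @param coverage target mean fold-coverage.
#' @return integer vector of per-position depths, length \code{genomeLength}.
#' @export
simulateReadDepth <- function(genomeLength = 10000, readLength = 100,
                              coverage = 1) {
    if (genomeLength < readLength)
        stop("genome must be at least one read long")
    nReads <- round(coverage * genomeLength / readLength)
    depth <- integer(genomeLength)
    if (nReads == 0L) return(depth)
    starts <- sample.int(genomeLength - readLength + 1L, nReads,
                         replace = TRUE)
    # difference-array accumulation of read intervals
    inc <- tabulate(starts, nbins = genomeLength)
    dec <- tabulate(starts + readLength, nbins = genomeLength + 1L)
    cumsum(inc - dec[seq_len(genomeLength)])
}
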