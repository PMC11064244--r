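#' Construct a gene universe
#'
#' The pool random target spaces are drawn from. In published analyses this
#' is the full set of curated drug target genes (order 3000 symbols); the
#' pipeline defaults to the union of all genes in the drug-target table when
#' no explicit universe file is given.
#'
#' @param genes character vector of gene symbols (normalized, deduplicated)
#' @param sourceTag free-text provenance label
#' @return a \linkS4class{GeneUniverse}
#' @export
geneUniverse <- function(genes, sourceTag = "user") {
  new("GeneUniverse", genes = sort(unique(normalizeGeneSymbols(genes))),
      sourceTag = sourceTag)
}

#' Resample a null distribution of supports
#'
#' Draws \code{nDraws} independent random target spaces, each a uniform
#' sample of \code{k} distinct genes from the universe (without replacement
#' within a draw), and computes the support of each random space — in the
#' drug-space, i.e. denominator, role — against the fixed formula space:
#' |R intersect Y| / k. Summarises the draws by their mean and population
#' variance (divide by \code{nDraws}). Fully reproducible from \code{seed}
#' (R's Mersenne-Twister generator, restored on exit).
#'
#' If \code{observed} is supplied, the add-one upper-tail permutation p of
#' the observed support against the draws is stored as well.
#'
#' @param formulaSpace the fixed \linkS4class{TargetSpace} (numerator side)
#' @param universe a \linkS4class{GeneUniverse}
#' @param k cardinality of each random space, 1 <= k <= |universe|
#' @param nDraws number of draws (default 1000)
#' @param seed integer seed
#' @param observed optional observed support to calibrate (default NA)
#' @return a \linkS4class{NullDistribution}
#' @export
sampleNull <- function(formulaSpace, universe, k, nDraws = 1000L,
                       seed = 1L, observed = NA_real_) {
  stopifnot(is(formulaSpace, "TargetSpace"), is(universe, "GeneUniverse"))
  k <- as.integer(k)
  nDraws <- as.integer(nDraws)
  N <- length(universe@genes)
  if (k < 1L) stop("k must be >= 1")
  if (k > N) stop(sprintf("k = %d exceeds universe size %d", k, N))
  if (nDraws < 1L) stop("nDraws must be >= 1")

  inY <- universe@genes %in% formulaSpace@genes

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  supports <- vapply(seq_len(nDraws), function(i) {
    sum(inY[sample.int(N, k)]) / k
  }, 0)

  mu <- mean(supports)
  new("NullDistribution",
      formulaId = formulaSpace@ownerId,
      k = k, nDraws = nDraws, supports = supports,
      mean = mu, variance = mean((supports - mu)^2),
      observed = as.numeric(observed),
      empiricalP = if (is.na(observed)) NA_real_ else
        (1 + sum(supports >= observed)) / (nDraws + 1),
      seed = as.integer(seed))
}

#' Hypergeometric closed-form moments of the null support
#'
#' If a random space of \code{k} distinct genes is drawn uniformly from a
#' universe of \code{N} genes of which \code{m} lie in the formula space,
#' the overlap count is hypergeometric, so the support (count / k) has
#' \deqn{E[S] = m/N, \quad
#'   Var[S] = \frac{k \, (m/N)(1 - m/N) \, (N-k)/(N-1)}{k^2}.}
#' This is the analytic check for the resampled null: the empirical mean and
#' variance of \code{\link{sampleNull}} converge to these values.
#'
#' @param N universe size, >= 1
#' @param m number of universe genes inside the formula space, 0 <= m <= N
#' @param k draw size, 1 <= k <= N
#' @return list with \code{expectedSupport} and \code{supportVariance}
#' @examples
#' hypergeometricMoments(3000, 300, 84)$expectedSupport  # 0.1
#' @export
hypergeometricMoments <- function(N, m, k) {
  if (N < 1L) stop("N must be >= 1")
  if (k < 1L || k > N) stop("k must satisfy 1 <= k <= N")
  if (m < 0L || m > N) stop("m must satisfy 0 <= m <= N")
  p <- m / N
  fpc <- if (N == 1L) 0 else (N - k) / (N - 1)
  list(expectedSupport = p,
       supportVariance = (k * p * (1 - p) * fpc) / k^2)
}

#' Add-one empirical p-value of an observed support
#'
#' Upper-tail permutation p with the add-one correction:
#' \code{(1 + #\{draws >= observed\}) / (nDraws + 1)}. Never exactly zero, so
#' an observed support above every draw yields \code{1/(nDraws + 1)} and an
#' observed support of 0 yields 1.
#'
#' @param observed observed support in [0, 1]
#' @param null a \linkS4class{NullDistribution}
#' @return the empirical p-value in (0, 1]
#' @export
empiricalP <- function(observed, null) {
  stopifnot(is(null, "NullDistribution"))
  if (is.na(observed) || observed < 0 || observed > 1)
    stop("observed support must lie in [0, 1]")
  (1 + sum(null@supports >= observed)) / (null@nDraws + 1)
}
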