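#' Composition + coverage features for contig binning
#'
#' Per contig: canonical tetranucleotide frequencies (a 4-mer and its
#' reverse complement are pooled, giving 136 classes), pseudocount-
#' smoothed, normalised to sum to 1 and log-transformed; plus
#' `log(depth + 1)` for every coverage sample. All dimensions are then
#' standardised (zero mean, unit variance) and each block (composition,
#' coverage) is scaled by the square root of its dimension count so the
#' two information sources carry equal total variance — otherwise the 136
#' composition dimensions would drown the coverage signal whenever there
#' are few samples. A contig and its reverse complement get identical
#' composition features.
#'
#' @param contigs a [ContigSet-class], prepared (all >= the binning
#'   length floor) and with coverage computed for at least one sample.
#' @param pseudocount smoothing count added to every 4-mer class.
#' @return numeric feature matrix, one row per contig; the pre-log
#'   frequency matrix is available as attribute `"frequencies"`.
#' @export
contigFeatures <- function(contigs, pseudocount = 1) {
  stopifnot(is(contigs, "ContigSet"))
  if (length(contigs) == 0L) stop("no contigs to featurise", call. = FALSE)
  if (any(Biostrings::width(contigs@sequences) < 4L))
    stop("contigs shorter than 4 bp cannot be featurised", call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(contigs@sequences, 4L)
  canon <- .canonical_4mer_map()
  pooled <- t(rowsum(t(counts), canon))           # contigs x 136
  pooled <- pooled[, sort(colnames(pooled)), drop = FALSE]
  sm <- pooled + pseudocount
  freq <- sm / rowSums(sm)
  comp <- .standardise(log(freq)) / sqrt(ncol(freq))
  out <- comp
  cov <- contigs@coverage
  if (nrow(cov) > 0L && ncol(cov) > 0L) {
    covf <- .standardise(log(cov + 1)) / sqrt(ncol(cov))
    colnames(covf) <- paste0("cov_", seq_len(ncol(covf)))
    out <- cbind(comp, covf)
  }
  rownames(out) <- names(contigs@sequences)
  attr(out, "frequencies") <- freq
  attr(out, "block_cols") <- list(
    composition = colnames(comp),
    coverage = setdiff(colnames(out), colnames(comp)))
  out
}

.standardise <- function(m) {
  s <- scale(m)
  s[, attr(s, "scaled:scale") == 0] <- 0  # constant dims carry no signal
  out <- s[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

.canonical_4mer_map <- function() {
  mers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  rc <- .revcomp_chr(mers)
  pmin(mers, rc)
}

#' Bin contigs with a diagonal-covariance Gaussian mixture
#'
#' Features are reduced by PCA to the leading components retaining 90% of
#' the variance, then clustered with a K-component Gaussian mixture
#' (diagonal covariances) fitted by EM from multiple initialisations:
#' `n_init` kmeans-seeded restarts at K, one restart per feature block
#' (composition only, coverage only), and coarser kmeans seedings that
#' leave some of the K components empty. K acts as a component budget
#' (an upper bound): the winning restart is the one with the best BIC,
#' where the parameter count covers only non-empty components, so when
#' the data support fewer groups than K the surplus components stay
#' empty instead of shredding a real cluster. Contigs are hard-assigned
#' to their maximum-responsibility component (ties to the lowest cluster
#' id). Deterministic for a fixed seed and input.
#'
#' @param features matrix from [contigFeatures()].
#' @param K number of clusters.
#' @param seed integer RNG seed.
#' @param n_init number of restarts.
#' @return a [ClusterAssignment-class].
#' @export
fitClusters <- function(features, K, seed = 1L, n_init = 10L) {
  if (is(K, "SpeciesEstimate")) K <- K@K
  K <- .assert_scalar_int(K, "K", 1L)
  seed <- .assert_scalar_int(seed, "seed")
  n <- nrow(features)
  if (n < K)
    stop(sprintf("%d contigs cannot form %d clusters; reduce K", n, K),
         call. = FALSE)

  pca <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  v <- pca$sdev^2
  d <- which(cumsum(v) / sum(v) >= 0.90)[1L]
  d <- max(1L, min(d, n - 1L))
  X <- pca$x[, seq_len(d), drop = FALSE]

  if (K == 1L) {
    z <- matrix(1, n, 1L)
  } else {
    # initial hard labelings: kmeans restarts on the reduced space, one
    # kmeans per feature block (composition-only, coverage-only) so that a
    # partition carried by a low-variance block is still reachable, and
    # coarser kmeans seedings (K' < K) that leave components of the budget
    # empty when the data have less structure than K
    inits <- list()
    for (init in seq_len(n_init)) {
      set.seed(seed + 1009L * init)
      km <- tryCatch(
        stats::kmeans(X, centers = K, nstart = 3L, iter.max = 100L),
        error = function(e) NULL)
      inits[[length(inits) + 1L]] <-
        if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
    }
    blocks <- attr(features, "block_cols")
    for (bl in blocks) {
      if (length(bl) == 0L) next
      sub <- features[, bl, drop = FALSE]
      if (nrow(unique(sub)) < K) next
      set.seed(seed)
      km <- tryCatch(
        stats::kmeans(sub, centers = K, nstart = 5L, iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(km)) inits[[length(inits) + 1L]] <- km$cluster
    }
    for (K2 in setdiff(seq(2L, K - 1L), K)) {
      set.seed(seed + 31L * K2)
      km <- tryCatch(
        stats::kmeans(X, centers = K2, nstart = 3L, iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(km)) inits[[length(inits) + 1L]] <- km$cluster
    }
    # model choice among restarts: BIC with parameters counted over
    # non-empty components only (K is a budget, not a mandate)
    best <- NULL
    d_X <- ncol(X)
    for (lab0 in inits) {
      fit <- .em_diag_gmm(X, K, lab0)
      k_eff <- sum(colSums(fit$z) >= 1)
      p_eff <- k_eff * (2 * d_X) + (k_eff - 1)
      fit$bic <- -2 * fit$loglik + p_eff * log(n)
      if (is.null(best) || fit$bic < best$bic - 1e-9) best <- fit
    }
    z <- best$z
  }
  hard <- max.col(z, ties.method = "first")
  rownames(z) <- rownames(features)
  new("ClusterAssignment", K = K,
      clusters = setNames(as.integer(hard), rownames(features)),
      responsibilities = z, seed = seed)
}

# EM for a K-component diagonal-covariance Gaussian mixture, initialised
# from hard labels. Component variances are floored at 1% of each
# dimension's global variance: an absolute floor lets a component collapse
# onto duplicated points and win the likelihood with a spike.
.em_diag_gmm <- function(X, K, labels, max_iter = 500L, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  floor_d <- pmax(1e-8, 0.01 * apply(X, 2L, stats::var))
  z <- matrix(1e-10, n, K)
  z[cbind(seq_len(n), labels)] <- 1
  z <- z / rowSums(z)
  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- pmax(colSums(z), 1e-10)
    w <- nk / n
    mu <- crossprod(z, X) / nk                       # K x d
    var <- crossprod(z, X^2) / nk - mu^2
    var <- pmax(sweep(var, 2L, floor_d, pmax), 1e-10)
    # log N(x | mu_k, diag(var_k)) for all points and components
    logd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      logd[, k] <- -0.5 * colSums((t(X) - mu[k, ])^2 / var[k, ]) -
        0.5 * sum(log(2 * pi * var[k, ])) + log(w[k])
    }
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    loglik <- sum(lse)
    z <- exp(logd - lse)
    if (is.finite(loglik) && loglik - loglik_old < tol && iter > 1L) break
    loglik_old <- loglik
  }
  list(z = z, loglik = loglik)
}

#' Per-cluster contig counts and bases
#'
#' @param assignment a [ClusterAssignment-class].
#' @param contigs the [ContigSet-class] that was clustered.
#' @return data.frame with one row per cluster id 1..K (empty clusters
#'   reported with count 0).
#' @export
clusterReport <- function(assignment, contigs) {
  stopifnot(is(assignment, "ClusterAssignment"), is(contigs, "ContigSet"))
  cl <- assignment@clusters
  w <- Biostrings::width(contigs@sequences)[match(names(cl),
                                                  names(contigs@sequences))]
  counts <- tabulate(cl, nbins = assignment@K)
  bases <- vapply(seq_len(assignment@K),
                  function(k) sum(as.numeric(w[cl == k])), 0)
  data.frame(cluster = seq_len(assignment@K), n_contigs = counts,
             total_bases = bases)
}
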