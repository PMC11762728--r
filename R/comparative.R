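#' Genus-level thermal preference from band records
#'
#' A genus's temperature preference is the unweighted arithmetic mean of
#' the band-level climate values over all of its occurrence records,
#' pooled across gradients. Genera with no climate-bearing record are
#' excluded and logged on the result's `dropped` attribute.
#'
#' @param records Band record data frame.
#' @param stats_df Band statistics with climate attached
#'   (see [attach_climate()]).
#' @param variable Bioclim variable to average, default `"bio1"`.
#' @return Named numeric vector genus -> mean climate value, with attribute
#'   `dropped` (character vector of excluded genera).
#' @export
genus_temp_pref <- function(records, stats_df, variable = "bio1") {
  variable <- .norm_bio(variable)
  if (!variable %in% names(stats_df))
    stop("band statistics carry no '", variable, "' column; run attach_climate()")
  key_r <- paste(records$gradient_id, records$elevation_m, records$class,
                 sep = "\r")
  key_s <- paste(stats_df$gradient_id, stats_df$elevation_m, stats_df$class,
                 sep = "\r")
  val <- stats_df[[variable]][match(key_r, key_s)]
  ok <- !is.na(val)
  pref <- tapply(val[ok], records$genus[ok], mean)
  out <- stats::setNames(as.numeric(pref), names(pref))
  dropped <- setdiff(unique(records$genus), names(out))
  attr(out, "dropped") <- dropped
  out
}

#' Pagel's lambda transform of the Brownian-motion covariance
#'
#' Among-tip trait covariance under Brownian motion with the shared-path
#' (off-diagonal) entries multiplied by `lambda`; diagonals (tip depths)
#' are unchanged. `lambda = 1` is pure BM, `lambda = 0` a star phylogeny.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param lambda Signal parameter in `[0, 1]`.
#' @return Tip covariance matrix (rows/cols in `tree$tip.label` order),
#'   in units of squared-trait per unit rate (multiply by `sigma2`).
#' @export
lambda_transform <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  V <- ape::vcv.phylo(tree)
  d <- diag(V)
  V <- lambda * V
  diag(V) <- d
  V
}

# Profile log-likelihood of a BM model at fixed covariance structure V:
# root state by GLS, sigma2 by its ML estimate.
.bm_profile_loglik <- function(V, x) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance (zero-length structure?): ",
         conditionMessage(e), call. = FALSE))
  iV_x <- backsolve(ch, forwardsolve(t(ch), x))
  iV_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(iV_x) / sum(iV_1)
  r <- x - mu
  iV_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * iV_r) / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
  list(logLik = ll, sigma2 = s2, root = mu)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the multivariate-normal Brownian-motion likelihood (root state
#' and rate sigma2 concentrated out by GLS) over the lambda transform and
#' maximizes it on `[0, 1]` by bounded one-dimensional search. Significance
#' of the signal is a likelihood-ratio test of `lambda_hat` against
#' `lambda = 0` on one degree of freedom.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param trait Named numeric vector (genus -> trait value); names must
#'   match tree tips. Tips without values are dropped from the tree.
#' @param tol Optimizer tolerance on lambda. Default `1e-6`.
#' @return A `lambda_fit` list: `lambda`, `logLik`, `logLik0` (at
#'   `lambda = 0`), `logLik1` (at `lambda = 1`), `lr_statistic`, `p`,
#'   `sigma2`, `root`, `n`.
#' @export
pagel_lambda <- function(tree, trait, tol = 1e-6) {
  tree <- .match_trait_tree(tree, trait)
  x <- trait[tree$tip.label]
  if (length(x) < 4L) stop("need >= 4 tips with trait values")
  V1 <- ape::vcv.phylo(tree)
  d <- diag(V1)
  obj <- function(lam) {
    V <- lam * V1; diag(V) <- d
    .bm_profile_loglik(V, x)$logLik
  }
  op <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE, tol = tol)
  ll0 <- obj(0); ll1 <- obj(1)
  # the optimum can sit on a boundary the golden-section search skirts
  cand <- rbind(c(op$maximum, op$objective), c(0, ll0), c(1, ll1))
  best <- cand[which.max(cand[, 2L]), ]
  lam <- best[1L]; ll <- best[2L]
  V <- lam * V1; diag(V) <- d
  prof <- .bm_profile_loglik(V, x)
  lr <- max(0, 2 * (ll - ll0))
  out <- list(lambda = lam, logLik = ll, logLik0 = ll0, logLik1 = ll1,
              lr_statistic = lr,
              p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
              sigma2 = prof$sigma2, root = prof$root, n = length(x))
  class(out) <- "lambda_fit"
  out
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (logLik %.3f; vs lambda=0: LR %.2f, p %.3g)\n",
              x$lambda, x$logLik, x$lr_statistic, x$p))
  cat(sprintf("  sigma2 = %.4g, root state = %.3f, n = %d tips\n",
              x$sigma2, x$root, x$n))
  invisible(x)
}

.match_trait_tree <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by genus")
  keep <- intersect(tree$tip.label, names(trait)[is.finite(trait)])
  if (length(keep) == 0L) stop("no tree tips carry trait values")
  if (length(keep) < ape::Ntip(tree)) tree <- ape::keep.tip(tree, keep)
  tree
}

#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood (GLS) estimates of the trait value at every internal
#' node under untransformed Brownian motion: the conditional expectation
#' of the node state given the tips, with the root state estimated by GLS
#' and the rate by its ML estimate. Variances come from the conditional
#' normal, inflated by the uncertainty of the estimated root (universal
#' kriging); 95% CI is the estimate +/- 1.96 sd. Reconstruction on the
#' lambda-rescaled covariance is available via `lambda`.
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param trait Named numeric vector (genus -> trait value).
#' @param lambda Optional Pagel's lambda applied to the covariance before
#'   reconstruction; default 1 (plain BM).
#' @return An `asr_result` data frame: `node` (ape node number), `estimate`,
#'   `variance`, `ci_low`, `ci_high`; attributes `sigma2`, `root_estimate`,
#'   `tree`.
#' @export
asr_bm <- function(tree, trait, lambda = 1) {
  tree <- .match_trait_tree(tree, trait)
  x <- trait[tree$tip.label]
  n <- ape::Ntip(tree); m <- tree$Nnode
  if (n < 2L) stop("need >= 2 tips for ancestral reconstruction")
  root <- n + 1L
  D <- ape::dist.nodes(tree)
  h <- D[root, ]                       # node heights above the root
  M <- ape::mrca(tree, full = TRUE)    # pairwise MRCAs, tips + nodes
  Vfull <- matrix(h[M], nrow = nrow(M))
  if (lambda != 1) {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    dd <- diag(Vfull)
    Vfull <- lambda * Vfull
    diag(Vfull) <- dd
  }
  tipi <- seq_len(n); anci <- (n + 1L):(n + m)
  Vtt <- Vfull[tipi, tipi]
  Vat <- Vfull[anci, tipi, drop = FALSE]

  ch <- tryCatch(chol(Vtt), error = function(e)
    stop("singular phylogenetic covariance (zero-length structure?): ",
         conditionMessage(e), call. = FALSE))
  solve_V <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  one <- rep(1, n)
  iV1 <- solve_V(one)
  denom <- sum(iV1)
  mu <- sum(solve_V(x)) / denom
  r <- x - mu
  s2 <- sum(r * solve_V(r)) / n

  iV_Vta <- solve_V(t(Vat))            # n x m
  est <- as.numeric(mu + crossprod(iV_Vta, r))
  cond <- diag(Vfull)[anci] - colSums(t(Vat) * iV_Vta)
  mean_adj <- (1 - as.numeric(crossprod(iV_Vta, one)))^2 / denom
  v <- s2 * (cond + mean_adj)
  v <- pmax(v, 0)
  out <- data.frame(
    node = anci,
    estimate = est,
    variance = v,
    ci_low = est - 1.96 * sqrt(v),
    ci_high = est + 1.96 * sqrt(v)
  )
  class(out) <- c("asr_result", class(out))
  attr(out, "sigma2") <- s2
  attr(out, "root_estimate") <- mu
  attr(out, "tree") <- tree
  out
}

#' Write an ancestral reconstruction as annotated Newick
#'
#' Node labels carry the point estimates so the reconstruction travels
#' with the topology.
#'
#' @param asr An `asr_result` from [asr_bm()].
#' @param path Output Newick file path.
#' @param digits Significant digits for the node annotations.
#' @return `path`, invisibly.
#' @export
write_asr_newick <- function(asr, path, digits = 6) {
  tree <- attr(asr, "tree")
  tree$node.label <- signif(asr$estimate, digits)
  ape::write.tree(tree, file = path)
  invisible(path)
}
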