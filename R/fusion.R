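#' Seeded k-fold split at case level
#'
#' Randomly partitions case ids into `k` validation folds of near-equal size
#' (within one case), so that every case appears in exactly one validation
#' fold — an 80/20 training-validation split per fold at the default k = 5.
#'
#' @param case_ids Character or integer vector of case identifiers.
#' @param seed Integer seed.
#' @param k Number of folds (default 5).
#' @return An object of class `fold_split`: list with `k` and `assignments`
#'   (named integer vector, case id -> fold id).
#' @export
make_folds <- function(case_ids, seed = 1L, k = 5L) {
  n <- length(case_ids)
  if (k < 2L) stop("k must be >= 2")
  if (n < k)
    stop(sprintf("need at least %d cases for %d folds, got %d", k, k, n))
  set.seed(seed)
  perm <- sample.int(n)
  fold <- rep(seq_len(k), length.out = n)[order(perm)]
  assignments <- stats::setNames(fold, as.character(case_ids))
  structure(list(k = as.integer(k), assignments = assignments),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds over %d cases (validation sizes: %s)\n",
              x$k, length(x$assignments),
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' STAPLE label fusion
#'
#' Simultaneous truth and performance level estimation: an
#' expectation-maximization estimate of a latent true binary segmentation
#' from multiple rater masks. The E-step computes the per-voxel foreground
#' posterior from the current rater sensitivities `p_j` and specificities
#' `q_j` and the foreground prior; the M-step re-estimates each rater's
#' `p_j` and `q_j` against the posterior. Iterates until the largest
#' posterior change falls below `tol` or `max_iter` is reached. Voxels are
#' grouped by their rater-decision pattern, which makes the EM exact and
#' fast for small rater counts.
#'
#' @param masks List of >= 2 binary `volume3d` masks on a common grid.
#' @param prior Foreground prior probability, or `"auto"` for the mean
#'   foreground fraction of the input masks.
#' @param tol Convergence tolerance on the posterior (default 1e-6).
#' @param max_iter Maximum EM iterations (default 100).
#' @param init_p,init_q Initial rater sensitivity/specificity (0.99).
#' @return An object of class `staple_result`: `consensus` (a
#'   `probability_map` of the foreground posterior), `per_rater`
#'   (data.frame with `p` and `q`), `iterations`, `converged`, `degenerate`
#'   and the per-iteration `log_likelihood` trace.
#' @export
staple <- function(masks, prior = "auto", tol = 1e-6, max_iter = 100L,
                   init_p = 0.99, init_q = 0.99) {
  if (length(masks) < 2L) stop("STAPLE needs at least 2 masks")
  for (m in masks[-1]) stop_if_grid_mismatch(masks[[1]], m, "input masks")
  J <- length(masks)
  d <- dim(masks[[1]]$values)
  D <- vapply(masks, function(m) as.numeric(as_binary_values(m) > 0),
              numeric(prod(d)))              # nvox x J
  fracs <- colMeans(D)
  if (all(fracs == 0)) {
    cons <- probability_map(array(0, d), masks[[1]])
    return(structure(list(consensus = cons,
                          per_rater = data.frame(p = rep(NA_real_, J),
                                                 q = rep(NA_real_, J)),
                          iterations = 0L, converged = TRUE,
                          degenerate = TRUE,
                          log_likelihood = numeric(0)),
                     class = "staple_result"))
  }
  g <- if (identical(prior, "auto")) mean(fracs) else as.numeric(prior)
  g <- min(max(g, 1e-12), 1 - 1e-12)
  # group voxels by rater-decision pattern
  pat_id <- as.integer(D %*% 2^(seq_len(J) - 1L)) + 1L
  cnt <- tabulate(pat_id, nbins = 2^J)
  present <- which(cnt > 0)
  Dp <- t(vapply(present, function(pid) {
    as.numeric(bitwAnd(pid - 1L, 2^(seq_len(J) - 1L)) > 0)
  }, numeric(J)))                             # patterns x J
  cp <- cnt[present]
  eps <- 1e-7
  p <- rep(init_p, J); q <- rep(init_q, J)
  W <- rep(g, length(present))
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step on patterns
    la <- log(g) + Dp %*% log(p) + (1 - Dp) %*% log(1 - p)
    lb <- log(1 - g) + Dp %*% log(1 - q) + (1 - Dp) %*% log(q)
    mx <- pmax(la, lb)
    a <- exp(la - mx); b <- exp(lb - mx)
    Wnew <- as.vector(a / (a + b))
    loglik <- c(loglik, sum(cp * (mx + log(a + b))))
    delta <- max(abs(Wnew - W))
    W <- Wnew
    # M-step
    wc <- cp * W
    sW <- sum(wc); sN <- sum(cp * (1 - W))
    p <- as.vector(crossprod(Dp, wc)) / sW
    q <- as.vector(crossprod(1 - Dp, cp * (1 - W))) / sN
    p <- pmin(pmax(p, eps), 1 - eps)
    q <- pmin(pmax(q, eps), 1 - eps)
    if (delta < tol) { converged <- TRUE; break }
  }
  cons_vals <- array(W[match(pat_id, present)], d)
  structure(list(
    consensus = probability_map(cons_vals, masks[[1]],
                                provenance = list(fold = "fused")),
    per_rater = data.frame(p = p, q = q),
    iterations = iter, converged = converged, degenerate = FALSE,
    log_likelihood = loglik), class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d raters, %d iteration(s), converged: %s\n",
              nrow(x$per_rater), x$iterations, x$converged))
  if (!x$degenerate)
    print(round(x$per_rater, 4))
  invisible(x)
}

#' Fuse cross-validation fold outputs with STAPLE
#'
#' Runs [staple()] over the binary masks predicted by the fold sub-models
#' and thresholds the consensus posterior at 0.5.
#'
#' @param fold_masks List of binary `volume3d` masks on a common grid
#'   (one per fold sub-model; 5 in the studied setup).
#' @param ... Passed to [staple()].
#' @return A binary `segmentation_mask`.
#' @export
fuse_folds <- function(fold_masks, ...) {
  res <- staple(fold_masks, ...)
  binarize(res$consensus, 0.5)
}

#' Combine the three variant outputs into the ensemble prediction
#'
#' STAPLE over the three input-configuration variants (Orig, Vess, LDim),
#' consensus thresholded at 0.5 — which degenerates to a majority vote when
#' the estimated rater qualities are symmetric. A plain majority-vote rule
#' is available as a fallback.
#'
#' @param variant_masks List of 3 binary `volume3d` masks on a common grid.
#' @param method `"staple"` (default) or `"majority"`.
#' @param ... Passed to [staple()].
#' @return A binary `segmentation_mask`.
#' @export
ensemble_combine <- function(variant_masks, method = c("staple", "majority"),
                             ...) {
  method <- match.arg(method)
  if (length(variant_masks) != 3L)
    stop("ensemble_combine expects exactly 3 variant masks")
  if (method == "staple") return(fuse_folds(variant_masks, ...))
  for (m in variant_masks[-1])
    stop_if_grid_mismatch(variant_masks[[1]], m, "variant masks")
  votes <- Reduce(`+`, lapply(variant_masks, function(m) m$values))
  segmentation_mask(array(as.numeric(votes >= 2), dim(votes)),
                    variant_masks[[1]])
}
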