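# Mutational signatures: 96-channel catalogs, cosine similarity, exposure
# refitting by non-negative least squares, and de novo extraction by
# non-negative matrix factorization.

#' Build a 96-channel mutation catalog
#'
#' Maps every single-base substitution to its pyrimidine-centered
#' trinucleotide channel and counts occurrences; indels and other non-SNV
#' calls are excluded. Counts are conserved: they sum to the number of
#' contributing SNVs.
#'
#' @param calls a [variant_calls()] data.frame; every SNV must carry a
#'   3-base `context3`.
#' @param scope label stored on the catalog (a sample id, or `"cohort"`).
#' @return named integer vector of length 96 (canonical channel order) with
#'   attribute `scope`.
#' @export
build_catalog <- function(calls, scope = "cohort") {
  snv <- calls[is_snv(calls$ref, calls$alt), , drop = FALSE]
  counts <- setNames(integer(96L), channel_labels())
  if (nrow(snv)) {
    ch <- channel_of(snv$ref, snv$alt, snv$context3)
    tab <- table(factor(ch, levels = channel_labels()))
    counts[] <- as.integer(tab)
  }
  attr(counts, "scope") <- scope
  counts
}

#' Cosine similarity of two 96-channel vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `dot(u, v) / (|u| |v|)`; in `[0, 1]` for non-negative input.
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Refit signature exposures by non-negative least squares
#'
#' Solves `min || W e - c ||_2` subject to `e >= 0`, where `W` is the
#' reference signature matrix and `c` the observed catalog (Lawson-Hanson
#' NNLS via [pracma::lsqnonneg()]). Exposures are reported both raw
#' (mutation-count scale) and normalized to proportions.
#'
#' @param catalog a non-zero 96-channel count vector (see
#'   [build_catalog()]).
#' @param reference a [signature_matrix()].
#' @return list of class `signature_fit`: `exposures` (raw),
#'   `exposures_prop`, `reconstruction` (96-vector `W e`),
#'   `residual_norm`, and `cosine_to_reference` (cosine of the catalog to
#'   each reference signature column).
#' @export
refit_exposures <- function(catalog, reference) {
  reference <- signature_matrix(reference)
  c_vec <- as.numeric(catalog)
  if (length(c_vec) != 96L) stop("catalog must have 96 channels")
  if (all(c_vec == 0)) stop("cannot refit a zero catalog")
  fit <- pracma::lsqnonneg(unclass(reference), c_vec)
  e <- setNames(fit$x, colnames(reference))
  recon <- as.numeric(unclass(reference) %*% e)
  structure(list(
    exposures = e,
    exposures_prop = if (sum(e) > 0) e / sum(e) else e,
    reconstruction = setNames(recon, rownames(reference)),
    residual_norm = sqrt(sum((recon - c_vec)^2)),
    cosine_to_reference = vapply(colnames(reference), function(s) {
      cosine_sim(c_vec, reference[, s])
    }, numeric(1))),
    class = "signature_fit")
}

# one multiplicative-update NMF run on Frobenius loss; V is n x 96
nmf_run <- function(V, k, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  E <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(E) %*% V) / (t(E) %*% E %*% H + eps)
    E <- E * (V %*% t(H)) / (E %*% H %*% t(H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      obj <- sum((V - E %*% H)^2)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
        obj_prev <- obj
        break
      }
      obj_prev <- obj
    }
  }
  list(E = E, H = H, objective = sum((V - E %*% H)^2))
}

#' De novo signature extraction by NMF
#'
#' Factorizes a samples-by-96 catalog matrix into `k` signatures and
#' per-sample exposures using multiplicative updates on the Frobenius loss,
#' with multiple seeded restarts; the restart with the best objective is
#' kept. Extracted signatures (columns normalized to sum 1) are matched to
#' reference columns by best cosine similarity, each reference assigned at
#' most once (greedy, best match first).
#'
#' @param catalogs list of 96-channel count vectors (one per sample), or a
#'   samples-by-96 matrix.
#' @param k number of signatures to extract (`1 <= k <=` number of
#'   samples).
#' @param seed integer seed; restart `r` uses stream `seed + r`.
#' @param reference optional [signature_matrix()] to match against.
#' @param n_restarts,max_iter,tol optimization controls.
#' @return list of class `denovo_fit`: `signatures` (a
#'   [signature_matrix()]), `exposures` (samples x k), `objective`, and —
#'   when a reference is supplied — `match` (data.frame signature /
#'   reference / cosine).
#' @export
extract_denovo <- function(catalogs, k, seed, reference = NULL,
                           n_restarts = 10L, max_iter = 2000L, tol = 1e-6) {
  V <- if (is.matrix(catalogs)) catalogs else do.call(rbind, lapply(catalogs, as.numeric))
  if (ncol(V) != 96L) stop("catalogs must have 96 channels")
  if (k < 1L || k > nrow(V)) {
    stop("configuration error: k must be between 1 and the number of samples (",
         nrow(V), ")")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    run <- nmf_run(V, k, max_iter, tol)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  # normalize signatures (rows of H) to probability distributions and fold
  # the scale into the exposures
  scale <- rowSums(best$H)
  degenerate <- scale == 0
  scale[degenerate] <- 1
  H <- best$H / scale
  H[degenerate, ] <- 1 / ncol(H)  # collapsed component -> flat signature
  E <- sweep(best$E, 2L, scale, "*")
  sig_names <- paste0("Denovo", seq_len(k))
  W <- t(H)
  rownames(W) <- channel_labels()
  colnames(W) <- sig_names
  colnames(E) <- sig_names
  out <- list(signatures = signature_matrix(W), exposures = E,
              objective = best$objective)
  if (!is.null(reference)) {
    reference <- signature_matrix(reference)
    cos <- outer(seq_len(k), seq_len(ncol(reference)),
                 Vectorize(function(i, j) cosine_sim(W[, i], reference[, j])))
    dimnames(cos) <- list(sig_names, colnames(reference))
    match <- data.frame(signature = character(), reference = character(),
                        cosine = numeric(), stringsAsFactors = FALSE)
    remaining <- cos
    for (step in seq_len(min(k, ncol(reference)))) {
      idx <- which(remaining == max(remaining), arr.ind = TRUE)[1, ]
      match <- rbind(match, data.frame(
        signature = rownames(remaining)[idx[1]],
        reference = colnames(remaining)[idx[2]],
        cosine = remaining[idx[1], idx[2]], stringsAsFactors = FALSE))
      remaining <- remaining[-idx[1], -idx[2], drop = FALSE]
    }
    out$cosine_matrix <- cos
    out$match <- match[order(match$signature), , drop = FALSE]
  }
  class(out) <- "denovo_fit"
  out
}
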