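#' Feature-table helpers
#'
#' A feature table is a tibble with one row per patient: `patient_id`,
#' a binary `label` (0/1, 1 = condition present) and one numeric column per
#' named radiomics feature.
#'
#' @param table A feature table.
#' @return `feature_columns()`: character vector of feature names;
#'   `feature_matrix()`: the numeric patients x features matrix.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

#' @rdname feature_columns
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(table[feature_columns(table)])
  rownames(m) <- table$patient_id
  m
}

#' Standardize a feature table
#'
#' Z-scores every feature column (sample sd, `n - 1`). Zero-variance
#' features are flagged and set to 0 so they can never be selected as
#' dictionary atoms.
#'
#' @param table A feature table (see [feature_columns()]).
#' @return The standardized table, with a `scaling` attribute: a tibble of
#'   `feature`, `mean`, `sd`, `constant`.
#' @export
standardize_features <- function(table) {
  if (nrow(table) < 2L) stop("need at least 2 patients", call. = FALSE)
  fc <- feature_columns(table)
  mu <- vapply(table[fc], mean, numeric(1))
  sd_ <- vapply(table[fc], stats::sd, numeric(1))
  constant <- sd_ == 0 | !is.finite(sd_)
  out <- table
  for (k in seq_along(fc)) {
    out[[fc[k]]] <- if (constant[k]) rep(0, nrow(table)) else (table[[fc[k]]] - mu[k]) / sd_[k]
  }
  attr(out, "scaling") <- tibble::tibble(feature = fc, mean = mu, sd = sd_, constant = constant)
  out
}

#' Orthogonal matching pursuit
#'
#' Greedy sparse approximation of `target` by columns of `dictionary`:
#' at each iteration the atom with the largest absolute inner product with
#' the current residual joins the active set (ties break to the lowest
#' index), the coefficients are refitted by least squares on the active
#' set, and the residual is updated. Stops at `max_atoms` atoms, when the
#' residual norm drops to `tol`, or when no atom correlates with the
#' residual. The residual norm is non-increasing across iterations.
#'
#' @param dictionary Numeric matrix, observations x atoms (atoms typically
#'   unit-normalized).
#' @param target Numeric vector, length `nrow(dictionary)`.
#' @param max_atoms Maximum support size (default `nrow(dictionary)`).
#' @param tol Residual-norm stopping threshold (default 1e-6).
#' @param corr_factor Noise-floor stopping factor: iteration also stops
#'   once the best absolute residual correlation drops below
#'   `corr_factor * ||residual||`. The default 0 disables it;
#'   [rank_by_src()] passes the universal threshold
#'   `sqrt(2 log(p) / n)`, the expected maximum correlation of pure noise
#'   atoms, so the support is not padded with noise.
#' @return List with `beta` (dense coefficient vector, zeros off-support),
#'   `support` (selection order), `residual_norms` (per iteration, starting
#'   with the target norm).
#' @export
omp <- function(dictionary, target, max_atoms = nrow(dictionary), tol = 1e-6,
                corr_factor = 0) {
  D <- as.matrix(dictionary)
  y <- as.numeric(target)
  stopifnot(length(y) == nrow(D), max_atoms >= 1L)
  p <- ncol(D)
  support <- integer(0)
  beta <- numeric(p)
  resid <- y
  norms <- sqrt(sum(resid^2))
  while (length(support) < min(max_atoms, p)) {
    corr <- abs(as.numeric(crossprod(D, resid)))
    corr[support] <- -Inf
    best <- which.max(corr)          # which.max takes the first (lowest index) tie
    if (!is.finite(corr[best]) || corr[best] <= 0) break
    if (corr[best] < corr_factor * sqrt(sum(resid^2))) break
    cand <- c(support, best)
    fit <- tryCatch(qr.solve(D[, cand, drop = FALSE], y), error = function(e) NULL)
    if (is.null(fit) || qr(D[, cand, drop = FALSE])$rank < length(cand)) break
    support <- cand
    beta <- numeric(p)
    beta[support] <- fit
    resid <- y - D[, support, drop = FALSE] %*% fit
    norms <- c(norms, sqrt(sum(resid^2)))
    if (norms[length(norms)] <= tol) break
  }
  list(beta = beta, support = support, residual_norms = norms)
}

#' Rank features by sparse-representation coefficients
#'
#' The feature table becomes a dictionary: each feature column is z-scored
#' and unit-normalized (one atom per feature), and the `{-1, +1}`-coded
#' label vector is the target. OMP solves for a sparse coefficient vector
#' beta; its entries are the sparse representation coefficients (SRCs), and
#' features are ranked by descending `|beta|`. Features outside the OMP
#' support are appended in descending order of absolute correlation with
#' the target, so the classifier sweep can extend past the support.
#'
#' @param table Feature table with both classes present in `label`.
#' @param max_atoms,tol Passed to [omp()] (defaults: number of patients,
#'   1e-6).
#' @return A tibble of class `src_ranking`: `rank`, `feature`, `beta`,
#'   `abs_corr`, `selected` (in the OMP support), ordered by rank; the
#'   support size is in `attr(, "n_nonzero")`.
#' @export
rank_by_src <- function(table, max_atoms = NULL, tol = 1e-6) {
  labs <- table$label
  if (length(unique(labs)) != 2L) stop("both classes must be present", call. = FALSE)
  y <- ifelse(labs == 1, 1, -1)
  std <- standardize_features(table)
  fc <- feature_columns(std)
  D <- as.matrix(std[fc])
  nrm <- sqrt(colSums(D^2))
  nz <- nrm > 0
  D[, nz] <- sweep(D[, nz, drop = FALSE], 2L, nrm[nz], `/`)
  if (is.null(max_atoms)) max_atoms <- nrow(table)
  fit <- omp(D, y, max_atoms = max_atoms, tol = tol,
             corr_factor = sqrt(2 * log(length(fc)) / nrow(table)))
  abs_corr <- abs(as.numeric(crossprod(D, y)))
  sel <- fit$beta != 0
  ord_sel <- which(sel)[order(-abs(fit$beta[sel]), which(sel))]
  ord_rest <- which(!sel)[order(-abs_corr[!sel], which(!sel))]
  ord <- c(ord_sel, ord_rest)
  out <- tibble::tibble(
    rank = seq_along(ord),
    feature = fc[ord],
    beta = fit$beta[ord],
    abs_corr = abs_corr[ord],
    selected = sel[ord])
  attr(out, "n_nonzero") <- sum(sel)
  class(out) <- c("src_ranking", class(out))
  out
}

#' @export
print.src_ranking <- function(x, ...) {
  cat(sprintf("<src_ranking> %d features, OMP support %d\n",
              nrow(x), attr(x, "n_nonzero")))
  NextMethod()
}
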