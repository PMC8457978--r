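# Dietary scoring: the dietary inflammatory index (a literature-weighted
# sum of component intakes) and dietary-pattern extraction by PCA with
# varimax rotation of a subjects x food-group intake matrix.

#' Dietary inflammatory index
#'
#' DII per subject = sum over components of (inflammatory weight x daily
#' intake) / 100. Weights are user-supplied literature values (typically 38
#' components: energy, nutrients, food products and caffeine); positive
#' weights are pro-inflammatory. The default is this plain weighted sum;
#' `standardize = TRUE` switches to the variant that z-scores each
#' component's intake across subjects before weighting.
#'
#' @param intakes data frame or matrix of daily intakes, columns named by
#'   component. A weighted component absent from `intakes` contributes 0,
#'   with a warning.
#' @param weights data frame with columns `component`, `weight` and
#'   optionally `units`; component names must be unique.
#' @param intake_units optional named character vector declaring the units
#'   of the intake columns; any declared unit disagreeing with the weights
#'   file is an error.
#' @param standardize z-score intakes before weighting (default FALSE).
#' @return numeric DII vector, one value per subject.
#' @export
compute_dii <- function(intakes, weights, intake_units = NULL,
                        standardize = FALSE) {
  stopifnot(is.data.frame(weights), all(c("component", "weight") %in% names(weights)))
  if (anyDuplicated(weights$component)) {
    stop("duplicate component names in weights", call. = FALSE)
  }
  if (any(!is.finite(weights$weight))) stop("non-finite weight", call. = FALSE)
  intakes <- as.data.frame(intakes)
  if (!is.null(intake_units) && "units" %in% names(weights)) {
    shared <- intersect(names(intake_units), weights$component)
    declared <- weights$units[match(shared, weights$component)]
    bad <- shared[!is.na(declared) & declared != intake_units[shared]]
    if (length(bad)) {
      stop("intake units disagree with weights file for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  absent <- setdiff(weights$component, names(intakes))
  if (length(absent)) {
    warning("components absent from intakes treated as 0: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  present <- intersect(weights$component, names(intakes))
  if (length(present) == 0L) return(rep(0, nrow(intakes)))
  M <- as.matrix(intakes[, present, drop = FALSE])
  if (standardize) M <- scale(M)
  w <- weights$weight[match(present, weights$component)]
  as.numeric(M %*% w) / 100
}

# Flip each factor so its largest-magnitude loading is positive.
fix_signs <- function(L, scores = NULL) {
  for (j in seq_len(ncol(L))) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) {
      L[, j] <- -L[, j]
      if (!is.null(scores)) scores[, j] <- -scores[, j]
    }
  }
  list(loadings = L, scores = scores)
}

#' Extract dietary patterns by PCA with varimax rotation
#'
#' Standardizes the food-group columns, computes principal components,
#' retains those with eigenvalue above `eigen_threshold` (1.5), applies
#' varimax rotation (with Kaiser normalization) to the retained component
#' loadings, and flags loadings at or above `loading_threshold` (0.40) as
#' each pattern's defining food groups. Per-subject factor scores use the
#' regression method on the rotated loadings; the high-intake flag marks
#' scores at or above the 75th percentile. Factor signs are fixed so each
#' factor's largest-magnitude loading is positive, making the output
#' deterministic. Patterns are reported by index plus their defining
#' groups; naming (e.g. Korean-balanced vs Western-style vs rice-based) is
#' left to the analyst.
#'
#' @param food_mat numeric subjects x food-groups matrix or data frame
#'   (commonly 29 groups); needs more subjects than groups.
#' @param eigen_threshold retention threshold on eigenvalues (default 1.5).
#' @param loading_threshold defining-group threshold on rotated loadings
#'   (default 0.40).
#' @return object of class `pattern_model`: list with `eigenvalues` (all),
#'   `n_retained`, `loadings` (rotated, sign-fixed), `defining_groups`
#'   (list per factor), `scores`, `high_flags` (logical matrix),
#'   `thresholds`.
#' @export
extract_patterns <- function(food_mat, eigen_threshold = 1.5,
                             loading_threshold = 0.40) {
  X <- as.matrix(food_mat)
  if (nrow(X) <= ncol(X)) {
    stop("need more subjects than food groups (", nrow(X), " x ", ncol(X), ")",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("group", seq_len(ncol(X)))
  Z <- scale(X)
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pca$sdev^2
  keep <- which(eig > eigen_threshold)
  if (length(keep) == 0L) {
    return(structure(list(eigenvalues = eig, n_retained = 0L,
                          loadings = NULL, defining_groups = list(),
                          scores = NULL, high_flags = NULL,
                          thresholds = c(eigen = eigen_threshold,
                                         loading = loading_threshold)),
                     class = "pattern_model"))
  }
  # component loadings (variable-component correlations)
  L <- pca$rotation[, keep, drop = FALSE] %*% diag(pca$sdev[keep],
                                                  length(keep))
  if (length(keep) >= 2L) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
    L <- unclass(vm$loadings)
  }
  R <- stats::cov(Z)   # correlation matrix of the standardized groups
  S <- Z %*% solve(R, L)          # regression-method factor scores
  fx <- fix_signs(L, S)
  L <- fx$loadings; S <- fx$scores
  colnames(L) <- colnames(S) <- paste0("factor", seq_along(keep))
  rownames(L) <- colnames(X)
  defining <- lapply(seq_len(ncol(L)), function(j)
    rownames(L)[L[, j] >= loading_threshold])
  names(defining) <- colnames(L)
  q75 <- apply(S, 2, stats::quantile, 0.75)
  high <- sweep(S, 2, q75, ">=")
  structure(list(eigenvalues = eig, n_retained = length(keep),
                 loadings = L, defining_groups = defining,
                 scores = S, high_flags = high,
                 thresholds = c(eigen = eigen_threshold,
                                loading = loading_threshold)),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("dietary pattern model: %d factor(s) retained (eigenvalue > %.2f)\n",
              x$n_retained, x$thresholds["eigen"]))
  for (nm in names(x$defining_groups)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(x$defining_groups[[nm]], collapse = ", ")))
  }
  invisible(x)
}
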