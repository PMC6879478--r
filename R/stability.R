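#' geNorm reference-gene stability
#'
#' Pairwise-variation stability of candidate reference genes on the Ct
#' scale: for genes j and k, `V_jk` is the standard deviation across
#' samples (n-1 denominator) of the difference `Ct_j - Ct_k`; the
#' stability of gene j is `M_j = mean(V_jk, k != j)`. Low M means stable.
#' Rows containing any missing value are excluded from the computation and
#' reported in the result. Selection takes genes with M below `cutoff`
#' (`direction = "below"`, the convention of the pairwise-variation
#' method, where 1.5 is an upper bound on acceptable M); `direction =
#' "above"` is available for compatibility with tools that applied the
#' threshold the other way around.
#'
#' @param m numeric matrix, features x samples (Ct scale).
#' @param cutoff stability threshold (default 1.5).
#' @param direction select genes with M `"below"` (default) or `"above"`
#'   the cutoff.
#' @return A `StabilityReport`: list with `scores` (named M values, in
#'   input order), `selected` (feature names), `ranking` (names, most
#'   stable first), `excluded` (rows dropped for missingness), `method`.
#' @export
genorm_stability <- function(m, cutoff = 1.5, direction = c("below", "above")) {
  direction <- match.arg(direction)
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("feature", seq_len(nrow(m)))
  complete <- !apply(is.na(m), 1L, any)
  excluded <- rownames(m)[!complete]
  x <- m[complete, , drop = FALSE]
  g <- nrow(x)
  if (g < 3L)
    stop("geNorm needs at least 3 features without missing values, found ",
         g, call. = FALSE)
  if (ncol(x) < 2L) stop("geNorm needs at least 2 samples", call. = FALSE)
  M <- numeric(g)
  for (j in seq_len(g)) {
    v <- vapply(seq_len(g)[-j], function(k) sd(x[j, ] - x[k, ]), 0)
    M[j] <- mean(v)
  }
  names(M) <- rownames(x)
  selected <- if (direction == "below") names(M)[M < cutoff] else
    names(M)[M > cutoff]
  structure(list(scores = M, selected = selected,
                 ranking = names(sort(M)), excluded = excluded,
                 method = "genorm", cutoff = cutoff, direction = direction),
            class = "StabilityReport")
}

#' NormFinder model-based reference-gene stability
#'
#' Model-based stability of candidate reference genes for a two-group
#' design on the Ct scale, following the Andersen variance-decomposition
#' approach: per gene and group, the intra-group variance is estimated
#' from the two-way centered residuals (gene value minus the per-sample
#' mean over genes and the gene's group mean), corrected for the shared
#' subtraction of the sample mean; the inter-group deviation of the
#' gene-specific group effect is shrunk towards zero by its sampling
#' variance. The stability value of gene j is
#' `rho_j = mean over groups of ( |shrunken inter-group deviation| +
#' sqrt(intra-group variance / n_group) )`; low rho means stable.
#'
#' @param m numeric matrix, features x samples (Ct scale); rows with any
#'   missing value are excluded and reported.
#' @param treatment a [treatment_map()] covering the columns of `m` (by
#'   name when `m` has column names, else by position).
#' @return A `StabilityReport` with `scores` (rho, input order),
#'   `selected` (single most stable gene), `ranking`, `excluded`,
#'   `method`.
#' @export
normfinder_stability <- function(m, treatment) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("feature", seq_len(nrow(m)))
  cols <- if (!is.null(colnames(m)))
    treatment$groups[match(colnames(m), treatment$sample_names)] else
      treatment$groups
  if (anyNA(cols) || length(cols) != ncol(m))
    stop("treatment map does not cover the samples of the matrix",
         call. = FALSE)
  complete <- !apply(is.na(m), 1L, any)
  excluded <- rownames(m)[!complete]
  x <- m[complete, , drop = FALSE]
  G <- nrow(x)
  if (G < 3L)
    stop("NormFinder needs at least 3 complete features", call. = FALSE)
  lev <- unique(cols)
  n_i <- table(factor(cols, levels = lev))
  if (any(n_i < 2L))
    stop("NormFinder needs at least 2 samples per group", call. = FALSE)

  # remove the per-sample mean over genes (sample effect + mean gene effect)
  z <- sweep(x, 2L, colMeans(x))
  d_hat <- s2 <- se2 <- matrix(0, G, length(lev),
                               dimnames = list(rownames(x), lev))
  for (i in seq_along(lev)) {
    zi <- z[, cols == lev[i], drop = FALSE]
    ni <- ncol(zi)
    d_hat[, i] <- rowMeans(zi)
    w <- rowSums((zi - rowMeans(zi))^2) / (ni - 1)  # var of centered values
    # E[w_g] = s2_g*(1-2/G) + mean(s2)/G  =>  unbiased inversion
    mbar <- mean(w)
    s2[, i] <- pmax(0, (w - mbar / (G - 1)) * G / (G - 2))
    se2[, i] <- s2[, i] / ni
  }
  # gene-specific group deviation relative to the gene's cross-group mean
  d_hat <- d_hat - rowMeans(d_hat)
  rho_i <- matrix(0, G, length(lev))
  for (i in seq_along(lev)) {
    # shrink the observed deviation by its sampling variance
    var_d <- max(0, sum(d_hat[, i]^2) / (G - 1) - mean(se2[, i]))
    gamma <- ifelse(var_d + se2[, i] > 0, var_d / (var_d + se2[, i]), 0)
    rho_i[, i] <- abs(d_hat[, i] * gamma) + sqrt(se2[, i])
  }
  rho <- rowMeans(rho_i)
  names(rho) <- rownames(x)
  structure(list(scores = rho, selected = names(rho)[which.min(rho)],
                 ranking = names(sort(rho)), excluded = excluded,
                 method = "normfinder"),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport (%s): %d scored, %d selected\n",
              x$method, length(x$scores), length(x$selected)))
  if (length(x$selected))
    cat("  selected:", paste(head(x$selected, 8L), collapse = ", "), "\n")
  invisible(x)
}
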