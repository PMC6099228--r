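#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_k - y_k| / sum (x_k + y_k)` between community unit
#' count vectors, computed with [vegan::vegdist()]. Units with all-zero
#' counts have no defined dissimilarity and raise an error naming the unit.
#'
#' @param table An [build_abundance_table()] result or a units x species
#'   count matrix.
#' @return A `dist` object with unit labels.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 community units")
  if (any(m < 0)) stop("negative counts are not allowed")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero community unit(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' SIMPER: per-species decomposition of between-group Bray-Curtis dissimilarity
#'
#' For every pair of units (j, l) with j in group A and l in group B, the
#' species component is `delta_k = |y_kj - y_kl| / sum_s (y_sj + y_sl)`; a
#' species' contribution is the mean of its component over all between-group
#' pairs, so contributions sum exactly to the mean between-group Bray-Curtis
#' dissimilarity. Significance of each species' contribution is assessed by
#' permuting group labels (one-sided "greater", with the +1 correction), the
#' convention for asking whether a species discriminates the two communities
#' more than expected by chance.
#'
#' @param table An `abundance_table` or count matrix.
#' @param group Factor/vector with exactly two levels, aligned with units.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Object of class `simper_bc`: a data frame sorted by decreasing
#'   contribution with columns `species`, `avg_A`, `avg_B` (raw group mean
#'   abundances), `contribution`, `cumulative` (nondecreasing, ends at 1)
#'   and `permutation_p`; the mean between-group dissimilarity is attached
#'   as attribute `mean_dissimilarity`.
#' @export
simper_bc <- function(table, group, n_perm = 1000L, seed = 1L) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (length(group) != nrow(m)) stop("group labels must align with units")
  if (any(table(group) < 1L)) stop("each group needs at least one unit")

  contrib <- function(lab) {
    A <- m[lab == levels(group)[1L], , drop = FALSE]
    B <- m[lab == levels(group)[2L], , drop = FALSE]
    denom <- outer(rowSums(A), rowSums(B), "+")  # sum_s (y_sj + y_sl)
    w <- 1 / denom
    np <- length(denom)
    vapply(seq_len(ncol(m)), function(k) {
      sum(abs(outer(A[, k], B[, k], "-")) * w) / np
    }, numeric(1))
  }
  obs <- contrib(group)

  perm_ge <- rep(1L, ncol(m))  # +1 correction
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pc <- contrib(sample(group))
      perm_ge <- perm_ge + (pc >= obs)
    }
  })
  pval <- perm_ge / (n_perm + 1L)

  ord <- order(obs, decreasing = TRUE)
  total <- sum(obs)
  out <- data.frame(
    species = colnames(m)[ord],
    avg_A = colMeans(m[group == levels(group)[1L], , drop = FALSE])[ord],
    avg_B = colMeans(m[group == levels(group)[2L], , drop = FALSE])[ord],
    contribution = obs[ord],
    cumulative = cumsum(obs[ord]) / total,
    permutation_p = pval[ord],
    row.names = NULL)
  structure(out, class = c("simper_bc", "data.frame"),
            mean_dissimilarity = total,
            groups = levels(group), n_perm = n_perm)
}

#' @export
print.simper_bc <- function(x, digits = 3, ...) {
  g <- attr(x, "groups")
  cat("SIMPER decomposition (group A =", g[1], ", group B =", g[2], ")\n")
  cat(sprintf("  mean between-group Bray-Curtis dissimilarity: %.4f\n",
              attr(x, "mean_dissimilarity")))
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Partial distance-based redundancy analysis
#'
#' Principal-coordinate embedding of an arbitrary dissimilarity matrix
#' followed by least-squares constrained ordination. The Gower-centered
#' matrix `-D^2/2` is eigendecomposed; positive-eigenvalue axes, scaled by
#' the square root of their eigenvalue, become site coordinates (negative
#' eigenvalues are dropped and their total magnitude reported). If a
#' conditioning design `Z` is given, the coordinates are replaced by their
#' residuals on `[1, Z]`; the constrained inertia is the sum of squared
#' fitted values from regressing the (residualized) coordinates on `[1, X]`.
#' All proportions are relative to the total positive inertia before
#' conditioning. Significance is assessed by permuting rows of the
#' residualized coordinates (the reduced-model scheme) and recomputing the
#' pseudo-F.
#'
#' @param D A `dist` or symmetric dissimilarity matrix.
#' @param X Explanatory design: data frame (expanded via `model.matrix`) or
#'   numeric matrix, rows aligned with `D`.
#' @param Z Optional conditioning design, same conventions.
#' @param n_perm Number of row permutations (default 1000; 0 disables the
#'   test).
#' @param seed Integer seed for the permutations.
#' @return Object of class `dbrda_bc` with inertia decomposition
#'   (`conditioned`, `constrained`, `residual`, `total`), the corresponding
#'   proportions, `pseudo_F`, `df_model`, `df_residual`, `permutation_p`,
#'   site scores on the constrained axes and biplot correlations of the
#'   explanatory columns.
#' @export
dbrda_bc <- function(D, X, Z = NULL, n_perm = 1000L, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")

  expand <- function(M, what) {
    if (is.null(M)) return(NULL)
    M <- if (is.data.frame(M)) stats::model.matrix(~ ., M)[, -1, drop = FALSE]
         else as.matrix(M)
    if (nrow(M) != n) stop(what, " design must have one row per unit of D")
    # drop collinear columns via pivoted QR
    q <- qr(cbind(1, M))
    if (q$rank < ncol(M) + 1L) {
      drop_idx <- q$pivot[-seq_len(q$rank)] - 1L
      warning("dropping collinear ", what, " column(s): ",
              paste(colnames(M)[drop_idx], collapse = ", "))
      M <- M[, -drop_idx, drop = FALSE]
    }
    M
  }
  X <- expand(X, "explanatory")
  Z <- expand(Z, "conditioning")

  # Gower double centering of -D^2/2
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  Y <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                               nrow = sum(pos))
  total <- sum(e$values[pos])
  neg_inertia <- sum(abs(e$values[e$values < -tol]))

  df_cond <- 0L
  conditioned <- 0
  Yr <- Y
  if (!is.null(Z)) {
    qz <- qr(cbind(1, Z))
    Yr <- qr.resid(qz, Y)
    conditioned <- sum(qr.fitted(qz, Y)^2)
    df_cond <- qz$rank - 1L
  }
  qx <- qr(cbind(1, X))
  constrained <- sum(qr.fitted(qx, Yr)^2)
  residual <- sum(qr.resid(qx, Yr)^2)
  df_model <- qx$rank - 1L
  df_residual <- n - 1L - df_cond - df_model
  pseudo_F <- (constrained / df_model) / (residual / df_residual)

  permutation_p <- NA_real_
  if (n_perm > 0L) {
    b <- 0L
    with_seed(seed, {
      for (i in seq_len(n_perm)) {
        Yp <- Yr[sample.int(n), , drop = FALSE]
        cs <- sum(qr.fitted(qx, Yp)^2)
        rs <- sum(qr.resid(qx, Yp)^2)
        Fp <- (cs / df_model) / (rs / df_residual)
        if (Fp >= pseudo_F) b <- b + 1L
      }
    })
    permutation_p <- (b + 1L) / (n_perm + 1L)
  }

  fitted_Y <- qr.fitted(qx, Yr)
  sv <- svd(fitted_Y, nu = min(df_model, 2L), nv = 0L)
  sites <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], nrow = ncol(sv$u))
  colnames(sites) <- paste0("dbRDA", seq_len(ncol(sites)))
  biplot <- suppressWarnings(stats::cor(X, sites))
  biplot[is.na(biplot)] <- 0

  structure(list(
    total = total, conditioned = conditioned, constrained = constrained,
    residual = residual, negative_inertia = neg_inertia,
    constrained_proportion = constrained / total,
    conditioned_proportion = conditioned / total,
    residual_proportion = residual / total,
    pseudo_F = pseudo_F, df_model = df_model, df_residual = df_residual,
    permutation_p = permutation_p, n_perm = n_perm,
    site_scores = sites, biplot_scores = biplot,
    eigenvalues = e$values[pos]), class = "dbrda_bc")
}

#' @export
print.dbrda_bc <- function(x, ...) {
  cat("Partial distance-based RDA\n")
  cat(sprintf("  inertia: total %.4f = conditioned %.4f + constrained %.4f + residual %.4f\n",
              x$total, x$conditioned, x$constrained, x$residual))
  cat(sprintf("  constrained proportion: %.2f%% (conditioned %.2f%%)\n",
              100 * x$constrained_proportion, 100 * x$conditioned_proportion))
  if (x$negative_inertia > 0)
    cat(sprintf("  negative eigenvalues dropped (total magnitude %.4f)\n",
                x$negative_inertia))
  cat(sprintf("  pseudo-F = %.3f on df %d,%d", x$pseudo_F, x$df_model,
              x$df_residual))
  if (!is.na(x$permutation_p))
    cat(sprintf(", permutation p = %.4g (%d permutations)", x$permutation_p,
                x$n_perm))
  cat("\n")
  invisible(x)
}
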