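#' Hierarchical bootstrap rate estimation
#'
#' Estimates group-wise proportions (infection, parasitism, hyperparasitism
#' rates) with uncertainty from a hierarchical bootstrap that mirrors the
#' nested field design: fields are resampled with replacement (13 of 13),
#' then plots within each drawn field, then colonies (collection tubes)
#' within each drawn plot; individuals within a colony stay together. This
#' respects the non-independence of individuals from the same aphid colony
#' the way nested random effects would. Point estimates are pooled
#' proportions (bootstrap-free); intervals are percentile intervals at the
#' 75% and 95% level, mirroring the box/whisker convention of the figures.
#'
#' @param samples Classified sample records.
#' @param outcome Name of a logical (or 0/1) column to average, e.g.
#'   `"fe_infected"`, `"primary_parasitized"`, `"hyperparasitized"`.
#' @param group_by Character vector of grouping columns (e.g.
#'   `c("parasitism_class", "fertilized")`); `NULL` for a single overall
#'   group.
#' @param B Number of bootstrap replicates (default 2000, minimum 500
#'   recommended).
#' @param seed Integer seed.
#' @param subset Optional logical vector restricting the samples (e.g. to
#'   living aphids) before estimation.
#' @return Object of class `rate_estimates`: a data frame with `group`,
#'   `estimate`, `ci75_lo`, `ci75_hi`, `ci95_lo`, `ci95_hi`, `n`; the B x
#'   groups matrix of bootstrap rates is attached as attribute `boot` so
#'   contrasts can reuse the shared replicates.
#' @export
estimate_rates <- function(samples, outcome, group_by = NULL, B = 2000L,
                           seed = 1L, subset = NULL) {
  if (!"parasitism_class" %in% names(samples)) samples <- classify_samples(samples)
  if (!is.null(subset)) samples <- samples[subset, , drop = FALSE]
  if (!outcome %in% names(samples)) stop("unknown outcome column: ", outcome)
  y <- as.numeric(samples[[outcome]])
  if (any(is.na(y) | !y %in% c(0, 1))) stop("outcome must be logical or 0/1")

  grp <- if (is.null(group_by)) factor(rep("all", nrow(samples))) else
    interaction(lapply(group_by, function(g) as.factor(samples[[g]])),
                sep = " | ", drop = FALSE, lex.order = TRUE)
  empty <- setdiff(levels(grp), unique(as.character(grp)))
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
    grp <- droplevels(grp)
  }
  G <- nlevels(grp)

  # colony-level sufficient statistics: counts and positives per group
  colony <- factor(paste(samples$field_id, samples$plot_id, samples$date,
                         samples$colony_id, sep = ":"))
  K <- nlevels(colony)
  ci <- as.integer(colony)
  gi <- as.integer(grp)
  n_mat <- matrix(0, K, G)
  pos_mat <- matrix(0, K, G)
  for (i in seq_along(y)) {
    n_mat[ci[i], gi[i]] <- n_mat[ci[i], gi[i]] + 1
    pos_mat[ci[i], gi[i]] <- pos_mat[ci[i], gi[i]] + y[i]
  }

  # hierarchy maps
  colony_meta <- do.call(rbind, strsplit(levels(colony), ":", fixed = TRUE))
  colony_plot <- paste(colony_meta[, 1], colony_meta[, 2], sep = ":")
  plots <- unique(colony_plot)
  plot_field <- vapply(strsplit(plots, ":", fixed = TRUE), `[`, character(1), 1L)
  fields <- unique(plot_field)
  colonies_of_plot <- split(seq_len(K), factor(colony_plot, levels = plots))
  plots_of_field <- split(seq_along(plots), factor(plot_field, levels = fields))
  nf <- length(fields)

  boot <- matrix(NA_real_, B, G, dimnames = list(NULL, levels(grp)))
  with_seed(seed, {
    mult <- numeric(K)
    for (b in seq_len(B)) {
      mult[] <- 0
      fsel <- sample.int(nf, nf, replace = TRUE)
      for (f in fsel) {
        pl <- plots_of_field[[f]]
        psel <- pl[sample.int(length(pl), length(pl), replace = TRUE)]
        for (p in psel) {
          cl <- colonies_of_plot[[p]]
          csel <- cl[sample.int(length(cl), length(cl), replace = TRUE)]
          for (cc in csel) mult[cc] <- mult[cc] + 1
        }
      }
      denom <- crossprod(mult, n_mat)
      num <- crossprod(mult, pos_mat)
      boot[b, ] <- ifelse(denom > 0, num / denom, NA_real_)
    }
  })

  qs <- apply(boot, 2, stats::quantile,
              probs = c(0.125, 0.875, 0.025, 0.975), na.rm = TRUE)
  est <- as.numeric(tapply(y, grp, mean))
  out <- data.frame(group = levels(grp), estimate = est,
                    ci75_lo = qs[1, ], ci75_hi = qs[2, ],
                    ci95_lo = qs[3, ], ci95_hi = qs[4, ],
                    n = as.integer(table(grp)), row.names = NULL)
  structure(out, class = c("rate_estimates", "data.frame"),
            boot = boot, outcome = outcome, B = B, seed = seed)
}

#' @export
print.rate_estimates <- function(x, digits = 3, ...) {
  cat("Hierarchical bootstrap rate estimates (outcome:", attr(x, "outcome"),
      ", B =", attr(x, "B"), ")\n")
  print.data.frame(cbind(x["group"], round(x[-1][-6], digits), n = x$n),
                   row.names = FALSE)
  invisible(x)
}

#' Bootstrap contrasts between group rates
#'
#' Differences between group rates are evaluated on the shared bootstrap
#' replicates of [estimate_rates()] (the same resampled fields underlie both
#' groups of a pair, a paired design). The two-sided bootstrap p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` with the +1 correction, and the set
#' of p-values is corrected for false discovery rate (Benjamini-Hochberg).
#'
#' @param estimates A `rate_estimates` object.
#' @param pairs Optional list of 2-element character vectors (group names);
#'   default all pairs.
#' @return Data frame with `group_a`, `group_b`, `difference`,
#'   `bootstrap_p`, `fdr_adjusted_p`.
#' @export
contrast_rates <- function(estimates, pairs = NULL) {
  boot <- attr(estimates, "boot")
  groups <- estimates$group
  if (length(groups) < 2L) stop("need at least 2 groups to contrast")
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
  B <- nrow(boot)
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% groups)) stop("unknown group in pair: ",
                                   paste(pr, collapse = " vs "))
    d <- boot[, pr[1]] - boot[, pr[2]]
    d <- d[!is.na(d)]
    p <- 2 * min((1 + sum(d <= 0)) / (length(d) + 1),
                 (1 + sum(d >= 0)) / (length(d) + 1))
    data.frame(group_a = pr[1], group_b = pr[2],
               difference = estimates$estimate[groups == pr[1]] -
                 estimates$estimate[groups == pr[2]],
               bootstrap_p = min(1, p))
  })
  out <- do.call(rbind, res)
  out$fdr_adjusted_p <- fdr_adjust(out$bootstrap_p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, order-preserving against the input. A thin,
#' validating wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
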