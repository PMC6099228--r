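#' Extract primary-hyperparasitoid interactions with covariates
#'
#' One interaction record is emitted for every (primary taxon,
#' hyperparasitoid taxon) pair detected in a primary-parasitized sample: a
#' sample with several primary and hyperparasitoid detections expands to all
#' pairs (set `multiplicity = "single"` to keep one random-free first pair
#' per sample instead). Each record carries the sample's binary covariates so
#' resampled webs can compute their proportional assembly. Samples with a
#' hyperparasitoid detection but no identified primary taxon (possible in
#' mummies) cannot contribute a link; they are counted in the
#' `n_hyper_without_primary` attribute. Hyperparasitoid tokens on living
#' unparasitized aphids are excluded by definition and counted in
#' `n_hyper_on_unparasitized`.
#'
#' @param samples Classified sample records.
#' @param multiplicity `"pairs"` (default; all pairs) or `"single"` (first
#'   listed primary and hyperparasitoid taxon only).
#' @return Data frame of interactions: `primary_taxon`, `hyper_taxon`,
#'   `fe_infected`, `fertilized`, `complex_landscape`, `date2`,
#'   `source_sample_id`.
#' @export
extract_interactions <- function(samples, multiplicity = c("pairs", "single")) {
  multiplicity <- match.arg(multiplicity)
  if (!"parasitism_class" %in% names(samples)) samples <- classify_samples(samples)
  has_hyper_token <- nzchar(samples$hyper_species)
  excluded_unpar <- sum(has_hyper_token &
                          samples$parasitism_class == "living_unparasitized")
  eligible <- samples$primary_parasitized & has_hyper_token
  no_primary <- sum(eligible & !nzchar(samples$primary_species))
  use <- eligible & nzchar(samples$primary_species)
  s <- samples[use, , drop = FALSE]

  out <- vector("list", nrow(s))
  if (nrow(s)) {
    ps <- split_species(s$primary_species)
    hs <- split_species(s$hyper_species)
    if (multiplicity == "single") {
      ps <- lapply(ps, `[`, 1L)
      hs <- lapply(hs, `[`, 1L)
    }
    for (i in seq_len(nrow(s))) {
      grid <- expand.grid(primary_taxon = ps[[i]], hyper_taxon = hs[[i]],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$fe_infected <- s$fe_infected[i]
      grid$fertilized <- s$fertilized[i]
      grid$complex_landscape <- s$landscape[i] == "complex"
      grid$date2 <- s$date[i] == 2L
      grid$source_sample_id <- s$sample_id[i]
      out[[i]] <- grid
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(primary_taxon = character(), hyper_taxon = character(),
               fe_infected = logical(), fertilized = logical(),
               complex_landscape = logical(), date2 = logical(),
               source_sample_id = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_hyper_without_primary") <- no_primary
  attr(res, "n_hyper_on_unparasitized") <- excluded_unpar
  if (no_primary > 0)
    message(no_primary, " hyperparasitized sample(s) without an identified ",
            "primary taxon cannot contribute interactions")
  res
}

#' Resampled bipartite food webs with covariate propagation
#'
#' Implements the fixed-size resampling device for size-biased food-web
#' metrics: each resampled web consists of `web_size` interactions drawn
#' uniformly with replacement from the pooled interaction list; H2' (integer
#' mode) is computed on the resulting count web, and each binary covariate is
#' summarized as the proportion of drawn interactions carrying it (the
#' proportional assembly). Webs are generated from a single seeded RNG
#' stream, so the first k webs are identical whenever `n_webs >= k`; the
#' computation streams one web at a time and memory does not grow with
#' `n_webs`.
#'
#' @param interactions Interaction records from [extract_interactions()].
#' @param n_webs Number of resampled webs (study default 200000).
#' @param web_size Interactions per web (study default 100).
#' @param seed Integer seed.
#' @return Data frame with `web_index`, `H2prime`, `prop_fe`, `prop_fert`,
#'   `prop_complex`, `prop_date2`.
#' @export
resample_webs <- function(interactions, n_webs = 200000L, web_size = 100L,
                          seed = 1L) {
  n <- nrow(interactions)
  if (!n) stop("empty interaction list: no hyperparasitized samples with an identified primary taxon")
  p <- factor(interactions$primary_taxon,
              levels = unique(c(intersect(PRIMARY_TAXA, interactions$primary_taxon),
                                sort(setdiff(interactions$primary_taxon, PRIMARY_TAXA)))))
  h <- factor(interactions$hyper_taxon,
              levels = unique(c(intersect(HYPER_TAXA, interactions$hyper_taxon),
                                sort(setdiff(interactions$hyper_taxon, HYPER_TAXA)))))
  np <- nlevels(p)
  nh <- nlevels(h)
  code <- (as.integer(p) - 1L) * nh + as.integer(h)
  fe <- as.numeric(interactions$fe_infected)
  fert <- as.numeric(interactions$fertilized)
  cplx <- as.numeric(interactions$complex_landscape)
  d2 <- as.numeric(interactions$date2)

  H2p <- numeric(n_webs)
  pf <- numeric(n_webs)
  pt <- numeric(n_webs)
  pc <- numeric(n_webs)
  pd <- numeric(n_webs)
  with_seed(seed, {
    for (w in seq_len(n_webs)) {
      idx <- sample.int(n, web_size, replace = TRUE)
      tab <- tabulate(code[idx], nbins = np * nh)
      a <- matrix(tab, nrow = nh, ncol = np)  # hyper rows, primary cols
      H2p[w] <- cpp_h2_prime_int(a, 1e-12)
      pf[w] <- sum(fe[idx]) / web_size
      pt[w] <- sum(fert[idx]) / web_size
      pc[w] <- sum(cplx[idx]) / web_size
      pd[w] <- sum(d2[idx]) / web_size
    }
  })
  data.frame(web_index = seq_len(n_webs), H2prime = H2p, prop_fe = pf,
             prop_fert = pt, prop_complex = pc, prop_date2 = pd)
}

#' Linear model of H2' on proportional-assembly covariates with AIC selection
#'
#' Fits ordinary least squares models of per-web H2' on all subsets of the
#' four proportional covariates (endosymbiont infection, fertilization,
#' landscape complexity, sampling date), optionally adding the
#' infection x date and infection x fertilization interactions where both
#' parents are present (marginality respected), and returns the minimum-AIC
#' model. Alongside the selected fit it reports the full-model R-squared,
#' single-predictor (marginal) R-squared per covariate, and the Pearson
#' correlation between H2' and the infection proportion.
#'
#' @param rows Resampled-web rows from [resample_webs()].
#' @param candidate_terms Main-effect candidates (default all four).
#' @param interactions Include the fe x date2 / fe x fert interaction
#'   candidates (default TRUE).
#' @return Object of class `h2_model_fit`.
#' @export
fit_h2_model <- function(rows,
                         candidate_terms = c("prop_fe", "prop_fert",
                                             "prop_complex", "prop_date2"),
                         interactions = TRUE) {
  stopifnot(all(c("H2prime", candidate_terms) %in% names(rows)))
  # constant covariates cannot enter a regression; drop with a warning
  keep <- vapply(candidate_terms, function(v) stats::var(rows[[v]]) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant term(s): ",
            paste(candidate_terms[!keep], collapse = ", "))
    candidate_terms <- candidate_terms[keep]
  }
  if (length(unique(rows$H2prime)) < 2L)
    warning("H2prime shows no variation across webs")

  inter_pool <- c("prop_fe:prop_date2", "prop_fe:prop_fert")
  subsets <- function(x) {
    out <- list(character(0))
    for (v in x) out <- c(out, lapply(out, c, v))
    out
  }
  candidates <- list()
  for (mains in subsets(candidate_terms)) {
    ints <- if (interactions)
      inter_pool[vapply(strsplit(inter_pool, ":", fixed = TRUE),
                        function(pr) all(pr %in% mains), logical(1))]
    else character(0)
    for (ii in subsets(ints))
      candidates[[length(candidates) + 1L]] <- c(mains, ii)
  }

  fits <- lapply(candidates, function(tt) {
    f <- if (length(tt)) stats::reformulate(tt, response = "H2prime")
         else H2prime ~ 1
    stats::lm(f, data = rows)
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  best <- which.min(aics)
  fit <- fits[[best]]

  marginal_r2 <- vapply(candidate_terms, function(v) {
    summary(stats::lm(stats::reformulate(v, "H2prime"), data = rows))$r.squared
  }, numeric(1))

  structure(list(
    selected_terms = candidates[[best]],
    formula = stats::formula(fit),
    coefficients = stats::coef(fit),
    AIC = aics[best],
    R2 = summary(fit)$r.squared,
    marginal_R2 = marginal_r2,
    pearson_r_fe = if ("prop_fe" %in% names(rows) &&
                       stats::var(rows$prop_fe) > 0 &&
                       stats::var(rows$H2prime) > 0)
      stats::cor(rows$H2prime, rows$prop_fe) else NA_real_,
    n_webs = nrow(rows),
    n_candidates = length(candidates),
    aic_table = data.frame(
      terms = vapply(candidates, function(tt)
        if (length(tt)) paste(tt, collapse = " + ") else "(intercept)",
        character(1)),
      AIC = aics)[order(aics), ],
    fit = fit), class = "h2_model_fit")
}

#' @export
print.h2_model_fit <- function(x, ...) {
  cat("H2' linear model (AIC selection over", x$n_candidates, "candidates)\n")
  cat("  selected:", if (length(x$selected_terms))
    paste(x$selected_terms, collapse = " + ") else "(intercept only)", "\n")
  cat(sprintf("  AIC = %.1f, R2 = %.4f, Pearson r(H2', prop_fe) = %.3f\n",
              x$AIC, x$R2, x$pearson_r_fe))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat("  marginal R2 per covariate:\n")
  print(round(x$marginal_R2, 4))
  invisible(x)
}
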