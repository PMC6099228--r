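#' Default generator configuration
#'
#' Returns the configuration of the hierarchical synthetic field survey:
#' 13 winter-wheat fields (7 in complex, 6 in simple landscapes), 8 plots of
#' 6 x 6 m per field with alternating fertilization, two sampling dates
#' (wheat milk and dough ripening), colony-level clustering of living aphids
#' (20-50 aphids/plot/date in ~4 collection tubes) and 5-15 mummies per
#' plot/date. Living-aphid endosymbiont infection probabilities default to
#' Hamiltonella defensa 0.401, Regiella insecticola 0.395 and superinfection
#' 0.0089 (combined 0.8049); mummies are generated from attacked aphids whose
#' immature parasitoid survives with relative odds `s_protect` (default
#' 0.153) in infected hosts, so the expected infected fraction among mummies
#' is `pi*s/(pi*s + 1 - pi)` = 0.387. Hyperparasitism probabilities depend on
#' infection class and sampling date, and hyperparasitoid taxa are drawn from
#' a primary-taxon association matrix that is sharpened for
#' endosymbiont-infected hosts (`hyper_concentration_fe`), which plants the
#' positive specialization-infection relationship the resampling engine
#' estimates.
#'
#' @return An object of class `symbioweb_config` (a named list).
#' @seealso [generate_study()], [validate_config()], [expected_rates()]
#' @export
default_config <- function() {
  comp_primary <- rbind(
    uninfected    = c(0.05, 0.05, 0.42, 0.05, 0.20, 0.75, 0.61, 0.53, 0.17, 0.52),
    Hd_only       = c(0.05, 0.05, 0.40, 0.05, 0.34, 1.11, 0.34, 0.63, 0.29, 0.81),
    Ri_only       = c(0.05, 0.05, 0.43, 0.05, 0.30, 0.82, 0.27, 0.20, 0.32, 0.70),
    superinfected = c(0.05, 0.05, 0.42, 0.05, 0.20, 0.75, 0.61, 0.53, 0.17, 0.52))
  colnames(comp_primary) <- PRIMARY_TAXA
  comp_primary <- comp_primary / rowSums(comp_primary)

  comp_hyper <- rbind(
    AEspp = c(0.10, 0.20, 0.10, 0.45, 0.15),
    APave = c(0.20, 0.10, 0.10, 0.45, 0.15),
    APerv = c(0.25, 0.10, 0.05, 0.50, 0.10),
    APmat = c(0.15, 0.15, 0.10, 0.45, 0.15),
    APrho = c(0.10, 0.10, 0.05, 0.60, 0.15),
    APuzb = c(0.15, 0.10, 0.10, 0.55, 0.10),
    APspp = c(0.20, 0.10, 0.05, 0.55, 0.10),
    EPpla = c(0.10, 0.25, 0.15, 0.35, 0.15),
    PRabj = c(0.10, 0.15, 0.10, 0.30, 0.35),
    PRvol = c(0.05, 0.15, 0.10, 0.30, 0.40))
  colnames(comp_hyper) <- HYPER_TAXA

  p_hyper <- rbind(
    uninfected    = c(0.16, 0.22),
    Hd_only       = c(0.15, 0.08),
    Ri_only       = c(0.09, 0.08),
    superinfected = c(0.12, 0.08))
  colnames(p_hyper) <- c("date1", "date2")

  cfg <- list(
    n_fields_complex = 7L,
    n_fields_simple = 6L,
    plots_per_field = 8L,
    colonies_per_plot_date = 4L,
    aphids_per_plot_date = c(20L, 50L),
    mummies_per_plot_date = c(5L, 15L),
    pi_hd = 0.401,
    pi_ri = 0.395,
    pi_super = 0.0089,
    sigma_field = 0.3,
    sigma_plot = 0.2,
    sigma_colony = 0.4,
    p_attack = c(uninfected = 0.115, Hd_only = 0.130,
                 Ri_only = 0.095, superinfected = 0.115),
    oviposition_avoidance = 1.0,
    s_protect = 0.153,
    fert_protect_boost = 1.0,
    p_mummy_primary_detect = 0.85,
    composition_primary = comp_primary,
    p_hyper = p_hyper,
    composition_hyper = comp_hyper,
    hyper_concentration_fe = 3.0)
  class(cfg) <- "symbioweb_config"
  cfg
}

#' Validate a generator configuration
#'
#' @param config A `symbioweb_config` list.
#' @return The config, invisibly, or an error describing the first violated
#'   constraint.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  p <- c(config$pi_hd, config$pi_ri, config$pi_super, config$p_attack,
         config$p_hyper, config$s_protect, config$p_mummy_primary_detect)
  if (any(p < 0 | p > 1)) stop("config validation error: probability outside [0, 1]")
  if (config$pi_hd + config$pi_ri + config$pi_super > 1)
    stop("config validation error: pi_hd + pi_ri + pi_super exceeds 1")
  if (config$s_protect <= 0)
    stop("config validation error: s_protect must be in (0, 1]")
  if (config$fert_protect_boost <= 0)
    stop("config validation error: fert_protect_boost must be positive")
  if (any(c(config$sigma_field, config$sigma_plot, config$sigma_colony) < 0))
    stop("config validation error: negative random-effect standard deviation")
  for (nm in c("composition_primary", "composition_hyper")) {
    rs <- rowSums(config[[nm]])
    if (any(config[[nm]] < 0) || any(abs(rs - 1) > 1e-8))
      stop("config validation error: ", nm, " rows must be probability vectors summing to 1")
  }
  if (any(config$aphids_per_plot_date < 1) || any(config$mummies_per_plot_date < 0))
    stop("config validation error: bad per-plot sample-size range")
  invisible(config)
}

#' Remove the primary-hyperparasitoid association from a configuration
#'
#' Sets every row of the hyperparasitoid association matrix to the common
#' mean profile and switches off the infection-dependent concentration, so
#' that hyperparasitoid taxa are drawn independently of the primary taxon and
#' of endosymbiont infection. Used for null-behaviour checks of the
#' resampling engine.
#'
#' @param config A `symbioweb_config`.
#' @return The modified config.
#' @export
config_no_association <- function(config = default_config()) {
  mean_row <- colMeans(config$composition_hyper)
  config$composition_hyper[] <- rep(mean_row, each = nrow(config$composition_hyper))
  config$hyper_concentration_fe <- 1.0
  config
}

#' Closed-form expected infection rates under the generator
#'
#' The combined living-aphid infection probability is `pi = pi_hd + pi_ri +
#' pi_super`. Because mummification requires the immature parasitoid to
#' survive, and survival odds are multiplied by `s` in infected hosts, the
#' expected infected fraction among mummies is `pi * s / (pi * s + 1 - pi)`.
#'
#' @param config A `symbioweb_config`.
#' @return Named vector with `living` and `mummy` expected combined
#'   facultative-endosymbiont infection rates (mummy rate averaged over the
#'   fertilized and unfertilized halves of the design).
#' @export
expected_rates <- function(config = default_config()) {
  pi_tot <- config$pi_hd + config$pi_ri + config$pi_super
  s_u <- config$s_protect
  s_f <- config$s_protect * config$fert_protect_boost
  mummy <- mean(c(expected_mummy_infection(pi_tot, s_u),
                  expected_mummy_infection(pi_tot, s_f)))
  c(living = pi_tot, mummy = mummy)
}

#' @rdname expected_rates
#' @param pi_living Combined infection probability of living aphids.
#' @param s Survival ratio of immature parasitoids in infected vs uninfected
#'   hosts.
#' @export
expected_mummy_infection <- function(pi_living, s) {
  pi_living * s / (pi_living * s + 1 - pi_living)
}

# mean shift so that E[plogis(mu + sigma*Z)] equals the target probability;
# keeps the marginal infection rate calibrated under logit-normal effects
calibrate_logit_mean <- function(p, sigma) {
  if (sigma == 0) return(stats::qlogis(p))
  f <- function(mu) {
    stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(f, c(stats::qlogis(p) - 3 * sigma - 1, stats::qlogis(p) + 3 * sigma + 1),
                 tol = 1e-10)$root
}

# sharpen a probability row: raise to power gamma and renormalize
concentrate <- function(p, gamma) {
  q <- p^gamma
  q / sum(q)
}

# uniform integer draw on [lo, hi], safe for degenerate ranges
sample_range <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Generate a synthetic hierarchical field study
#'
#' Simulates individual-level records of the full study design. Fields get
#' landscape labels; logit-normal random effects at field, plot and colony
#' level perturb the combined infection probability (the logit mean is
#' calibrated so the marginal infection rate matches the configured value);
#' each living aphid draws an infection class, a Bernoulli primary-parasitoid
#' detection with class-specific probability, and a primary taxon from the
#' class-specific composition. Mummies are drawn from the attacked-aphid
#' stream with survival odds multiplied by `s_protect` for infected hosts
#' (and additionally by `fert_protect_boost` in fertilized plots), so mummies
#' under-represent infection. Hyperparasitism on parasitized samples follows
#' class- and date-specific probabilities; the hyperparasitoid taxon is drawn
#' from the primary-taxon association row, sharpened by
#' `hyper_concentration_fe` for infected hosts. Fully reproducible from
#' `seed`.
#'
#' @param config A `symbioweb_config`, validated before any draws.
#' @param seed Integer seed.
#' @return A classified sample-record data frame (see [classify_samples()]).
#' @export
generate_study <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  with_seed(seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  pi_tot <- cfg$pi_hd + cfg$pi_ri + cfg$pi_super
  class_share <- c(uninfected = 1 - pi_tot, Hd_only = cfg$pi_hd,
                   Ri_only = cfg$pi_ri, superinfected = cfg$pi_super)
  sigma_tot <- sqrt(cfg$sigma_field^2 + cfg$sigma_plot^2 + cfg$sigma_colony^2)
  mu0 <- calibrate_logit_mean(pi_tot, sigma_tot)
  # mummy-stream logit means: the survival tilt (odds multiplied by s) is
  # applied on the calibrated marginal scale, so the closed-form expectation
  # pi*s/(pi*s + 1 - pi) holds exactly under colony heterogeneity
  mu_mum <- vapply(c(unfert = 1, fert = cfg$fert_protect_boost), function(bst)
    calibrate_logit_mean(expected_mummy_infection(pi_tot, cfg$s_protect * bst),
                         sigma_tot), numeric(1))
  classes <- names(class_share)

  n_fields <- cfg$n_fields_complex + cfg$n_fields_simple
  field_ids <- c(sprintf("C%d", seq_len(cfg$n_fields_complex)),
                 sprintf("S%d", seq_len(cfg$n_fields_simple)))
  landscapes <- rep(c("complex", "simple"),
                    c(cfg$n_fields_complex, cfg$n_fields_simple))

  # sharpened hyper-association rows for infected hosts
  comp_hyper_fe <- t(apply(cfg$composition_hyper, 1, concentrate,
                           gamma = cfg$hyper_concentration_fe))
  colnames(comp_hyper_fe) <- colnames(cfg$composition_hyper)
  mean_hyper <- colMeans(cfg$composition_hyper)
  mean_hyper_fe <- concentrate(mean_hyper, cfg$hyper_concentration_fe)

  draw_taxon <- function(n, prob, labels) labels[sample.int(length(labels), n,
                                                            replace = TRUE, prob = prob)]
  rows <- vector("list", n_fields * cfg$plots_per_field * 2L)
  k <- 0L
  for (f in seq_len(n_fields)) {
    u_f <- stats::rnorm(1, 0, cfg$sigma_field)
    for (p in seq_len(cfg$plots_per_field)) {
      u_p <- stats::rnorm(1, 0, cfg$sigma_plot)
      fert <- (p %% 2L) == 1L  # alternating, 4 fertilized per field
      mu_m <- mu_mum[[if (fert) "fert" else "unfert"]]
      for (d in 1:2) {
        n_col <- cfg$colonies_per_plot_date
        u_c <- stats::rnorm(n_col, 0, cfg$sigma_colony)
        pi_col <- stats::plogis(mu0 + u_f + u_p + u_c)
        pi_col_m <- stats::plogis(mu_m + u_f + u_p + u_c)
        n_liv <- sample_range(cfg$aphids_per_plot_date[1], cfg$aphids_per_plot_date[2])
        colony_of <- sample.int(n_col, n_liv, replace = TRUE)
        n_mum <- sample_range(cfg$mummies_per_plot_date[1], cfg$mummies_per_plot_date[2])
        colony_of_m <- sample.int(n_col, n_mum, replace = TRUE)

        # class probabilities per colony: total infection tilted by the
        # random effect, relative class shares fixed
        cls_prob <- function(pi_c) c(1 - pi_c, pi_c * class_share[2:4] / pi_tot)

        sim_unit <- function(n, colony_idx, mummy) {
          if (n == 0L) return(NULL)
          pvec <- if (mummy) pi_col_m else pi_col
          cls <- character(n)
          for (i in seq_len(n)) {
            pr <- cls_prob(pvec[colony_idx[i]])
            cls[i] <- classes[sample.int(4L, 1L, prob = pr)]
          }
          infected <- cls != "uninfected"
          primary <- character(n)
          hyper <- character(n)
          if (mummy) {
            det <- stats::runif(n) < cfg$p_mummy_primary_detect
            for (i in seq_len(n)) if (det[i])
              primary[i] <- draw_taxon(1L, cfg$composition_primary[cls[i], ], PRIMARY_TAXA)
            hyp <- stats::runif(n) < cfg$p_hyper[cls, d]
            for (i in seq_len(n)) if (hyp[i]) {
              prob <- if (nzchar(primary[i])) {
                if (infected[i]) comp_hyper_fe[primary[i], ] else cfg$composition_hyper[primary[i], ]
              } else if (infected[i]) mean_hyper_fe else mean_hyper
              hyper[i] <- draw_taxon(1L, prob, HYPER_TAXA)
            }
          } else {
            p_att <- cfg$p_attack[cls]
            p_att[infected] <- p_att[infected] * cfg$oviposition_avoidance
            att <- stats::runif(n) < p_att
            for (i in seq_len(n)) if (att[i])
              primary[i] <- draw_taxon(1L, cfg$composition_primary[cls[i], ], PRIMARY_TAXA)
            hyp <- att & stats::runif(n) < cfg$p_hyper[cls, d]
            for (i in seq_len(n)) if (hyp[i]) {
              prob <- if (infected[i]) comp_hyper_fe[primary[i], ] else cfg$composition_hyper[primary[i], ]
              hyper[i] <- draw_taxon(1L, prob, HYPER_TAXA)
            }
          }
          hd <- cls %in% c("Hd_only", "superinfected")
          ri <- cls %in% c("Ri_only", "superinfected")
          data.frame(
            sample_id = sprintf("%s_P%d_d%d_%s%03d", field_ids[f], p, d,
                                if (mummy) "M" else "L", seq_len(n)),
            field_id = field_ids[f], landscape = landscapes[f],
            plot_id = sprintf("P%d", p), fertilized = fert, date = d,
            colony_id = sprintf("T%d", colony_idx),
            status = if (mummy) "mummy" else "living",
            endo_hd = as.integer(hd), endo_ri = as.integer(ri),
            endo_paxs = 0L,
            primary_species = primary, hyper_species = hyper,
            stringsAsFactors = FALSE)
        }
        k <- k + 1L
        rows[[k]] <- rbind(sim_unit(n_liv, colony_of, mummy = FALSE),
                           sim_unit(n_mum, colony_of_m, mummy = TRUE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  classify_samples(out)
}

#' Serialize / read a generator configuration as YAML
#'
#' @param config A `symbioweb_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$composition_primary <- as.data.frame(x$composition_primary)
  x$composition_hyper <- as.data.frame(x$composition_hyper)
  x$p_hyper <- as.data.frame(x$p_hyper)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("composition_primary", "composition_hyper", "p_hyper")) {
    m <- as.matrix(as.data.frame(x[[nm]]))
    rownames(m) <- switch(nm,
      composition_primary = c("uninfected", "Hd_only", "Ri_only", "superinfected"),
      composition_hyper = PRIMARY_TAXA,
      p_hyper = c("uninfected", "Hd_only", "Ri_only", "superinfected"))
    x[[nm]] <- m
  }
  x$p_attack <- stats::setNames(unlist(x$p_attack),
                                c("uninfected", "Hd_only", "Ri_only", "superinfected"))
  for (nm in c("n_fields_complex", "n_fields_simple", "plots_per_field",
               "colonies_per_plot_date"))
    x[[nm]] <- as.integer(x[[nm]])
  for (nm in c("aphids_per_plot_date", "mummies_per_plot_date"))
    x[[nm]] <- as.integer(unlist(x[[nm]]))
  class(x) <- "symbioweb_config"
  validate_config(x)
  x
}

#' @export
print.symbioweb_config <- function(x, ...) {
  er <- expected_rates(x)
  cat("symbioweb generator config:",
      x$n_fields_complex + x$n_fields_simple, "fields,",
      x$plots_per_field, "plots/field, 2 dates\n")
  cat(sprintf("  living infection pi = %.4f (Hd %.3f, Ri %.3f, super %.4f)\n",
              er["living"], x$pi_hd, x$pi_ri, x$pi_super))
  cat(sprintf("  s_protect = %.3f -> expected mummy infection %.3f\n",
              x$s_protect, er["mummy"]))
  invisible(x)
}
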