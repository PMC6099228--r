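#' Assemble a pipeline run configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it and logged in the manifest.
#' @param input Optional path to a sample CSV; if `NULL`, samples are
#'   generated from `generator`.
#' @param generator A `symbioweb_config` for synthetic input.
#' @param stages Character subset of `c("rates", "community", "webs")`;
#'   classification always runs.
#' @param B Bootstrap replicates for the rates stage.
#' @param n_perm Permutations for SIMPER and dbRDA.
#' @param n_webs,web_size Resampling-engine parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, input = NULL,
                       generator = default_config(),
                       stages = c("rates", "community", "webs"),
                       B = 2000L, n_perm = 1000L,
                       n_webs = 10000L, web_size = 100L) {
  stages <- match.arg(stages, c("rates", "community", "webs"),
                      several.ok = TRUE)
  structure(list(outdir = outdir, seed = as.integer(seed), input = input,
                 generator = generator, stages = stages, B = B,
                 n_perm = n_perm, n_webs = n_webs, web_size = web_size),
            class = "run_config")
}

stage_seed <- function(master, k) as.integer((master + k * 10007L) %% 2147483647L)

#' Run the full analysis pipeline
#'
#' Executes generate/load -> classify -> rates -> community -> webs with a
#' single master seed, writing each stage's tables plus a JSON manifest
#' (seed, per-stage seeds, parameters, output files, timings) to the output
#' directory. Reruns with the same configuration are bit-identical. A stage
#' failure halts the run with a stage-scoped error; outputs of completed
#' stages are retained and the manifest marks the run incomplete.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("symbioweb")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   master_seed = config$seed,
                   parameters = config[c("B", "n_perm", "n_webs", "web_size")],
                   stages_requested = config$stages,
                   stages_completed = character(0),
                   complete = FALSE, files = list(), timings = list())
  results <- list()
  current_stage <- "input"
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  finish_stage <- function(name, t0, files) {
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    manifest$timings[[name]] <<- round(as.numeric(Sys.time()) - t0, 2)
    manifest$files[[name]] <<- files
  }
  run <- function() {
    t0 <- as.numeric(Sys.time())
    samples <- if (!is.null(config$input)) read_samples(config$input)
               else generate_study(config$generator, seed = stage_seed(config$seed, 1L))
    samples <- classify_samples(samples)
    write_samples(samples, out("samples_classified.tsv"))
    results$samples <<- samples
    finish_stage("classify", t0, "samples_classified.tsv")

    if ("rates" %in% config$stages) {
      current_stage <<- "rates"
      t0 <- as.numeric(Sys.time())
      est <- estimate_rates(samples, outcome = "fe_infected",
                            group_by = c("parasitism_class", "fertilized"),
                            B = config$B, seed = stage_seed(config$seed, 2L))
      ctr <- contrast_rates(est)
      utils::write.table(est, out("rates_fe_infection.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(ctr, out("rate_contrasts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results$rates <<- est
      results$contrasts <<- ctr
      finish_stage("rates", t0, c("rates_fe_infection.tsv", "rate_contrasts.tsv"))
    }

    if ("community" %in% config$stages) {
      current_stage <<- "community"
      t0 <- as.numeric(Sys.time())
      tab <- build_abundance_table(samples)
      write_abundance_table(tab, out("abundance_table.tsv"))
      D <- bray_curtis(tab)
      X <- data.frame(infection = factor(tab$units$infection),
                      date = factor(tab$units$date))
      Z <- data.frame(fertilized = tab$units$fertilized,
                      landscape = factor(tab$units$landscape))
      ord <- dbrda_bc(D, X, Z, n_perm = config$n_perm,
                      seed = stage_seed(config$seed, 3L))
      jsonlite::write_json(
        list(constrained_proportion = ord$constrained_proportion,
             conditioned_proportion = ord$conditioned_proportion,
             pseudo_F = ord$pseudo_F, df_model = ord$df_model,
             df_residual = ord$df_residual,
             permutation_p = ord$permutation_p,
             negative_inertia = ord$negative_inertia),
        out("dbrda.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
      # pairwise SIMPER between infection classes, as in the headline table
      cls <- intersect(c("uninfected", "Hd_only", "Ri_only"),
                       unique(tab$units$infection))
      simper_rows <- list()
      sp_seed <- stage_seed(config$seed, 4L)
      for (i in seq_along(cls)) for (j in seq_along(cls)) if (i < j) {
        keep <- tab$units$infection %in% c(cls[i], cls[j])
        sm <- simper_bc(tab$counts[keep, , drop = FALSE],
                        tab$units$infection[keep], n_perm = config$n_perm,
                        seed = sp_seed)
        sm <- cbind(group_a = cls[i], group_b = cls[j], as.data.frame(sm))
        simper_rows[[length(simper_rows) + 1L]] <- sm
      }
      simper_all <- do.call(rbind, simper_rows)
      utils::write.table(simper_all, out("simper.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results$abundance <<- tab
      results$dbrda <<- ord
      results$simper <<- simper_all
      finish_stage("community", t0,
                   c("abundance_table.tsv", "dbrda.json", "simper.tsv"))
    }

    if ("webs" %in% config$stages) {
      current_stage <<- "webs"
      t0 <- as.numeric(Sys.time())
      inter <- extract_interactions(samples)
      webs <- resample_webs(inter, n_webs = config$n_webs,
                            web_size = config$web_size,
                            seed = stage_seed(config$seed, 5L))
      fit <- fit_h2_model(webs)
      utils::write.table(webs, out("webs.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(
        list(selected_terms = fit$selected_terms,
             coefficients = as.list(fit$coefficients),
             AIC = fit$AIC, R2 = fit$R2,
             marginal_R2 = as.list(fit$marginal_R2),
             pearson_r_fe = fit$pearson_r_fe, n_webs = fit$n_webs),
        out("h2_model.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
      results$webs <<- webs
      results$h2_model <<- fit
      finish_stage("webs", t0, c("webs.tsv", "h2_model.json"))
    }
  }
  ok <- tryCatch({ run(); TRUE }, error = function(e) {
    manifest$error <<- list(stage = current_stage, message = conditionMessage(e))
    write_manifest()
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  manifest$complete <- TRUE
  write_manifest()
  results$manifest <- manifest
  invisible(results)
}
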