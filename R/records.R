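#' Read individual-level sample records
#'
#' Reads a delimited text file with one row per screened aphid or mummy and
#' validates it against the package's controlled vocabularies. The canonical
#' columns are `sample_id`, `field_id`, `landscape` (complex/simple),
#' `plot_id`, `fertilized` (0/1), `date` (1 = milk ripening, 2 = dough
#' ripening), `colony_id` (collection tube), `status` (living/mummy),
#' `endo_hd`, `endo_ri`, `endo_paxs` (0/1 detection flags), and
#' `primary_species` / `hyper_species` as semicolon-separated token lists
#' (empty cell = nothing detected).
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param sep Field delimiter, `","` by default.
#' @return A data frame of validated sample records, row order preserved.
#' @export
read_samples <- function(path, sep = ",") {
  if (!file.exists(path)) stop("sample file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL,
                          fileEncoding = "UTF-8")
  validate_samples(df)
}

#' Write sample records to delimited text
#'
#' @param samples A sample-record data frame.
#' @param path Output path.
#' @param sep Field delimiter (tab by default).
#' @export
write_samples <- function(samples, path, sep = "\t") {
  out <- samples
  out$fertilized <- as.integer(out$fertilized)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

SAMPLE_COLUMNS <- c("sample_id", "field_id", "landscape", "plot_id",
                    "fertilized", "date", "colony_id", "status",
                    "endo_hd", "endo_ri", "endo_paxs",
                    "primary_species", "hyper_species")

validate_samples <- function(df) {
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  df <- df[c(SAMPLE_COLUMNS, setdiff(names(df), SAMPLE_COLUMNS))]
  n <- nrow(df)
  bad_row <- function(what, rows)
    stop(what, " in row(s) ", paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) " ...", call. = FALSE)

  ls <- tolower(trimws(df$landscape))
  if (any(!ls %in% c("complex", "simple")))
    bad_row("unknown landscape value", which(!ls %in% c("complex", "simple")))
  df$landscape <- ls

  st <- tolower(trimws(df$status))
  if (any(!st %in% c("living", "mummy")))
    bad_row("parse error: conflicting status token", which(!st %in% c("living", "mummy")))
  df$status <- st

  fert <- tolower(trimws(df$fertilized))
  ok <- fert %in% c("0", "1", "true", "false")
  if (any(!ok)) bad_row("unreadable fertilized flag", which(!ok))
  df$fertilized <- fert %in% c("1", "true")

  dt <- suppressWarnings(as.integer(df$date))
  if (any(is.na(dt) | !dt %in% 1:2)) bad_row("sampling date must be 1 or 2",
                                             which(is.na(dt) | !dt %in% 1:2))
  df$date <- dt

  for (col in c("endo_hd", "endo_ri", "endo_paxs")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (any(is.na(v) | !v %in% 0:1)) bad_row(paste0(col, " must be 0/1"),
                                             which(is.na(v) | !v %in% 0:1))
    df[[col]] <- v
  }

  check_tokens <- function(col, vocab) {
    toks <- split_species(df[[col]])
    bad <- vapply(toks, function(v) any(!v %in% vocab), logical(1))
    if (any(bad)) {
      rows <- which(bad)
      offenders <- unique(unlist(lapply(toks[rows], setdiff, y = vocab)))
      stop("vocabulary error: unknown ", col, " token(s) ",
           paste(offenders, collapse = ", "), " in row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "), call. = FALSE)
    }
    vapply(toks, paste, character(1), collapse = ";")
  }
  df$primary_species <- check_tokens("primary_species", PRIMARY_TAXA)
  df$hyper_species <- check_tokens("hyper_species", HYPER_TAXA)
  rownames(df) <- NULL
  df
}

#' Classify samples by parasitism and endosymbiont infection
#'
#' Applies the operational definitions used throughout the analysis:
#' primary parasitism is the molecular detection of a primary parasitoid in a
#' living aphid, and a mummy is parasitized by definition (whether or not a
#' primary taxon amplified). Infection classes are derived from the
#' Hamiltonella defensa (Hd) and Regiella insecticola (Ri) flags; PAXS is
#' carried in the schema but ignored for classing (it was never detected).
#' Hyperparasitism is the detection of a hyperparasitoid in a
#' primary-parasitized aphid or mummy; hyperparasitoid tokens on living
#' unparasitized aphids do not count as hyperparasitism.
#'
#' @param samples A sample-record data frame (see [read_samples()]).
#' @return The input with added columns `parasitism_class`
#'   (living_unparasitized / living_parasitized / mummy), `infection_class`
#'   (uninfected / Hd_only / Ri_only / superinfected), and logicals
#'   `fe_infected`, `primary_parasitized`, `hyperparasitized`.
#' @export
classify_samples <- function(samples) {
  samples <- validate_samples(samples)
  has_primary <- nzchar(samples$primary_species)
  has_hyper <- nzchar(samples$hyper_species)
  mummy <- samples$status == "mummy"

  pc <- ifelse(mummy, "mummy",
               ifelse(has_primary, "living_parasitized", "living_unparasitized"))
  samples$parasitism_class <- factor(pc, levels = c("living_unparasitized",
                                                    "living_parasitized", "mummy"))
  hd <- samples$endo_hd == 1L
  ri <- samples$endo_ri == 1L
  ic <- ifelse(hd & ri, "superinfected",
               ifelse(hd, "Hd_only", ifelse(ri, "Ri_only", "uninfected")))
  samples$infection_class <- factor(ic, levels = c("uninfected", "Hd_only",
                                                   "Ri_only", "superinfected"))
  samples$fe_infected <- hd | ri
  samples$primary_parasitized <- mummy | has_primary
  samples$hyperparasitized <- samples$primary_parasitized & has_hyper
  samples
}

#' Build a community abundance table with occurrence filters
#'
#' Aggregates parasitoid detections (all 15 taxa, primary and hyperparasitoid)
#' into a community unit x species count matrix. The default community unit is
#' plot x sampling date x infection class. Two inclusion filters are applied,
#' both with strict inequalities: species observed more than
#' `min_species_occurrence` times are kept, and plots with more than
#' `min_plot_samples` molecularly analysed individuals are kept. Superinfected
#' samples are removed before aggregation unless `exclude_superinfected` is
#' `FALSE`. All-zero units remaining after filtering are dropped.
#'
#' @param samples A classified sample-record data frame
#'   ([classify_samples()] is applied if the derived columns are absent).
#' @param unit_by Character vector of unit-defining keys among
#'   `"plot"`, `"date"`, `"infection"`.
#' @param exclude_superinfected Drop superinfected samples first (default TRUE).
#' @param min_species_occurrence Keep species with total occurrence strictly
#'   greater than this (default 5).
#' @param min_plot_samples Keep plots with strictly more analysed individuals
#'   than this (default 3).
#' @return An object of class `abundance_table`: a list with `counts`
#'   (integer matrix, units x species), `units` (per-unit covariates: field,
#'   plot, date, infection class, fertilization, landscape) and a `log` of
#'   dropped species/plots/samples.
#' @export
build_abundance_table <- function(samples,
                                  unit_by = c("plot", "date", "infection"),
                                  exclude_superinfected = TRUE,
                                  min_species_occurrence = 5L,
                                  min_plot_samples = 3L) {
  if (!nrow(samples)) stop("empty sample list")
  if (!"infection_class" %in% names(samples)) samples <- classify_samples(samples)
  unit_by <- match.arg(unit_by, c("plot", "date", "infection"), several.ok = TRUE)

  log <- list()
  if (exclude_superinfected) {
    drop <- samples$infection_class == "superinfected"
    log$superinfected_samples_removed <- sum(drop)
    samples <- samples[!drop, , drop = FALSE]
  }
  if (!nrow(samples)) stop("no samples left after removing superinfected individuals")

  # plot filter: > min_plot_samples analysed individuals per (field, plot)
  plot_key <- paste(samples$field_id, samples$plot_id, sep = ":")
  n_per_plot <- table(plot_key)
  keep_plots <- names(n_per_plot)[n_per_plot > min_plot_samples]
  log$plots_dropped <- setdiff(names(n_per_plot), keep_plots)
  log$samples_in_dropped_plots <- sum(!plot_key %in% keep_plots)
  keep <- plot_key %in% keep_plots
  samples <- samples[keep, , drop = FALSE]
  plot_key <- plot_key[keep]
  if (!nrow(samples)) stop("no plots pass the >", min_plot_samples, " analysed-individuals filter")

  taxa <- c(PRIMARY_TAXA, HYPER_TAXA)
  parts <- character(nrow(samples))
  unit_cols <- list()
  if ("plot" %in% unit_by) unit_cols$plot <- plot_key
  if ("date" %in% unit_by) unit_cols$date <- samples$date
  if ("infection" %in% unit_by) unit_cols$infection <- as.character(samples$infection_class)
  unit_key <- do.call(paste, c(unit_cols, sep = "|"))
  units <- sort(unique(unit_key))

  counts <- matrix(0L, nrow = length(units), ncol = length(taxa),
                   dimnames = list(units, taxa))
  toks <- Map(c, split_species(samples$primary_species),
              split_species(samples$hyper_species))
  ui <- match(unit_key, units)
  for (i in seq_along(toks)) {
    for (tk in toks[[i]]) counts[ui[i], tk] <- counts[ui[i], tk] + 1L
  }

  occ <- colSums(counts)
  keep_sp <- occ > min_species_occurrence
  log$species_dropped <- names(occ)[!keep_sp & occ > 0L]
  log$species_absent <- names(occ)[occ == 0L]
  counts <- counts[, keep_sp, drop = FALSE]
  if (!ncol(counts)) stop("no species pass the >", min_species_occurrence, " occurrence filter")

  keep_units <- rowSums(counts) > 0L
  log$empty_units_dropped <- sum(!keep_units)
  counts <- counts[keep_units, , drop = FALSE]
  if (!nrow(counts)) stop("abundance table is empty after filtering")

  first <- !duplicated(unit_key)
  meta <- data.frame(unit = unit_key[first],
                     field = samples$field_id[first],
                     plot = plot_key[first],
                     date = samples$date[first],
                     infection = as.character(samples$infection_class)[first],
                     fertilized = samples$fertilized[first],
                     landscape = samples$landscape[first],
                     n_samples = as.integer(table(unit_key)[unit_key[first]]),
                     stringsAsFactors = FALSE)
  if (!"date" %in% unit_by) meta$date <- NA_integer_
  if (!"infection" %in% unit_by) meta$infection <- NA_character_
  meta <- meta[match(rownames(counts), meta$unit), , drop = FALSE]
  rownames(meta) <- NULL

  structure(list(counts = counts, units = meta, log = log,
                 unit_by = unit_by,
                 filters = c(species = min_species_occurrence,
                             plot = min_plot_samples)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$counts), "community units x",
      ncol(x$counts), "species (unit =", paste(x$unit_by, collapse = " x "),
      ")\n", sep = " ")
  cat("  total detections:", sum(x$counts), "\n")
  if (length(x$log$species_dropped))
    cat("  species dropped (occurrence <=", x$filters[["species"]], "):",
        paste(x$log$species_dropped, collapse = ", "), "\n")
  if (length(x$log$plots_dropped))
    cat("  plots dropped (<=", x$filters[["plot"]], "samples):",
        length(x$log$plots_dropped), "\n")
  invisible(x)
}

#' Write an abundance table as wide TSV plus a covariate sidecar
#'
#' @param x An `abundance_table`.
#' @param path Output path for the counts; the unit covariates go to
#'   `<path>.units.tsv`.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(unit = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$units, paste0(path, ".units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
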