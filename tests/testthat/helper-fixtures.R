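# in-code fixtures shared across test files

# one hand-written sample row; override any field
make_sample <- function(sample_id = "s1", field_id = "C1",
                        landscape = "complex", plot_id = "P1",
                        fertilized = TRUE, date = 1L, colony_id = "T1",
                        status = "living", endo_hd = 0L, endo_ri = 0L,
                        endo_paxs = 0L, primary_species = "",
                        hyper_species = "") {
  data.frame(sample_id = sample_id, field_id = field_id,
             landscape = landscape, plot_id = plot_id,
             fertilized = fertilized, date = date, colony_id = colony_id,
             status = status, endo_hd = endo_hd, endo_ri = endo_ri,
             endo_paxs = endo_paxs, primary_species = primary_species,
             hyper_species = hyper_species, stringsAsFactors = FALSE)
}

make_samples <- function(...) do.call(rbind, list(...))

# small, fast generator configuration: same mechanisms, fewer individuals
small_config <- function(...) {
  cfg <- default_config()
  cfg$aphids_per_plot_date <- c(8L, 12L)
  cfg$mummies_per_plot_date <- c(2L, 4L)
  cfg$colonies_per_plot_date <- 2L
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

# interaction records built directly, bypassing sample generation
make_interactions <- function(primary, hyper, fe = FALSE, fert = FALSE,
                              cplx = FALSE, d2 = FALSE) {
  n <- max(length(primary), length(hyper))
  data.frame(primary_taxon = rep_len(primary, n),
             hyper_taxon = rep_len(hyper, n),
             fe_infected = rep_len(fe, n), fertilized = rep_len(fert, n),
             complex_landscape = rep_len(cplx, n), date2 = rep_len(d2, n),
             source_sample_id = sprintf("x%d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# any web realizing the given marginals (northwest-corner allocation);
# entropy bounds depend on the marginals only
web_from_marginals <- function(r, cc) {
  a <- matrix(0L, length(r), length(cc))
  i <- j <- 1L
  r <- as.numeric(r)
  cc <- as.numeric(cc)
  while (i <= length(r) && j <= length(cc)) {
    v <- min(r[i], cc[j])
    a[i, j] <- as.integer(v)
    r[i] <- r[i] - v
    cc[j] <- cc[j] - v
    if (r[i] == 0) i <- i + 1L
    if (j <= length(cc) && cc[j] == 0) j <- j + 1L
  }
  a
}

# integer partitions of m into at most k parts (decreasing order)
partitions_max_parts <- function(m, k) {
  rec <- function(m, k, maxv) {
    if (m == 0) return(list(integer(0)))
    if (k == 0) return(list())
    out <- list()
    for (v in seq_len(min(m, maxv))) {
      for (tail in rec(m - v, k - 1, v)) out <- c(out, list(c(v, tail)))
    }
    out
  }
  rec(m, k, m)
}
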