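test_that("sample files round-trip with order and multi-taxon cells preserved", {
  s <- make_samples(
    make_sample("a1", primary_species = "APrho;EPpla"),
    make_sample("a2", status = "mummy", endo_hd = 1L, hyper_species = "DEcar",
                primary_species = "APuzb"),
    make_sample("a3", endo_ri = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samples(s, path)
  back <- read_samples(path, sep = "\t")
  expect_identical(back$sample_id, c("a1", "a2", "a3"))
  expect_identical(back$primary_species, s$primary_species)
  expect_identical(back$fertilized, s$fertilized)
  # 2-element primary set parsed from the semicolon list
  expect_length(symbioweb:::split_species(back$primary_species[1])[[1]], 2L)
  # re-classification of a serialized-then-reparsed record is identical
  expect_identical(classify_samples(back)$infection_class,
                   classify_samples(s)$infection_class)
})

test_that("schema and vocabulary violations are reported with location", {
  s <- make_samples(make_sample("a1"), make_sample("a2", primary_species = "XYZ"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, path, sep = ",")
  expect_error(read_samples(path), "XYZ.*row.*2")
  s2 <- make_sample("a1")
  s2$status <- NULL
  expect_error(classify_samples(s2), "missing column.*status")
  expect_error(classify_samples(make_sample(status = "larva")),
               "status token")
})

test_that("parasitism and infection classes follow the operational definitions", {
  s <- make_samples(
    make_sample("a", primary_species = "APrho"),                      # living parasitized
    make_sample("b", endo_hd = 1L),                                   # living unparasitized, Hd
    make_sample("c", status = "mummy", endo_hd = 1L, endo_ri = 1L),   # mummy, superinfected
    make_sample("d", status = "mummy"),                               # mummy without amplified primary
    make_sample("e", endo_paxs = 1L))                                 # PAXS ignored for classing
  cl <- classify_samples(s)
  expect_equal(as.character(cl$parasitism_class),
               c("living_parasitized", "living_unparasitized", "mummy",
                 "mummy", "living_unparasitized"))
  expect_equal(as.character(cl$infection_class),
               c("uninfected", "Hd_only", "superinfected", "uninfected",
                 "uninfected"))
  # mummies count as primary-parasitized even without an amplified taxon
  expect_true(all(cl$primary_parasitized[cl$parasitism_class == "mummy"]))
  # hyperparasitoid token on a living unparasitized aphid is not hyperparasitism
  f <- classify_samples(make_sample(hyper_species = "DEcar"))
  expect_false(f$hyperparasitized)
})

test_that("abundance-table filters are strict, conservative and idempotent", {
  # one plot with exactly 3 samples (excluded), one with 7 (kept);
  # a species seen exactly 5 times (excluded) vs 6 times (kept)
  rows <- list()
  for (i in 1:3) rows[[length(rows) + 1]] <-
    make_sample(paste0("p3_", i), plot_id = "P9", primary_species = "APuzb")
  for (i in 1:7) rows[[length(rows) + 1]] <-
    make_sample(paste0("p7_", i), plot_id = "P1",
                primary_species = if (i <= 6) "APuzb" else "")
  for (i in 1:5) rows[[length(rows) + 1]] <-
    make_sample(paste0("q_", i), plot_id = "P1", colony_id = "T2",
                primary_species = "EPpla", date = 2L)
  s <- do.call(rbind, rows)
  tab <- build_abundance_table(s, min_species_occurrence = 5L)
  expect_false(any(grepl("P9", rownames(tab$counts))))   # = 3 analysed: dropped
  expect_false("EPpla" %in% colnames(tab$counts))        # occurrence 5: dropped
  expect_true("APuzb" %in% colnames(tab$counts))         # occurrence 6: kept
  expect_equal(sum(tab$counts), 6L)

  # conservation: retained + logged drops account for every detection
  total_detections <- sum(lengths(symbioweb:::split_species(s$primary_species)))
  dropped <- 3L + 5L  # P9 detections + EPpla occurrences in kept plots
  expect_equal(sum(tab$counts), total_detections - dropped)

  # single plot, single species, seen 6 times -> 1 x 1 table of 6
  one <- do.call(rbind, lapply(1:6, function(i)
    make_sample(paste0("o", i), primary_species = "APuzb")))
  t1 <- build_abundance_table(one)
  expect_equal(unname(as.vector(t1$counts)), 6L)
  expect_equal(dim(t1$counts), c(1L, 1L))

  # idempotence: re-applying the filters to the filtered table changes nothing
  refiltered <- tab$counts[, colSums(tab$counts) > 5L, drop = FALSE]
  refiltered <- refiltered[rowSums(refiltered) > 0L, , drop = FALSE]
  expect_identical(refiltered, tab$counts)
})

test_that("superinfected samples are excluded before aggregation on request", {
  rows <- lapply(1:8, function(i)
    make_sample(paste0("s", i), primary_species = "APuzb",
                endo_hd = if (i <= 2) 1L else 0L,
                endo_ri = if (i <= 2) 1L else 0L))
  s <- do.call(rbind, rows)
  with_super <- build_abundance_table(s, exclude_superinfected = FALSE)
  without <- build_abundance_table(s, exclude_superinfected = TRUE)
  expect_equal(sum(with_super$counts) - sum(without$counts), 2L)
  expect_equal(without$log$superinfected_samples_removed, 2L)
})
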