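#' Controlled species vocabulary
#'
#' The taxon codes recognized throughout the package: 10 primary-parasitoid
#' taxa (\emph{Aphelinus} spp. AEspp, \emph{Aphidius avenae} APave,
#' \emph{A. ervi} APerv, \emph{A. matricariae} APmat, \emph{A. rhopalosiphi}
#' APrho, \emph{A. uzbekistanicus} APuzb, \emph{Aphidius} spp. APspp,
#' \emph{Ephedrus plagiator} EPpla, \emph{Praon abjectum} PRabj,
#' \emph{P. volucre} PRvol) and 5 hyperparasitoid taxa (\emph{Alloxysta} spp.
#' ALspp, \emph{Asaphes vulgaris} ASvul, \emph{A. suspensus} ASsus,
#' \emph{Dendrocerus carpenteri} DEcar, \emph{Phaenoglyphis villosa} PHvil).
#'
#' @return A list with character vectors `primary` and `hyper`.
#' @export
#' @examples
#' species_vocabulary()$primary
species_vocabulary <- function() {
  list(primary = PRIMARY_TAXA, hyper = HYPER_TAXA)
}

PRIMARY_TAXA <- c("AEspp", "APave", "APerv", "APmat", "APrho",
                  "APuzb", "APspp", "EPpla", "PRabj", "PRvol")

HYPER_TAXA <- c("ALspp", "ASvul", "ASsus", "DEcar", "PHvil")

ENDO_TAXA <- c("Hd", "Ri", "PAXS")

# split a semicolon-delimited species cell into a token vector ("" -> none)
split_species <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(trimws(v))])
}

# temporarily set the RNG seed, restoring the caller's stream on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
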