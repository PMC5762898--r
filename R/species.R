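#' Default ten-species set for evenness-panel microcosms
#'
#' The stock design uses ten environmental bacterial strains drawn from four
#' phylum-level groups (Alpha-, Beta-, Gammaproteobacteria and Firmicutes).
#' Species ids are short genus-derived keys used as column names throughout
#' the pipeline.
#'
#' @return A data.frame with columns `species_id`, `name`, `phylum`
#'   (10 rows).
#' @export
#' @examples
#' default_species_set()
default_species_set <- function() {
  out <- data.frame(
    species_id = c("rhizobium", "delftia", "burkholderia", "aeromonas",
                   "serratia", "enterococcus", "bacillus_i", "clostridium",
                   "tissierella", "bacillus_ii"),
    name = c("Rhizobium sp.", "Delftia sp.", "Burkholderia sp.",
             "Aeromonas sp.", "Serratia sp.", "Enterococcus sp.",
             "Bacillus sp. (I)", "Clostridium sp.", "Tissierella sp.",
             "Bacillus sp. (II)"),
    phylum = c("Alphaproteobacteria", "Betaproteobacteria",
               "Betaproteobacteria", "Gammaproteobacteria",
               "Gammaproteobacteria", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes"),
    stringsAsFactors = FALSE
  )
  validate_species_set(out)
  out
}

#' @keywords internal
validate_species_set <- function(species) {
  stopifnot(is.data.frame(species),
            all(c("species_id", "name", "phylum") %in% names(species)))
  if (anyDuplicated(species$species_id))
    stop("species ids must be unique")
  ok <- species$phylum %in% c("Alphaproteobacteria", "Betaproteobacteria",
                              "Gammaproteobacteria", "Firmicutes")
  if (!all(ok))
    stop("unknown phylum: ", paste(unique(species$phylum[!ok]),
                                   collapse = ", "))
  invisible(species)
}
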