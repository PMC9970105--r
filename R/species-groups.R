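# Species pooling --------------------------------------------------------

# Lookup from lower-case species names/codes to the modelled groups. Ponderosa
# and Jeffrey pine are pooled to yellow pine; grand fir and white fir to white
# fir. Hardwoods keep their own group so the stand-level standardization
# filter can remove them.
.species_pool_table <- local({
  tbl <- c(
    # yellow pine
    "ponderosa pine" = "yellow_pine",
    "jeffrey pine" = "yellow_pine",
    "jeffery pine" = "yellow_pine",
    "pinus ponderosa" = "yellow_pine",
    "pinus jeffreyi" = "yellow_pine",
    "pipo" = "yellow_pine",
    "pije" = "yellow_pine",
    "yellow pine" = "yellow_pine",
    "yellow_pine" = "yellow_pine",
    # Douglas-fir
    "douglas-fir" = "douglas_fir",
    "douglas fir" = "douglas_fir",
    "pseudotsuga menziesii" = "douglas_fir",
    "psme" = "douglas_fir",
    "douglas_fir" = "douglas_fir",
    # white fir (incl. grand fir)
    "white fir" = "white_fir",
    "grand fir" = "white_fir",
    "abies concolor" = "white_fir",
    "abies grandis" = "white_fir",
    "abco" = "white_fir",
    "abgr" = "white_fir",
    "white_fir" = "white_fir",
    # western larch
    "western larch" = "western_larch",
    "larix occidentalis" = "western_larch",
    "laoc" = "western_larch",
    "western_larch" = "western_larch",
    # lodgepole pine
    "lodgepole pine" = "lodgepole_pine",
    "pinus contorta" = "lodgepole_pine",
    "pico" = "lodgepole_pine",
    "lodgepole_pine" = "lodgepole_pine",
    # named other conifers
    "incense cedar" = "other_conifer",
    "calocedrus decurrens" = "other_conifer",
    "cade" = "other_conifer",
    "western juniper" = "other_conifer",
    "juniperus occidentalis" = "other_conifer",
    "juoc" = "other_conifer",
    "sugar pine" = "other_conifer",
    "pinus lambertiana" = "other_conifer",
    "pila" = "other_conifer",
    "western white pine" = "other_conifer",
    "pinus monticola" = "other_conifer",
    "pimo" = "other_conifer",
    "engelmann spruce" = "other_conifer",
    "picea engelmannii" = "other_conifer",
    "pien" = "other_conifer",
    "subalpine fir" = "other_conifer",
    "abies lasiocarpa" = "other_conifer",
    "abla" = "other_conifer",
    "red fir" = "other_conifer",
    "abies magnifica" = "other_conifer",
    "abma" = "other_conifer",
    "mountain hemlock" = "other_conifer",
    "tsuga mertensiana" = "other_conifer",
    "tsme" = "other_conifer",
    "western hemlock" = "other_conifer",
    "tsuga heterophylla" = "other_conifer",
    "tshe" = "other_conifer",
    "western redcedar" = "other_conifer",
    "thuja plicata" = "other_conifer",
    "thpl" = "other_conifer",
    "other_conifer" = "other_conifer",
    "other conifer" = "other_conifer",
    # hardwoods
    "tanoak" = "hardwood",
    "notholithocarpus densiflorus" = "hardwood",
    "lide" = "hardwood",
    "bigleaf maple" = "hardwood",
    "big leaf maple" = "hardwood",
    "acer macrophyllum" = "hardwood",
    "acma" = "hardwood",
    "quaking aspen" = "hardwood",
    "populus tremuloides" = "hardwood",
    "potr" = "hardwood",
    "black cottonwood" = "hardwood",
    "populus trichocarpa" = "hardwood",
    "oregon white oak" = "hardwood",
    "quercus garryana" = "hardwood",
    "quga" = "hardwood",
    "red alder" = "hardwood",
    "alnus rubra" = "hardwood",
    "alru" = "hardwood",
    "pacific madrone" = "hardwood",
    "arbutus menziesii" = "hardwood",
    "arme" = "hardwood",
    "golden chinquapin" = "hardwood",
    "chrysolepis chrysophylla" = "hardwood",
    "willow" = "hardwood",
    "salix" = "hardwood",
    "hardwood" = "hardwood"
  )
  tbl
})

#' Pool species codes into modelled species groups
#'
#' Maps raw species names, scientific names, or 4-letter codes onto the
#' species groups used throughout the pipeline: ponderosa and Jeffrey pine are
#' combined into `"yellow_pine"`, grand fir and white fir into `"white_fir"`,
#' known hardwoods into `"hardwood"`, and any unrecognised code into
#' `"other_conifer"`. Matching is case-insensitive.
#'
#' @param code Character vector of species names or codes. Values already
#'   equal to a species group are passed through.
#' @return Character vector of species groups (one of
#'   `yellow_pine`, `douglas_fir`, `white_fir`, `western_larch`,
#'   `lodgepole_pine`, `other_conifer`, `hardwood`).
#' @export
#' @examples
#' pool_species(c("Jeffrey pine", "grand fir", "PSME", "mystery conifer"))
pool_species <- function(code) {
  key <- tolower(trimws(as.character(code)))
  out <- unname(.species_pool_table[key])
  out[is.na(out)] <- "other_conifer"
  out
}

#' Is a species group a hardwood?
#'
#' @param species_group Character vector of species groups (or raw codes,
#'   which are pooled first).
#' @return Logical vector.
#' @export
is_hardwood <- function(species_group) {
  grp <- ifelse(species_group %in% SPECIES_GROUPS, species_group,
    pool_species(species_group)
  )
  grp == "hardwood"
}

# Composition group for stand basal-area proportions: lodgepole and other
# conifers collapse into "other"; hardwoods never reach the stand stage.
comp_group <- function(species_group) {
  ifelse(species_group %in% c("yellow_pine", "douglas_fir", "white_fir", "western_larch"),
    species_group, "other"
  )
}
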