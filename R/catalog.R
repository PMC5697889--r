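#' Bundled glycoside hydrolase lignocellulose-category map
#'
#' Assigns GH families implicated in lignocellulose degradation to their role
#' in the degradation process: cellulases hydrolyse beta-1,4 linkages in
#' cellulose; endohemicellulases attack the hemicellulose backbone; accessory
#' hemicellulases remove side chains; oligosaccharide-degrading enzymes act on
#' the soluble products of both. Families outside the map are treated as
#' `other_gh` downstream, and auxiliary-activity (AA) families as
#' `auxiliary_activity`.
#'
#' @return Named character vector mapping GH family (e.g. `"GH5"`) to one of
#'   `"cellulase"`, `"endohemicellulase"`, `"accessory_hemicellulase"`,
#'   `"oligosaccharide_degrading"`.
#' @export
gh_category_map <- function() {
  c(
    GH5 = "cellulase", GH6 = "cellulase", GH7 = "cellulase",
    GH9 = "cellulase", GH44 = "cellulase", GH45 = "cellulase",
    GH48 = "cellulase",
    GH8 = "endohemicellulase", GH10 = "endohemicellulase",
    GH11 = "endohemicellulase", GH12 = "endohemicellulase",
    GH26 = "endohemicellulase", GH28 = "endohemicellulase",
    GH53 = "endohemicellulase",
    GH16 = "accessory_hemicellulase", GH17 = "accessory_hemicellulase",
    GH51 = "accessory_hemicellulase", GH54 = "accessory_hemicellulase",
    GH62 = "accessory_hemicellulase", GH67 = "accessory_hemicellulase",
    GH74 = "accessory_hemicellulase", GH78 = "accessory_hemicellulase",
    GH81 = "accessory_hemicellulase",
    GH1 = "oligosaccharide_degrading", GH2 = "oligosaccharide_degrading",
    GH3 = "oligosaccharide_degrading", GH29 = "oligosaccharide_degrading",
    GH35 = "oligosaccharide_degrading", GH38 = "oligosaccharide_degrading",
    GH39 = "oligosaccharide_degrading", GH42 = "oligosaccharide_degrading",
    GH43 = "oligosaccharide_degrading", GH52 = "oligosaccharide_degrading"
  )
}

#' Lignocellulose GH categories, in presentation order
#' @return Character vector of the four category labels.
#' @export
gh_categories <- function() {
  c("cellulase", "endohemicellulase", "accessory_hemicellulase",
    "oligosaccharide_degrading")
}

#' Construct a function catalog
#'
#' The catalog couples the KO -> pathway universe (KEGG metabolism hierarchy,
#' categories 1.1-1.11) with the GH -> lignocellulose-category map and the
#' minimum pathway size filter. A KO may belong to several pathways and is
#' assigned to all of them.
#'
#' @param ko_to_pathways Named list: KO id -> character vector of pathway ids.
#' @param pathway_category Optional named character vector: pathway id ->
#'   hierarchy label ("1.1".."1.11").
#' @param min_kos_per_pathway Pathways with fewer distinct observed KOs than
#'   this are excluded from cumulative profiles. Default 3.
#' @param gh_category Named character vector GH family -> category; defaults
#'   to the bundled map ([gh_category_map()]).
#' @return Object of class `function_catalog`.
#' @export
function_catalog <- function(ko_to_pathways = list(),
                             pathway_category = NULL,
                             min_kos_per_pathway = 3L,
                             gh_category = gh_category_map()) {
  stopifnot(is.list(ko_to_pathways), min_kos_per_pathway >= 1)
  if (length(ko_to_pathways) && is.null(names(ko_to_pathways)))
    stop("ko_to_pathways must be named by KO id")
  cat_ok <- c("cellulase", "endohemicellulase", "accessory_hemicellulase",
              "oligosaccharide_degrading", "auxiliary_activity", "other_gh")
  if (!all(gh_category %in% cat_ok))
    stop("unknown GH category label in gh_category")
  pathways <- sort(unique(unlist(ko_to_pathways, use.names = FALSE)))
  structure(
    list(ko_to_pathways = ko_to_pathways,
         pathway_category = pathway_category,
         pathways = pathways,
         min_kos_per_pathway = as.integer(min_kos_per_pathway),
         gh_category = gh_category),
    class = "function_catalog")
}

#' Invert a catalog to pathway -> KO members
#' @param catalog A `function_catalog`.
#' @return Named list pathway id -> character vector of member KOs.
#' @export
pathway_members <- function(catalog) {
  stopifnot(inherits(catalog, "function_catalog"))
  if (!length(catalog$ko_to_pathways)) return(list())
  ko <- rep(names(catalog$ko_to_pathways),
            lengths(catalog$ko_to_pathways))
  pw <- unlist(catalog$ko_to_pathways, use.names = FALSE)
  lapply(split(ko, pw), unique)
}

#' Classify a CAZy family label
#'
#' GH families in the bundled (or supplied) map get their lignocellulose
#' category; AA families are `auxiliary_activity`; any other GH family is
#' `other_gh`; non-GH, non-AA families are `not_gh`.
#'
#' @param family Character vector of CAZy family labels.
#' @param catalog A `function_catalog` (for its `gh_category` map).
#' @return Character vector of category labels.
#' @export
classify_cazy_family <- function(family, catalog = function_catalog()) {
  map <- catalog$gh_category
  out <- rep("not_gh", length(family))
  is_gh <- grepl("^GH", family)
  is_aa <- grepl("^AA", family)
  out[is_gh] <- "other_gh"
  out[is_aa] <- "auxiliary_activity"
  hit <- is_gh & family %in% names(map)
  out[hit] <- unname(map[family[hit]])
  out
}

#' Reference weighted GH profiles across lignocellulolytic biomes
#'
#' Per-family relative weighted profiles (percent of lignocellulolytic GHs)
#' for six communities: koala feces, wombat feces, wallaby foregut, cow rumen,
#' termite hindgut, and switchgrass-adapted compost. These are published
#' literature values shipped as a static reference table for cross-biome
#' comparison; they are not recomputed by this package.
#'
#' @return data.frame with columns `family`, `activity`, and one numeric
#'   column per biome.
#' @export
reference_gh_profiles <- function() {
  path <- system.file("extdata", "gh_weighted_profiles_reference.tsv",
                      package = "mgprofiler")
  read_tsv_checked(path, c("family", "activity"))
}

#' Default urea-processing KO sets
#'
#' Curated KO identifiers for the urea transport and hydrolysis machinery:
#' the five subunits of the Urt ABC-type urea transporter (UrtABCDE), the
#' monomeric Utp urea channel, the three structural urease subunits
#' (UreA/B/C), and the urease accessory proteins (UreD/E/F/G). The mapping is
#' an editable configuration, not a fixed constant: pass your own sets if
#' your annotation source uses different identifiers.
#'
#' @return Named list with elements `urt_subunits` (5 KOs), `utp` (1 KO),
#'   `urease_structural` (3 KOs), `urease_accessory`.
#' @export
urea_ko_config <- function() {
  list(
    urt_subunits = c("K11959", "K11960", "K11961", "K11962", "K11963"),
    utp = "K08717",
    urease_structural = c("K01428", "K01429", "K01430"),
    urease_accessory = c("K03187", "K03188", "K03189", "K03190")
  )
}

# BLOSUM62 substitution matrix (standard NCBI values), 25-letter alphabet.
blosum62_alphabet <- "ARNDCQEGHILKMFPSTWYVBJZX*"

#' BLOSUM62 substitution matrix
#' @return Integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  v <- c(
    4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,-2,-1,-1,-1,-4,
    -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,-1,-2,0,-1,-4,
    -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,4,-3,0,-1,-4,
    -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,4,-3,1,-1,-4,
    0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-1,-3,-1,-4,
    -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,0,-2,4,-1,-4,
    -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,1,-3,4,-1,-4,
    0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,-1,-4,-2,-1,-4,
    -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,0,-3,0,-1,-4,
    -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,-3,3,-3,-1,-4,
    -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,-4,3,-3,-1,-4,
    -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,0,-3,1,-1,-4,
    -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,-3,2,-1,-1,-4,
    -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,-3,0,-3,-1,-4,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,-2,-3,-1,-1,-4,
    1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,0,-2,0,-1,-4,
    0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,-1,-1,-1,-1,-4,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,-4,-2,-2,-1,-4,
    -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,-3,-1,-2,-1,-4,
    0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4,-3,2,-2,-1,-4,
    -2,-1,4,4,-3,0,1,-1,0,-3,-4,0,-3,-3,-2,0,-1,-4,-3,-3,4,-3,0,-1,-4,
    -1,-2,-3,-3,-1,-2,-3,-4,-3,3,3,-3,2,0,-3,-2,-1,-2,-1,2,-3,3,-3,-1,-4,
    -1,0,0,1,-3,4,4,-2,0,-3,-3,1,-1,-3,-1,0,-1,-2,-2,-2,0,-3,4,-1,-4,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-4,
    -4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,1)
  a <- strsplit(blosum62_alphabet, "")[[1]]
  matrix(as.integer(v), 25, 25, byrow = TRUE, dimnames = list(a, a))
}
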