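#' Packaged data fixtures
#'
#' The package ships, as plain-text files under `extdata/`:
#'
#' * the curated opsin-family presence matrix over the five terminal clades
#'   (Cnidaria, Xenacoelomorpha, Protostomia, Chordata, Ambulacraria), in two
#'   variants that differ in exactly one cell: the main matrix scores the
#'   xenacoelomorph xenopsins as `uncertain` (their sequences lack the K296
#'   lysine), the alternative scores that cell absent;
#' * the phototransduction-pathway presence matrix (18 fly-pathway and 18
#'   vertebrate-pathway KEGG orthologs by clade) together with its
#'   pathway/gene-name side table;
#' * a small synthetic demonstration alignment for the K296 residue check.
#'
#' @param name fixture file name (see `list_fixtures()`).
#' @return `fixture_path` returns the absolute path to an installed fixture.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "dollopsin")
  if (!nzchar(p)) stop("no packaged fixture named: ", name)
  p
}

#' @rdname fixture_path
#' @export
list_fixtures <- function() {
  dir(system.file("extdata", package = "dollopsin"))
}

#' Ordered identifiers of the opsin families in the packaged matrix
#' @return character vector of 11 family identifiers.
#' @export
opsin_families <- function() {
  c("anthozoa_I", "chaopsin", "xenopsin", "c_opsin", "r_opsin_canonical",
    "r_opsin_noncanonical", "go_opsin", "neuropsin", "rgr_retinochrome",
    "bathyopsin", "xeno_specific")
}

#' Packaged opsin-family presence matrix
#'
#' @param variant `"main"` (xenopsin uncertain in Xenacoelomorpha, the primary
#'   scoring) or `"xenopsin_absent"` (the alternative scoring).
#' @return a [presence_matrix()] of 11 families x 5 clades. In the main
#'   variant the (xenopsin, Xenacoelomorpha) cell carries the note
#'   `"lacks K296"`.
#' @export
opsin_matrix <- function(variant = c("main", "xenopsin_absent")) {
  variant <- match.arg(variant)
  m <- read_matrix(fixture_path(sprintf("opsin_presence_%s.tsv", variant)))
  if (variant == "main")
    m$notes["xenopsin", "Xenacoelomorpha"] <- "lacks K296"
  m
}

#' Packaged phototransduction-pathway presence matrix
#'
#' KEGG orthologs of the fly (rhabdomeric) and vertebrate (ciliary)
#' phototransduction cascades by clade. Row identifiers are
#' `"<pathway>:<KO>"` because one ortholog (K02183, calmodulin) belongs to
#' both pathways and is listed once under each.
#'
#' @return a [presence_matrix()] of 36 rows x 3 clades
#'   (Xenacoelomorpha, Chordata, Protostomia).
#' @export
phototransduction_matrix <- function() {
  read_matrix(fixture_path("phototransduction_table1.tsv"))
}

#' @rdname phototransduction_matrix
#' @return `phototransduction_partition` returns the side table assigning each
#'   matrix row to its pathway, with KEGG ortholog id and gene name
#'   (columns `family`, `pathway`, `ko`, `gene`).
#' @export
phototransduction_partition <- function() {
  utils::read.delim(fixture_path("phototransduction_pathways.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bovine rhodopsin reference sequence
#'
#' The 348-residue bovine rhodopsin used as the default reference for the
#' residue-homology check; its lysine 296 (ungapped, 1-based) is the
#' conserved retinal-binding site that gives functional opsins their name.
#'
#' @return a named character vector of length 1 (name `"BOVIN_OPSD"`), with
#'   attribute `position` = 296.
#' @export
bovine_rhodopsin <- function() {
  s <- paste0(
    "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLYVTVQHKKLRT",
    "PLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLGGEIALWSLVVLAIERYVVVC",
    "KPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIPEGMQCSCGIDYYTPHEETNNESFVIYMFVV",
    "HFIIPLIVIFFCYGQLVFTVKEAAAQQQESATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQG",
    "SDFGPIFMTIPAFFAKTSAVYNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA")
  structure(c(BOVIN_OPSD = s), position = 296L)
}

#' Export the packaged fixtures to a directory
#'
#' Copies every `extdata/` fixture and writes the two built-in species trees
#' as Newick files, so the shipped inputs can be inspected or fed back through
#' the file readers.
#'
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src <- vapply(list_fixtures(), fixture_path, "")
  dst <- file.path(dir, basename(src))
  file.copy(src, dst, overwrite = TRUE)
  for (h in c("nephrozoa", "xenambulacraria")) {
    p <- file.path(dir, paste0(h, ".nwk"))
    write_clade_tree(builtin_tree(h), p)
    dst <- c(dst, p)
  }
  invisible(dst)
}
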