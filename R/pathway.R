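#' Species-to-group mapping
#'
#' Assigns each species to one or more groups; an umbrella group (e.g.
#' Xenacoelomorpha over Acoela, Nemertodermatida and Xenoturbella) is simply
#' listed as an additional group for each member species, so umbrella
#' presence follows automatically from the aggregation rule.
#'
#' @param df data.frame with character columns `species` and `group`; one row
#'   per (species, group) membership. Every species must appear in at least
#'   one group.
#' @return object of class `group_map`.
#' @export
group_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("species", "group") %in% names(df)))
  if (nrow(df) == 0L) stop("empty group map")
  if (any(!nzchar(df$species)) || any(!nzchar(df$group)))
    stop("empty species or group id in group map")
  structure(df[c("species", "group")], class = c("group_map", "data.frame"))
}

#' Aggregate per-species annotations into clade-level presence
#'
#' Implements the concatenation rule used for clade-level pathway scoring:
#' annotation of a gene in a single member species suffices to score it
#' present for the whole group. Genes in `gene_universe` never annotated in
#' any member are absent.
#'
#' @param decisions data.frame with columns `species`, `ko`, `status`; rows
#'   with `status == "annotated"` carry presence.
#' @param groups a [group_map()].
#' @param gene_universe character vector of KO ids defining the matrix rows.
#' @return a [presence_matrix()] (KO x group), states `present`/`absent` only.
#' @export
aggregate_presence <- function(decisions, groups, gene_universe) {
  stopifnot(inherits(groups, "group_map"))
  ann <- decisions[decisions$status == "annotated", , drop = FALSE]
  unknown <- setdiff(unique(ann$species), unique(groups$species))
  if (length(unknown))
    stop("species not in group map: ", paste(unknown, collapse = ", "))
  gset <- sort(unique(groups$group))
  states <- matrix("absent", length(gene_universe), length(gset),
                   dimnames = list(gene_universe, gset))
  for (i in seq_len(nrow(ann))) {
    ko <- ann$ko[i]
    if (!ko %in% gene_universe) next
    for (g in groups$group[groups$species == ann$species[i]])
      states[ko, g] <- "present"
  }
  presence_matrix(states)
}

#' Pathway completeness report
#'
#' Counts, for every pathway and every clade column of the presence matrix,
#' how many member genes are present and which are missing. Uncertain cells
#' count as present (there are none in the packaged phototransduction matrix).
#'
#' @param matrix a [presence_matrix()] whose rows are pathway members.
#' @param partition data.frame assigning every matrix row to exactly one
#'   pathway: columns `family` and `pathway` (the packaged
#'   [phototransduction_partition()] also carries `ko` and `gene`). A gene
#'   belonging to two pathways appears as two matrix rows, one per pathway.
#' @return data.frame: `pathway`, `group`, `n_total`, `n_present`, `n_absent`,
#'   `absent` (comma-separated KO ids, using the `ko` column when available).
#' @export
pathway_report <- function(matrix, partition) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!all(c("family", "pathway") %in% names(partition)))
    stop("partition needs columns `family` and `pathway`")
  un <- setdiff(matrix$families, partition$family)
  if (length(un))
    stop("unpartitioned row(s): ", paste(un, collapse = ", "))
  if (anyDuplicated(partition$family))
    stop("row assigned to more than one pathway: ",
         partition$family[duplicated(partition$family)][1L])
  label <- if ("ko" %in% names(partition)) partition$ko else partition$family
  names(label) <- partition$family
  rows <- list()
  for (pw in unique(partition$pathway)) {
    fams <- partition$family[partition$pathway == pw]
    fams <- intersect(matrix$families, fams)
    for (g in matrix$clades) {
      st <- matrix$states[fams, g]
      st[st == "uncertain"] <- "present"
      absent <- fams[st == "absent"]
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, group = g,
        n_total = length(fams),
        n_present = sum(st == "present"),
        n_absent = length(absent),
        absent = paste(label[absent], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a Table-1-style pathway matrix as TSV
#'
#' One row per pathway member with its KO, one presence column per clade
#' (`X` present, `.` absent), and the gene name.
#'
#' @param matrix a [presence_matrix()].
#' @param partition as in [pathway_report()].
#' @param path output path.
#' @export
write_pathway_table <- function(matrix, partition, path) {
  idx <- match(matrix$families, partition$family)
  if (anyNA(idx)) stop("unpartitioned row(s)")
  sym <- ifelse(matrix$states == "absent", ".", "X")
  df <- data.frame(pathway = partition$pathway[idx],
                   ko = if ("ko" %in% names(partition)) partition$ko[idx]
                        else partition$family[idx],
                   sym,
                   gene = if ("gene" %in% names(partition)) partition$gene[idx]
                          else "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
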