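#' Pathway definition database for tiered annotation
#'
#' Maps each KEGG ortholog (KO) to the evidence sets the three annotation
#' tiers consult: reference protein accessions, canonical display names (with
#' an explicit list of ambiguous names that must never fire the name tier),
#' and sequence-cluster ids.
#'
#' @param entries named list (names = KO ids); each element a list with
#'   character vectors `accessions` (non-empty), `names`, `ambiguous`
#'   (optional) and `clusters` (optional).
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(entries) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("pathway_db entries must be named by KO id")
  for (ko in names(entries)) {
    e <- entries[[ko]]
    if (is.null(e$accessions) || length(e$accessions) == 0L)
      stop("configuration error: KO '", ko, "' has an empty accession set")
    entries[[ko]]$names <- e$names %||% character(0)
    entries[[ko]]$ambiguous <- e$ambiguous %||% character(0)
    entries[[ko]]$clusters <- e$clusters %||% character(0)
  }
  structure(entries, class = "pathway_db")
}

#' @rdname pathway_db
#' @param path JSON file: an object keyed by KO id, each value an object with
#'   arrays `accessions`, `names`, `ambiguous`, `clusters`.
#' @export
read_pathway_db <- function(path) {
  pathway_db(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Three-tier pathway annotation of best-hit tables
#'
#' Assigns each protein the first tier that fires, in strict precedence:
#'
#' 1. **accession** — the protein's best-hit accession is in a KO's accession
#'    set (automatic annotation);
#' 2. **name** — the best-hit display name matches a KO's canonical name
#'    exactly (case-insensitive) and is not listed as ambiguous; no fuzzy
#'    matching (e.g. a hit named "Adenosine receptor A2a" can be accepted
#'    while plain "adenosin A2" is configured as ambiguous and never fires);
#' 3. **cluster** — the best-hit cluster id is in the KO's cluster set, or
#'    matches the best-hit cluster of a protein already annotated at tiers
#'    1-2 for that KO (one non-iterative pass).
#'
#' Proteins firing no tier are reported `unresolved`.
#'
#' @param proteome_hits a `hit_table` already reduced to one best hit per
#'   protein ([best_hit_per_query()]).
#' @param db a [pathway_db()].
#' @param subjects subject metadata ([read_subject_metadata()] layout) for the
#'   hit subjects.
#' @return data.frame: `protein`, `status` (`annotated`/`unresolved`), `tier`
#'   (`accession`/`name`/`cluster` or `NA`), `ko`, `evidence`.
#' @export
kegg_tiered_annotation <- function(proteome_hits, db, subjects) {
  stopifnot(inherits(db, "pathway_db"))
  if (anyDuplicated(proteome_hits$qseqid))
    stop("proteome_hits must hold one best hit per protein; run best_hit_per_query() first")
  meta <- subjects[match(proteome_hits$sseqid, subjects$subject), , drop = FALSE]
  kos <- names(db)

  tier_of <- function(i) {
    acc <- meta$accession[i]; nm <- tolower(meta$name[i])
    for (ko in kos) {
      if (!is.na(acc) && acc %in% db[[ko]]$accessions)
        return(list(tier = "accession", ko = ko,
                    evidence = sprintf("best hit %s accession %s",
                                       proteome_hits$sseqid[i], acc)))
    }
    for (ko in kos) {
      e <- db[[ko]]
      if (!is.na(nm) && nm %in% tolower(e$names) && !nm %in% tolower(e$ambiguous))
        return(list(tier = "name", ko = ko,
                    evidence = sprintf("best hit %s name '%s'",
                                       proteome_hits$sseqid[i], meta$name[i])))
    }
    NULL
  }

  n <- nrow(proteome_hits)
  res <- vector("list", n)
  for (i in seq_len(n)) res[[i]] <- tier_of(i)

  # cluster tier: qualifying clusters = configured clusters plus best-hit
  # clusters of proteins annotated at tiers 1-2 (single pass, no iteration)
  cluster_sets <- lapply(kos, function(ko) db[[ko]]$clusters)
  names(cluster_sets) <- kos
  for (i in seq_len(n)) {
    if (!is.null(res[[i]])) {
      ko <- res[[i]]$ko
      cl <- meta$cluster[i]
      if (!is.na(cl) && nzchar(cl))
        cluster_sets[[ko]] <- union(cluster_sets[[ko]], cl)
    }
  }
  for (i in seq_len(n)) {
    if (is.null(res[[i]])) {
      cl <- meta$cluster[i]
      if (!is.na(cl) && nzchar(cl)) {
        for (ko in kos) {
          if (cl %in% cluster_sets[[ko]]) {
            res[[i]] <- list(tier = "cluster", ko = ko,
                             evidence = sprintf("best hit %s cluster %s",
                                                proteome_hits$sseqid[i], cl))
            break
          }
        }
      }
    }
  }

  out <- data.frame(
    protein = proteome_hits$qseqid,
    status = ifelse(vapply(res, is.null, TRUE), "unresolved", "annotated"),
    tier = vapply(res, function(r) r$tier %||% NA_character_, ""),
    ko = vapply(res, function(r) r$ko %||% NA_character_, ""),
    evidence = vapply(res, function(r) r$evidence %||% "", ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
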