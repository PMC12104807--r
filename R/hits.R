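HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular similarity-search hit table
#'
#' The standard 12-column tabular dialect (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score), as emitted by `blastp -outfmt 6`
#' or `diamond --outfmt 6`. A header line is optional and detected by a
#' non-numeric e-value field. Rows are normalized to per-query descending bit
#' score on the way in.
#'
#' @param path path to a tab-separated hit file.
#' @return a `hit_table` data.frame with columns `r toString(HIT_COLS)`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][11L])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) != 12L)
    stop("expected 12 tab-separated columns, got ", ncol(df))
  names(df) <- HIT_COLS
  hit_table(df)
}

#' @rdname read_hit_table
#' @param df data.frame with the 12 standard columns (named or positional).
#' @export
hit_table <- function(df) {
  if (ncol(df) != 12L) stop("hit table must have 12 columns")
  names(df) <- HIT_COLS
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (nrow(df)) {
    if (any(!nzchar(df$qseqid)) || any(!nzchar(df$sseqid)))
      stop("empty query or subject id")
    if (any(df$evalue < 0)) stop("negative e-value")
    if (any(!is.finite(df$bitscore))) stop("non-finite bit score")
    df <- df[order(df$qseqid, -df$bitscore, df$evalue, df$sseqid), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("hit_table", "data.frame")
  df
}

#' @rdname read_hit_table
#' @param x a `hit_table`.
#' @export
write_hit_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject-metadata side table
#'
#' TSV with columns `subject` (id as it appears in hit tables), `name`
#' (display name), `is_opsin` (`TRUE`/`FALSE` or `1`/`0`), `cluster`
#' (sequence-cluster id standing in for Uniref90 membership) and `accession`.
#'
#' @param path path to the TSV (header required).
#' @return data.frame with those five columns.
#' @export
read_subject_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "name", "is_opsin", "cluster", "accession")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c))
    stop("subject metadata lacks column(s): ", paste(missing_c, collapse = ", "))
  df$is_opsin <- as.logical(df$is_opsin) | df$is_opsin == 1
  df
}

#' Drop hits above an e-value threshold
#'
#' @param hits a `hit_table`.
#' @param threshold maximum e-value retained (default `1e-5`, the cutoff used
#'   throughout the annotation searches).
#' @return the filtered `hit_table`.
#' @export
evalue_prefilter <- function(hits, threshold = 1e-5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number")
  out <- hits[hits$evalue <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(hits)
  out
}

#' Keep the single best hit per query
#'
#' Best = maximal bit score; ties broken by lower e-value, then lexicographic
#' subject id. Every tie-break actually exercised is recorded in the
#' `tie_log` attribute (query, competing subjects, rule that decided).
#'
#' @param hits a `hit_table`.
#' @return a `hit_table` with exactly one row per query (empty in, empty out),
#'   with attribute `tie_log` (data.frame).
#' @export
best_hit_per_query <- function(hits) {
  tie_log <- data.frame(qseqid = character(0), subjects = character(0),
                        decided_by = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    attr(hits, "tie_log") <- tie_log
    return(hits)
  }
  keep <- lapply(split(seq_len(nrow(hits)), hits$qseqid), function(idx) {
    h <- hits[idx, , drop = FALSE]
    top <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    if (nrow(top) > 1L) {
      by_e <- top[top$evalue == min(top$evalue), , drop = FALSE]
      rule <- if (nrow(by_e) > 1L) "subject id" else "e-value"
      tie_log[nrow(tie_log) + 1L, ] <<- list(
        top$qseqid[1L], paste(sort(top$sseqid), collapse = ","), rule)
      top <- by_e[order(by_e$sseqid), , drop = FALSE][1L, , drop = FALSE]
    }
    idx[match(paste(top$sseqid, top$evalue), paste(h$sseqid, h$evalue))[1L]]
  })
  out <- hits[sort(unlist(keep)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(hits)
  attr(out, "tie_log") <- tie_log
  out
}

top_k_per_query <- function(hits, k) {
  idx <- unlist(lapply(split(seq_len(nrow(hits)), hits$qseqid),
                       function(i) i[seq_len(min(k, length(i)))]),
                use.names = FALSE)
  out <- hits[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(hits)
  out
}

#' Reciprocal opsin filter for candidate sequences
#'
#' A candidate survives iff at least one of its top-`k` back-search subjects
#' (by bit score, after normalization) is flagged as an opsin in the subject
#' metadata; candidates whose top-`k` contain no opsin — or with no back-hits
#' at all — are removed. This is the false-positive screen applied after the
#' initial best-hit retrieval of putative opsins.
#'
#' @param candidates character vector of candidate protein (query) ids.
#' @param back_hits a `hit_table` of the candidates searched back against the
#'   reference protein set.
#' @param subjects subject metadata ([read_subject_metadata()] layout).
#' @param k number of back-hits considered per candidate (default 3).
#' @return data.frame of `annotation_decision` rows: `protein`, `status`
#'   (`annotated`/`removed`), `tier` (`"candidate_filter"`), `evidence`
#'   (the top-k subjects with their opsin flags), `reason`.
#' @export
reciprocal_opsin_filter <- function(candidates, back_hits, subjects, k = 3L) {
  stopifnot(k >= 1L)
  topk <- top_k_per_query(back_hits, k)
  rows <- lapply(candidates, function(q) {
    h <- topk[topk$qseqid == q, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(protein = q, status = "removed",
                        tier = "candidate_filter", evidence = "",
                        reason = "no hits", stringsAsFactors = FALSE))
    flag <- subjects$is_opsin[match(h$sseqid, subjects$subject)]
    flag[is.na(flag)] <- FALSE
    ev <- paste(sprintf("%s[%s]", h$sseqid,
                        ifelse(flag, "opsin", "non-opsin")), collapse = ";")
    if (any(flag))
      data.frame(protein = q, status = "annotated", tier = "candidate_filter",
                 evidence = ev, reason = sprintf("opsin among top-%d back-hits", k),
                 stringsAsFactors = FALSE)
    else
      data.frame(protein = q, status = "removed", tier = "candidate_filter",
                 evidence = ev, reason = sprintf("no opsin among top-%d back-hits", k),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
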