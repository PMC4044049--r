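#' Homolog pools
#'
#' A homolog pool is the set of n non-redundant sequences homologous to one
#' query, each carrying a taxon id and a similarity score (e.g. a BLAST
#' bitscore). It is stored as a tibble with columns `seq_id`, `taxon_id`,
#' `score` and optionally `evalue`; the input is assumed to be already
#' dereplicated — the constructor only enforces `seq_id` uniqueness.
#'
#' @param records A data frame with columns `seq_id`, `taxon_id`, `score` and
#'   optionally `evalue`.
#' @param query_id Optional identifier of the query sequence.
#' @return A tibble of class `astax_pool`.
#' @export
homolog_pool <- function(records, query_id = NULL) {
  records <- as_tibble(records)
  need <- c("seq_id", "taxon_id", "score")
  if (!all(need %in% names(records))) {
    abort_validation(paste0(
      "homolog records need columns ", paste(need, collapse = ", ")
    ))
  }
  records$seq_id <- as.character(records$seq_id)
  records$taxon_id <- as.character(records$taxon_id)
  records$score <- as.numeric(records$score)
  if (nrow(records) > 0L) {
    if (anyNA(records$seq_id) || anyNA(records$taxon_id)) {
      abort_validation("homolog records with missing seq_id or taxon_id")
    }
    if (any(!is.finite(records$score))) {
      abort_validation("homolog scores must be finite")
    }
    if (anyDuplicated(records$seq_id)) {
      dup <- unique(records$seq_id[duplicated(records$seq_id)])
      abort_validation(paste0(
        "duplicate seq_id(s) in homolog pool: ",
        paste(utils::head(dup, 5), collapse = ", ")
      ))
    }
    if ("evalue" %in% names(records)) {
      ev <- as.numeric(records$evalue)
      if (any(!is.na(ev) & ev < 0)) abort_validation("evalue must be >= 0")
      records$evalue <- ev
    }
  }
  cols <- intersect(c("seq_id", "taxon_id", "score", "evalue"), names(records))
  new_tibble(records[cols], query_id = query_id, class = "astax_pool")
}

#' @export
print.astax_pool <- function(x, ...) {
  qid <- attr(x, "query_id")
  cat(sprintf(
    "<homolog pool> n = %d record(s)%s\n", nrow(x),
    if (is.null(qid)) "" else paste0(", query ", qid)
  ))
  NextMethod()
}

#' Read a prepared homolog table
#'
#' Reads the 3-or-4-column tab-separated table the basic sampling workflow
#' consumes: sequence id, taxon id, similarity score and optionally E-value.
#' A header line is detected by a non-numeric score field.
#'
#' @param path Path to the TSV file.
#' @param query_id Optional query identifier attached to the pool.
#' @return An `astax_pool` tibble (see [homolog_pool()]).
#' @export
read_homolog_table <- function(path, query_id = NULL) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) {
    return(homolog_pool(
      tibble(seq_id = character(), taxon_id = character(), score = numeric()),
      query_id = query_id
    ))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "malformed homolog row at line %d (need seq_id, taxon_id, score[, evalue])",
      keep[bad[1]]
    ))
  }
  col <- function(k) {
    vapply(parts, function(p) if (length(p) >= k) trimws(p[[k]]) else NA_character_, character(1))
  }
  seq_id <- col(1L); taxon_id <- col(2L); score_raw <- col(3L); evalue_raw <- col(4L)
  # optional header: first row whose score field is not numeric
  is_header <- suppressWarnings(is.na(as.numeric(score_raw[1])))
  if (is_header) {
    seq_id <- seq_id[-1]; taxon_id <- taxon_id[-1]
    score_raw <- score_raw[-1]; evalue_raw <- evalue_raw[-1]
    keep <- keep[-1]
  }
  score <- suppressWarnings(as.numeric(score_raw))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    abort_parse(sprintf(
      "non-numeric similarity score '%s' at line %d", score_raw[bad], keep[bad]
    ))
  }
  rec <- tibble(seq_id = seq_id, taxon_id = taxon_id, score = score)
  if (any(!is.na(evalue_raw))) {
    evalue <- suppressWarnings(as.numeric(evalue_raw))
    if (any(is.na(evalue) & !is.na(evalue_raw))) {
      bad <- which(is.na(evalue) & !is.na(evalue_raw))[1]
      abort_parse(sprintf(
        "non-numeric evalue '%s' at line %d", evalue_raw[bad], keep[bad]
      ))
    }
    rec$evalue <- evalue
  }
  homolog_pool(rec, query_id = query_id)
}

#' Write a homolog table
#' @param pool An `astax_pool` tibble.
#' @param path Output TSV path.
#' @param header Write a header line?
#' @return `path`, invisibly.
#' @export
write_homolog_table <- function(pool, path, header = TRUE) {
  utils::write.table(
    as.data.frame(pool), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = header
  )
  invisible(path)
}

#' Build a homolog pool from a BLAST XML report
#'
#' Parses an NCBI BLAST XML report (`-outfmt 5`, historically `-m7`) and keeps
#' one record per subject sequence, scored by its best HSP bitscore. A hit is
#' retained when that best HSP passes both cutoffs (`evalue <= evalue_cutoff`
#' and `bitscore >= bitscore_cutoff`). The default E-value cutoff of 0.01
#' matches common practice for collecting homologs of a protein query; both
#' cutoffs can be loosened or tightened freely.
#'
#' Taxon ids are resolved from, in order: a supplied `taxid_map`
#' (seq id -> taxon id), a `taxid|<id>` or `taxid=<id>` token in the hit
#' definition line. Hits without a resolvable taxon are dropped with a
#' warning; the number dropped is available as attribute `n_dropped`.
#'
#' @param path Path to the BLAST XML file.
#' @param evalue_cutoff Keep hits with best-HSP E-value `<=` this (default 0.01).
#' @param bitscore_cutoff Keep hits with best-HSP bitscore `>=` this (default 0).
#' @param taxid_map Optional mapping from sequence id to taxon id: a named
#'   character vector or a two-column data frame (seq_id, taxon_id).
#' @return An `astax_pool` tibble with columns seq_id, taxon_id, score, evalue.
#' @export
read_blast_xml <- function(path, evalue_cutoff = 0.01, bitscore_cutoff = 0,
                           taxid_map = NULL) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  if (!is.finite(evalue_cutoff) || !is.finite(bitscore_cutoff)) {
    abort_validation("cutoffs must be finite numbers")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort_parse(paste0("malformed BLAST XML: ", conditionMessage(e)))
  )
  query_id <- xml2::xml_text(xml2::xml_find_first(doc, ".//BlastOutput_query-def"))
  hits <- xml2::xml_find_all(doc, ".//Hit")
  if (!is.null(taxid_map) && is.data.frame(taxid_map)) {
    tm <- stats::setNames(as.character(taxid_map[[2]]), as.character(taxid_map[[1]]))
    taxid_map <- tm
  }

  rows <- lapply(hits, function(hit) {
    hid <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_id"))
    hdef <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
    acc <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_accession"))
    seq_id <- if (!is.na(acc) && nzchar(acc)) acc else hid
    bits <- xml2::xml_double(xml2::xml_find_all(hit, ".//Hsp_bit-score"))
    evs <- xml2::xml_double(xml2::xml_find_all(hit, ".//Hsp_evalue"))
    if (length(bits) == 0L) return(NULL)
    best <- which.max(bits)
    taxid <- NA_character_
    for (cand in c(seq_id, hid, hdef)) {
      if (!is.null(taxid_map) && !is.na(cand) && cand %in% names(taxid_map)) {
        taxid <- unname(taxid_map[[cand]])
        break
      }
    }
    if (is.na(taxid) && !is.na(hdef)) {
      mt <- regmatches(hdef, regexpr("taxid[|=]([0-9A-Za-z_]+)", hdef))
      if (length(mt) == 1L) taxid <- sub("^taxid[|=]", "", mt)
    }
    list(seq_id = seq_id, taxon_id = taxid,
         score = bits[best], evalue = evs[best])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    pool <- homolog_pool(
      tibble(seq_id = character(), taxon_id = character(),
             score = numeric(), evalue = numeric()),
      query_id = query_id
    )
    attr(pool, "n_dropped") <- 0L
    return(pool)
  }
  rec <- tibble(
    seq_id = vapply(rows, `[[`, character(1), "seq_id"),
    taxon_id = vapply(rows, `[[`, character(1), "taxon_id"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    evalue = vapply(rows, `[[`, numeric(1), "evalue")
  )
  rec <- rec[rec$evalue <= evalue_cutoff & rec$score >= bitscore_cutoff, , drop = FALSE]
  n_dropped <- sum(is.na(rec$taxon_id))
  if (n_dropped > 0L) {
    warn(sprintf(
      "%d BLAST hit(s) dropped: no resolvable taxon id", n_dropped
    ))
    rec <- rec[!is.na(rec$taxon_id), , drop = FALSE]
  }
  pool <- homolog_pool(rec, query_id = query_id)
  attr(pool, "n_dropped") <- n_dropped
  pool
}

#' Optional dereplication by taxon and score
#'
#' Convenience filter (off the main path): within groups of records sharing
#' the same taxon id and identical score, keeps the record with the smallest
#' seq id. The core workflow assumes the caller already supplies a
#' non-redundant pool.
#'
#' @param pool An `astax_pool` tibble.
#' @return A filtered `astax_pool`.
#' @export
dereplicate_pool <- function(pool) {
  if (nrow(pool) == 0L) return(pool)
  ord <- order_by_score(pool$score, pool$seq_id)
  x <- pool[ord, , drop = FALSE]
  keep <- !duplicated(paste(x$taxon_id, x$score, sep = "\r"))
  homolog_pool(x[keep, , drop = FALSE], query_id = attr(pool, "query_id"))
}

#' Count homologs under each child of a taxon
#'
#' For taxon `t`, tallies how many pool records fall under each direct child
#' of `t` (i.e. the record's lineage passes through that child). Records whose
#' taxon is `t` itself are reported under the pseudo-child `".self"`, so the
#' bucket counts always sum to the number of records in `t`'s subtree.
#'
#' @param pool An `astax_pool` tibble.
#' @param tree A [taxonomy()] object resolving every record's taxon.
#' @param taxon_id The parent taxon.
#' @return A tibble with columns `child_id` (direct children in canonical
#'   order, then `".self"`) and `n`.
#' @export
counts_by_child <- function(pool, tree, taxon_id) {
  t_idx <- taxon_index(tree, taxon_id)
  stopifnot(length(t_idx) == 1L)
  rec_idx <- match(pool$taxon_id, tree$ids)
  if (anyNA(rec_idx)) {
    bad <- unique(pool$taxon_id[is.na(rec_idx)])
    abort_validation(paste0(
      "homolog taxon id(s) absent from taxonomy: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  kids <- tree$children[[t_idx]]
  lev <- tree$level[t_idx]
  # child of t on each record's root path: the record's ancestor at level + 1
  anc <- rec_idx
  repeat {
    deeper <- which(!is.na(anc) & tree$level[anc] > lev + 1L)
    if (length(deeper) == 0L) break
    anc[deeper] <- tree$parent[anc[deeper]]
  }
  under_child <- !is.na(anc) & tree$level[anc] == lev + 1L &
    !is.na(tree$parent[anc]) & tree$parent[anc] == t_idx
  n_by_child <- vapply(kids, function(k) sum(under_child & anc == k), integer(1))
  tibble(
    child_id = c(tree$ids[kids], ".self"),
    n = c(n_by_child, sum(rec_idx == t_idx))
  )
}
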