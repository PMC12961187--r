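#' Build an in-memory search database
#'
#' Wraps a set of subject sequences with the metadata the annotator needs
#' (fish flag, species label for reference records, taxon label for
#' background centroids).
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param is_fish logical vector (recycled).
#' @param species species labels for fish reference records (`NA` for
#'   background sequences).
#' @param taxon free-text taxon labels (used for background sequences).
#' @return an object of class `mb_searchdb`.
#' @export
search_db <- function(seqs, is_fish = TRUE, species = NA_character_,
                      taxon = NA_character_) {
    seqs <- setNames(toupper(as.character(seqs)), names(seqs))
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("subject sequences must have unique names")
    n <- length(seqs)
    structure(list(
        seqs = seqs,
        meta = data.frame(id = names(seqs),
                          is_fish = rep_len(as.logical(is_fish), n),
                          species = rep_len(as.character(species), n),
                          taxon = rep_len(as.character(taxon), n),
                          stringsAsFactors = FALSE)),
        class = "mb_searchdb")
}

#' Combine reference and background databases for searching
#' @param ref an `mb_refdb`.
#' @param background a background centroid data.frame from
#'   [build_background_db()] (or `NULL`).
#' @return an `mb_searchdb` covering both.
#' @export
combined_search_db <- function(ref, background = NULL) {
    stopifnot(inherits(ref, "mb_refdb"))
    seqs <- setNames(ref$sequence, ref$record_id)
    is_fish <- ref$is_fish
    species <- ref$species
    taxon <- ref$species
    if (!is.null(background) && nrow(background) > 0L) {
        seqs <- c(seqs, setNames(background$sequence, background$id))
        is_fish <- c(is_fish, rep(FALSE, nrow(background)))
        species <- c(species, rep(NA_character_, nrow(background)))
        taxon <- c(taxon, background$taxon)
    }
    search_db(seqs, is_fish, species, taxon)
}

.empty_hits <- function() {
    data.frame(query_id = character(0), subject_id = character(0),
               subject_is_fish = logical(0), identity = numeric(0),
               query_coverage = numeric(0), score = numeric(0),
               columns = integer(0), mismatches = integer(0),
               gap_opens = integer(0), query_start = integer(0),
               query_end = integer(0), subject_start = integer(0),
               subject_end = integer(0), strand = character(0),
               species = character(0), taxon = character(0),
               stringsAsFactors = FALSE)
}

#' Similarity search of a query against a database
#'
#' Aligns the query (both strands, semi-global) against every subject that
#' shares at least one exact word of `word_size` bases with it, keeps one
#' best alignment per subject, discards hits covering less than
#' `min_coverage` percent of the query, sorts by score (descending, ties by
#' subject id) and returns at most `max_targets` hits. `word_size = 28`
#' emulates a fast low-sensitivity search, `11` a sensitive one.
#'
#' @param query DNA string (optionally named; the name becomes `query_id`).
#' @param db an `mb_searchdb`.
#' @param max_targets maximum number of hits (default 10).
#' @param min_coverage query-coverage gate in percent (default 80).
#' @param word_size exact-seed length for the pre-filter.
#' @return data.frame of hits (possibly empty), one row per subject, with
#'   0-based half-open subject intervals.
#' @export
search_topk <- function(query, db, max_targets = 10, min_coverage = 80,
                        word_size = 28) {
    stopifnot(inherits(db, "mb_searchdb"), max_targets >= 1)
    qid <- if (!is.null(names(query)) && nzchar(names(query)[1]))
        names(query)[1] else "query"
    q <- toupper(as.character(query)[1])
    if (length(db$seqs) == 0L) return(.empty_hits())
    qrc <- revcomp(q)
    rows <- vector("list", length(db$seqs))
    for (j in seq_along(db$seqs)) {
        s <- db$seqs[[j]]
        if (!.shares_kmer_cpp(q, s, word_size) &&
            !.shares_kmer_cpp(qrc, s, word_size)) next
        best <- .best_strand_alignment(q, s)
        cov <- best$query_coverage
        if (cov < min_coverage) next
        rows[[j]] <- data.frame(
            query_id = qid, subject_id = db$meta$id[j],
            subject_is_fish = db$meta$is_fish[j],
            identity = best$identity, query_coverage = cov,
            score = best$score, columns = as.integer(best$columns),
            mismatches = as.integer(best$mismatches),
            gap_opens = as.integer(best$gap_opens),
            query_start = as.integer(best$query_start),
            query_end = as.integer(best$query_end),
            subject_start = as.integer(best$subject_start),
            subject_end = as.integer(best$subject_end),
            strand = best$strand,
            species = db$meta$species[j], taxon = db$meta$taxon[j],
            stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(.empty_hits())
    hits <- do.call(rbind, rows)
    hits <- hits[order(-round(hits$score, 1), hits$subject_id), , drop = FALSE]
    hits <- head(hits, max_targets)
    rownames(hits) <- NULL
    hits
}

#' Recursive retrieval of the full top-score hit stratum
#'
#' A fixed-size search can truncate the set of equally-best hits. Starting
#' from `max_targets = 10`, while the returned list is full, all scores are
#' tied at the maximum (scores compared after rounding to one decimal) and
#' all identities are at or above `species_threshold`, the search is re-run
#' with `max_targets` increased by 50, until a lower-scoring hit shows that
#' the stratum is complete. Returns every hit sharing the maximum score.
#' `saturated` is `TRUE` unless the database was exhausted while the hit
#' list was still uniform (in which case the stratum may extend beyond the
#' database).
#'
#' @inheritParams search_topk
#' @param species_threshold identity threshold (percent) below which no
#'   recursion is attempted.
#' @return list with `hits` (the top-score stratum) and `saturated`.
#' @export
recursive_top_hits <- function(query, db, species_threshold = 99,
                               min_coverage = 80, word_size = 28) {
    m <- 10L
    n_db <- length(db$seqs)
    repeat {
        hits <- search_topk(query, db, max_targets = m,
                            min_coverage = min_coverage,
                            word_size = word_size)
        if (nrow(hits) == 0L)
            return(list(hits = hits, saturated = TRUE))
        rs <- round(hits$score, 1)
        uniform <- all(rs == rs[1])
        if (nrow(hits) == m && uniform &&
            all(hits$identity >= species_threshold) && m < n_db) {
            m <- m + 50L
            next
        }
        top <- hits[rs == rs[1], , drop = FALSE]
        rownames(top) <- NULL
        saturated <- if (!uniform) TRUE
            else if (nrow(hits) < m) FALSE
            else if (m >= n_db && all(hits$identity >= species_threshold)) FALSE
            else TRUE
        return(list(hits = top, saturated = saturated))
    }
}

#' Search with sensitive-mode fallback
#'
#' Runs [recursive_top_hits()] in fast mode (word size 28); when no hit is
#' found, the slower sensitive mode (word size 11) is tried before giving
#' up, so divergent queries still receive their best hits.
#'
#' @inheritParams recursive_top_hits
#' @return list with `hits`, `saturated` and `mode`
#'   (`"fast"`/`"sensitive"`).
#' @export
search_with_fallback <- function(query, db, species_threshold = 99,
                                 min_coverage = 80) {
    res <- recursive_top_hits(query, db, species_threshold, min_coverage,
                              word_size = 28)
    if (nrow(res$hits) > 0L) { res$mode <- "fast"; return(res) }
    res <- recursive_top_hits(query, db, species_threshold, min_coverage,
                              word_size = 11)
    res$mode <- "sensitive"
    res
}

#' Read / write hits in BLAST tabular format
#'
#' The 12-column tabular dialect (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) plus an optional 13th
#' `qcovhsp` column. On disk coordinates are 1-based inclusive with
#' minus-strand hits carrying `sstart > send`; in memory they are 0-based
#' half-open plus-strand intervals with a `strand` column. The E-value
#' column is parsed but unused.
#'
#' @param path file path.
#' @return `parse_hit_table` returns a hit data.frame in row order.
#' @export
parse_hit_table <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(.empty_hits())
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (!(length(f) %in% c(12L, 13L)))
            stop("parse error at line ", i, ": expected 12 or 13 columns, got ",
                 length(f))
        num <- suppressWarnings(as.numeric(f[3:12]))
        if (anyNA(num))
            stop("parse error at line ", i, ": non-numeric field")
        sstart <- num[7]; send <- num[8]
        minus <- sstart > send
        rows[[i]] <- data.frame(
            query_id = f[1], subject_id = f[2],
            subject_is_fish = NA, identity = num[1],
            query_coverage = if (length(f) == 13L) as.numeric(f[13]) else NA_real_,
            score = num[10], columns = as.integer(num[2]),
            mismatches = as.integer(num[3]), gap_opens = as.integer(num[4]),
            query_start = as.integer(num[5] - 1), query_end = as.integer(num[6]),
            subject_start = as.integer(if (minus) send - 1 else sstart - 1),
            subject_end = as.integer(if (minus) sstart else send),
            strand = if (minus) "-" else "+",
            species = NA_character_, taxon = NA_character_,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' @rdname parse_hit_table
#' @param hits a hit data.frame.
#' @export
write_hit_table <- function(hits, path) {
    fmt <- vapply(seq_len(nrow(hits)), function(i) {
        minus <- hits$strand[i] == "-"
        sstart <- if (minus) hits$subject_end[i] else hits$subject_start[i] + 1L
        send <- if (minus) hits$subject_start[i] + 1L else hits$subject_end[i]
        paste(hits$query_id[i], hits$subject_id[i],
              sprintf("%.3f", hits$identity[i]), hits$columns[i],
              hits$mismatches[i], hits$gap_opens[i],
              hits$query_start[i] + 1L, hits$query_end[i],
              sstart, send, "0.0", sprintf("%.1f", hits$score[i]),
              sprintf("%.1f", hits$query_coverage[i]), sep = "\t")
    }, character(1))
    writeLines(fmt, path)
    invisible(hits)
}
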