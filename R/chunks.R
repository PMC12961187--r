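#' Split a gene sequence into 100-bp validation chunks
#'
#' Taxonomy labels are validated on 100-bp subsequences rather than on
#' full-length sequences, because chimeric (heterospecific) segments in
#' deposited records can be as short as about 100 bp. Chunks start at
#' multiples of 100; when the final chunk would be shorter than 100 bp it is
#' instead the final 100 bp of the sequence (so the last two chunks may
#' overlap). Sequences shorter than 100 bp form a single whole-length chunk.
#'
#' @param length positive integer sequence length.
#' @return data.frame with 0-based half-open `start`, `end` columns.
#' @examples
#' split_gene_into_chunks(250)   # (0,100) (100,200) (150,250)
#' @export
split_gene_into_chunks <- function(length) {
    if (length(length) != 1L || is.na(length) || length < 1)
        stop("length must be a positive integer")
    length <- as.integer(length)
    if (length < 100L) return(data.frame(start = 0L, end = length))
    starts <- seq.int(0L, length - 100L, by = 100L)
    ends <- starts + 100L
    if (length %% 100L != 0L) {
        starts <- c(starts, length - 100L)
        ends <- c(ends, length)
    }
    data.frame(start = starts, end = ends)
}

#' Collect homologs of one reference chunk
#'
#' Searches the chunk subsequence against the other records of the database
#' (semi-global alignment, both strands) and returns every record whose best
#' alignment has identity strictly greater than 99\% with at least 80\% of
#' the chunk covered. Records sharing any accession with the query record
#' are excluded, so a record never corroborates itself.
#'
#' @param record_id id of the record the chunk belongs to.
#' @param chunk one-row data.frame (or list) with `start`, `end`.
#' @param db an `mb_refdb`.
#' @param identity_gt exclusive identity threshold (percent), default 99.
#' @return data.frame with columns `record_id`, `species`, `identity` and a
#'   list column `authors`.
#' @export
collect_chunk_homologs <- function(record_id, chunk, db, identity_gt = 99) {
    stopifnot(inherits(db, "mb_refdb"))
    i <- match(record_id, db$record_id)
    if (is.na(i)) stop("unknown record id: ", record_id)
    qseq <- substr(db$sequence[i], chunk$start + 1L, chunk$end)
    own_acc <- db$accessions[[i]]
    keep <- vapply(seq_len(nrow(db)), function(j)
        j != i && !any(db$accessions[[j]] %in% own_acc), logical(1))
    cand <- which(keep)
    rows <- list()
    for (j in cand) {
        best <- .best_strand_alignment(qseq, db$sequence[j])
        if (best$identity > identity_gt && best$query_coverage >= 80) {
            rows[[length(rows) + 1L]] <- data.frame(
                record_id = db$record_id[j], species = db$species[j],
                identity = best$identity, stringsAsFactors = FALSE)
            attr(rows[[length(rows)]], "authors") <- db$authors[[j]]
        }
    }
    if (length(rows) == 0L)
        return(data.frame(record_id = character(0), species = character(0),
                          identity = numeric(0),
                          authors = I(list()))[0, , drop = FALSE])
    out <- do.call(rbind, rows)
    out$authors <- I(lapply(rows, attr, "authors"))
    rownames(out) <- NULL
    out
}

# best semi-global alignment over both strands
.best_strand_alignment <- function(query, subject, ...) {
    fw <- pairwise_alignment(query, subject, mode = "semi-global", ...)
    rv <- pairwise_alignment(revcomp(query), subject, mode = "semi-global", ...)
    if (rv$score > fw$score) { rv$strand <- "-"; rv } else { fw$strand <- "+"; fw }
}

#' Classify a chunk as homospecific, heterospecific or unknown
#'
#' A chunk is \emph{homospecific} when at least one >99\%-identity homolog
#' carries the same species label under an independent (disjoint) author
#' set: an independent submitter corroborates the taxonomy.
#' It is \emph{heterospecific} when no same-species homolog exists at all
#' and the homologs comprise at least two distinct other species contributed
#' by at least two mutually disjoint author sets: independent evidence that
#' the segment belongs to other species. Everything else (no homologs,
#' same-author evidence only, a single other species) is \emph{unknown}.
#'
#' @param record_species species label of the record under validation.
#' @param record_authors character vector of its authors.
#' @param homologs data.frame as returned by [collect_chunk_homologs()].
#' @return one of `"homospecific"`, `"heterospecific"`, `"unknown"`.
#' @export
classify_chunk <- function(record_species, record_authors, homologs) {
    if (nrow(homologs) == 0L) return("unknown")
    same <- homologs$species == record_species
    if (any(same)) {
        indep <- vapply(which(same), function(k)
            authors_disjoint(record_authors, homologs$authors[[k]]), logical(1))
        if (any(indep)) return("homospecific")
        return("unknown")
    }
    # no same-species homolog: need >=2 other species from >=2 disjoint
    # author sets (mutually disjoint, so the species are independently vouched)
    other_sp <- unique(homologs$species)
    if (length(other_sp) < 2L) return("unknown")
    sets <- lapply(homologs$authors, .normalize_authors)
    sets <- sets[lengths(sets) > 0L]
    n_indep <- 0L
    pool <- character(0)
    for (s in sets) {
        if (length(intersect(s, pool)) == 0L) n_indep <- n_indep + 1L
        pool <- union(pool, s)
    }
    if (n_indep >= 2L) "heterospecific" else "unknown"
}

#' Validate taxonomy labels of every reference record per 100-bp chunk
#'
#' Tiles each record into chunks (see [split_gene_into_chunks()]), collects
#' homologs above 99\% identity for each chunk from the merged database and
#' classifies the chunk via [classify_chunk()]. The result does not depend
#' on record order.
#'
#' @param db an `mb_refdb` (ideally after [merge_identical_sequences()]).
#' @param identity_gt exclusive homolog identity threshold, percent.
#' @return data.frame (class `"mb_chunks"`) with columns `record_id`,
#'   `start`, `end`, `status`.
#' @export
validate_reference_set <- function(db, identity_gt = 99) {
    stopifnot(inherits(db, "mb_refdb"))
    out <- vector("list", nrow(db))
    for (i in seq_len(nrow(db))) {
        ch <- split_gene_into_chunks(nchar(db$sequence[i]))
        ch$record_id <- db$record_id[i]
        ch$status <- vapply(seq_len(nrow(ch)), function(k) {
            hom <- collect_chunk_homologs(db$record_id[i], ch[k, ], db,
                                          identity_gt = identity_gt)
            classify_chunk(db$species[i], db$authors[[i]], hom)
        }, character(1))
        out[[i]] <- ch[, c("record_id", "start", "end", "status")]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("mb_chunks", "data.frame")
    res
}

#' Read / write chunk statuses as a BED-like TSV
#' @param chunks an `mb_chunks` data.frame.
#' @param path file path.
#' @return `read_chunk_statuses` returns an `mb_chunks` data.frame.
#' @export
write_chunk_statuses <- function(chunks, path) {
    write.table(chunks[, c("record_id", "start", "end", "status")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(chunks)
}

#' @rdname write_chunk_statuses
#' @export
read_chunk_statuses <- function(path) {
    res <- read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
    class(res) <- c("mb_chunks", "data.frame")
    res
}
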