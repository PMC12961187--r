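#' Assemble a reference database of mitochondrial gene sequences
#'
#' A reference database is a data.frame (class `"mb_refdb"`) with one row per
#' curated record: `record_id`, `sequence` (uppercase DNA), `gene` (canonical
#' name, see [normalize_gene_name()]), `species`, `genus`, `family`, `order`,
#' `accessions` and `authors` (list columns of character vectors), `is_fish`.
#'
#' @param record_id character vector of unique record ids.
#' @param sequence DNA strings over `A,C,G,T,N`.
#' @param gene canonical gene names (or raw names; they are normalized).
#' @param species,genus,family,order taxonomy labels per record.
#' @param accessions list of character vectors (>= 1 accession per record).
#' @param authors list of character vectors (may be empty).
#' @param is_fish logical vector.
#' @return an `mb_refdb` data.frame.
#' @export
reference_db <- function(record_id, sequence, gene, species,
                         genus = vapply(strsplit(species, " "), `[[`, "", 1L),
                         family = rep("FamilyUnknown", length(record_id)),
                         order = rep("OrderUnknown", length(record_id)),
                         accessions = as.list(record_id),
                         authors = rep(list(character(0)), length(record_id)),
                         is_fish = rep(TRUE, length(record_id))) {
    sequence <- toupper(sequence)
    if (any(grepl("[^ACGTN]", sequence)))
        stop("sequences must be over {A,C,G,T,N}")
    if (anyDuplicated(record_id)) stop("record ids must be unique")
    canon <- normalize_gene_name(gene)
    bad <- is.na(canon)
    canon[bad] <- gene[bad]          # keep raw label; caller may re-check
    db <- data.frame(record_id = record_id, sequence = sequence,
                     gene = canon, species = species, genus = genus,
                     family = family, order = order,
                     stringsAsFactors = FALSE)
    db$accessions <- lapply(accessions, as.character)
    db$authors <- lapply(authors, as.character)
    db$is_fish <- as.logical(is_fish)
    if (any(lengths(db$accessions) < 1L))
        stop("every record needs at least one accession")
    class(db) <- c("mb_refdb", "data.frame")
    db
}

#' Is a species name a proper binomial?
#'
#' A binomial is `"<Genus> <epithet>"` with no open-nomenclature qualifiers:
#' names containing `sp.`, `cf.`, `aff.` or extra tokens are nonbinomial
#' (they denote material not yet formally described). The genus of a binomial
#' equals its first token.
#'
#' @param species character vector of species names.
#' @return logical vector.
#' @examples
#' is_binomial(c("Gadus morhua", "Gadus sp.", "Gadus cf. morhua"))
#' @export
is_binomial <- function(species) {
    vapply(species, function(sp) {
        if (is.na(sp) || !nzchar(sp)) return(FALSE)
        toks <- strsplit(trimws(sp), "[[:space:]]+")[[1]]
        if (length(toks) != 2L) return(FALSE)
        if (!grepl("^[A-Z][a-z]+$", toks[1])) return(FALSE)
        grepl("^[a-z]+(-[a-z]+)?$", toks[2])
    }, logical(1), USE.NAMES = FALSE)
}

# author-name normalization: case-fold, strip initials punctuation, squeeze
.normalize_authors <- function(a) {
    a <- tolower(a)
    a <- gsub("[.,]", " ", a)
    a <- gsub("[[:space:]]+", " ", trimws(a))
    unique(a[nzchar(a)])
}

#' Are two author sets disjoint?
#'
#' Records corroborate each other's taxonomy only when they come from
#' different submitters; "different" means the normalized author-name sets
#' share no member.
#' @param a,b character vectors of author names.
#' @return `TRUE` when the normalized sets are disjoint. Two empty sets are
#'   treated as not disjoint (no evidence of independence).
#' @export
authors_disjoint <- function(a, b) {
    na <- .normalize_authors(a); nb <- .normalize_authors(b)
    if (length(na) == 0L && length(nb) == 0L) return(FALSE)
    length(intersect(na, nb)) == 0L
}

#' Merge identical reference sequences
#'
#' Records with identical (sequence, gene, species) are combined into one
#' record whose accession list and author set are the unions of the merged
#' records; the total accession count is conserved. Identical sequences of
#' the same species but carrying conflicting gene labels are kept separate
#' and a warning names them.
#'
#' @param db an `mb_refdb`.
#' @return an `mb_refdb` with duplicates merged.
#' @export
merge_identical_sequences <- function(db) {
    stopifnot(inherits(db, "mb_refdb"))
    if (nrow(db) == 0L) return(db)
    key <- paste(db$sequence, db$gene, db$species, sep = "\r")
    sp_key <- paste(db$sequence, db$species, sep = "\r")
    conflict <- tapply(db$gene, sp_key, function(g) length(unique(g)) > 1L)
    if (any(conflict)) {
        ids <- db$record_id[sp_key %in% names(conflict)[conflict]]
        warning("conflicting gene labels for identical sequences kept separate: ",
                paste(ids, collapse = ", "))
    }
    first <- !duplicated(key)
    out <- db[first, , drop = FALSE]
    grp <- match(key, key[first])
    out$accessions <- lapply(seq_len(sum(first)), function(i)
        unique(unlist(db$accessions[grp == i])))
    out$authors <- lapply(seq_len(sum(first)), function(i)
        unique(unlist(db$authors[grp == i])))
    rownames(out) <- NULL
    class(out) <- c("mb_refdb", "data.frame")
    out
}

#' Extract the taxonomy table of a reference database
#'
#' One row per species with its genus, family and order (used for
#' lowest-common-ancestor computation and published-result comparison).
#' @param db an `mb_refdb`.
#' @return data.frame with columns `species`, `genus`, `family`, `order`.
#' @export
taxonomy_table <- function(db) {
    stopifnot(inherits(db, "mb_refdb"))
    tax <- unique(data.frame(species = db$species, genus = db$genus,
                             family = db$family, order = db$order,
                             stringsAsFactors = FALSE))
    rownames(tax) <- NULL
    tax
}

#' Read / write a reference database (FASTA + TSV sidecar)
#'
#' The on-disk form is a FASTA file (record id in the header) plus a TSV
#' sidecar with columns `record_id`, `accessions` (semicolon-joined),
#' `species`, `genus`, `family`, `order`, `gene_raw`, `authors`
#' (semicolon-joined) and `is_fish` (0/1).
#'
#' @param fasta,tsv file paths.
#' @return `read_reference_db` returns an `mb_refdb`;
#'   `write_reference_db` returns its input invisibly.
#' @export
read_reference_db <- function(fasta, tsv) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    meta <- read.table(tsv, header = TRUE, sep = "\t", quote = "",
                       stringsAsFactors = FALSE)
    ids <- sub("\\s.*$", "", names(seqs))
    m <- match(meta$record_id, ids)
    if (anyNA(m)) stop("TSV records missing from FASTA: ",
                       paste(meta$record_id[is.na(m)], collapse = ", "))
    reference_db(
        record_id = meta$record_id,
        sequence = as.character(seqs)[m],
        gene = meta$gene_raw,
        species = meta$species, genus = meta$genus,
        family = meta$family, order = meta$order,
        accessions = strsplit(meta$accessions, ";", fixed = TRUE),
        authors = strsplit(ifelse(is.na(meta$authors), "", meta$authors),
                           ";", fixed = TRUE),
        is_fish = meta$is_fish == 1)
}

#' @rdname read_reference_db
#' @param db an `mb_refdb` to write.
#' @export
write_reference_db <- function(db, fasta, tsv) {
    stopifnot(inherits(db, "mb_refdb"))
    ss <- Biostrings::DNAStringSet(setNames(db$sequence, db$record_id))
    Biostrings::writeXStringSet(ss, fasta)
    meta <- data.frame(
        record_id = db$record_id,
        accessions = vapply(db$accessions, paste, "", collapse = ";"),
        species = db$species, genus = db$genus, family = db$family,
        order = db$order, gene_raw = db$gene,
        authors = vapply(db$authors, paste, "", collapse = ";"),
        is_fish = as.integer(db$is_fish),
        stringsAsFactors = FALSE)
    write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(db)
}
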