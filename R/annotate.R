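#' Lowest common ancestor of a set of species
#'
#' Walks the ranks genus < family < order and returns the deepest rank
#' shared by all input species; species in different orders fall back to the
#' unranked root (`"Fish"`). A single species reports its genus -- a
#' sub-threshold match to one reference species is evidence for the genus,
#' not the species.
#'
#' @param species character vector of species names.
#' @param taxonomy data.frame with columns `species`, `genus`, `family`,
#'   `order` (see [taxonomy_table()]).
#' @return list with `name` and `rank` (one of `"genus"`, `"family"`,
#'   `"order"`, `"root"`).
#' @export
lowest_common_ancestor <- function(species, taxonomy) {
    i <- match(unique(species), taxonomy$species)
    if (anyNA(i))
        stop("species not in taxonomy: ",
             paste(unique(species)[is.na(i)], collapse = ", "))
    for (rank in c("genus", "family", "order")) {
        v <- unique(taxonomy[[rank]][i])
        if (length(v) == 1L) return(list(name = v, rank = rank))
    }
    list(name = "Fish", rank = "root")
}

#' Does a hit lie in heterospecific territory?
#'
#' A supporting hit is discounted when at least `min_frac` of its subject
#' interval is covered by chunks validated as heterospecific -- the labeled
#' taxonomy of that region is unsupported.
#'
#' @param subject_start,subject_end 0-based half-open hit interval on the
#'   reference.
#' @param chunks chunk-status rows for that reference (columns `start`,
#'   `end`, `status`).
#' @param min_frac minimum covered fraction (default 0.5).
#' @return logical.
#' @export
overlaps_heterospecific <- function(subject_start, subject_end, chunks,
                                    min_frac = 0.5) {
    het <- chunks[chunks$status == "heterospecific", , drop = FALSE]
    if (nrow(het) == 0L) return(FALSE)
    len <- subject_end - subject_start
    if (len <= 0L) return(FALSE)
    covered <- rep(FALSE, len)
    for (k in seq_len(nrow(het))) {
        lo <- max(het$start[k], subject_start)
        hi <- min(het$end[k], subject_end)
        if (hi > lo)
            covered[(lo - subject_start + 1L):(hi - subject_start)] <- TRUE
    }
    sum(covered) / len >= min_frac
}

#' Assign one ASV to a species, species complex, higher taxon or non-fish
#'
#' Implements the annotation decision algorithm on the saturated top-score
#' hit stratum:
#' \enumerate{
#'   \item no hits: \emph{unassigned};
#'   \item top hits exclusively from the background database:
#'     \emph{nonfish}, labeled with the background taxon (a score tie
#'     between fish and background hits is resolved toward fish and
#'     flagged);
#'   \item fish hits below the species threshold: \emph{higher_taxon} --
#'     the lowest common ancestor of the top-hit species;
#'   \item fish hits at or above the threshold: the distinct top-hit
#'     species are filtered -- nonbinomial species are dropped when at
#'     least one binomial is present, then species whose every supporting
#'     hit lies in heterospecific reference territory are dropped. One
#'     survivor is a \emph{species} call; several survivors form a
#'     \emph{species_complex} (alphabetical, joined by `/`); if the
#'     filters remove everything, the unfiltered species set is restored
#'     and flagged `all_filtered_fallback`.
#' }
#'
#' @param asv_id id of the ASV (bookkeeping only).
#' @param hits top-score hit stratum from [search_with_fallback()].
#' @param chunk_statuses `mb_chunks` table for the reference database (may
#'   be `NULL`: heterospecific filtering disabled).
#' @param taxonomy taxonomy table ([taxonomy_table()]).
#' @param threshold species-level identity threshold in percent
#'   (default 99; adjustable).
#' @param hetero_overlap_frac fraction of a hit interval that must be
#'   heterospecific for exclusion (default 0.5).
#' @return list of class `mb_annotation`: `asv_id`, `category`, `taxa`,
#'   `rank`, `best_identity`, `evidence` (retained hits), `notes`.
#' @export
annotate_asv <- function(asv_id, hits, chunk_statuses, taxonomy,
                         threshold = 99, hetero_overlap_frac = 0.5) {
    notes <- character(0)
    res <- function(category, taxa, rank = NA_character_,
                    best_identity = NA_real_, evidence = hits)
        structure(list(asv_id = asv_id, category = category,
                       taxa = taxa, rank = rank,
                       best_identity = best_identity,
                       evidence = evidence, notes = notes),
                  class = "mb_annotation")
    if (is.null(hits) || nrow(hits) == 0L)
        return(res("unassigned", character(0), evidence = .empty_hits()))
    fish <- hits[hits$subject_is_fish %in% TRUE, , drop = FALSE]
    nonfish <- hits[!(hits$subject_is_fish %in% TRUE), , drop = FALSE]
    if (nrow(fish) == 0L)
        return(res("nonfish", nonfish$taxon[1],
                   best_identity = max(nonfish$identity)))
    if (nrow(nonfish) > 0L)
        notes <- c(notes, "score_tie_with_nonfish")
    best_id <- max(fish$identity)
    if (best_id < threshold) {
        lca <- lowest_common_ancestor(unique(fish$species), taxonomy)
        return(res("higher_taxon", lca$name, rank = lca$rank,
                   best_identity = best_id, evidence = fish))
    }
    species <- sort(unique(fish$species))
    kept <- species
    # nonbinomial filter
    bin <- is_binomial(kept)
    if (any(bin) && any(!bin)) {
        notes <- c(notes, "nonbinomial_filtered")
        kept <- kept[bin]
    }
    # heterospecific filter
    if (!is.null(chunk_statuses)) {
        supported <- vapply(kept, function(sp) {
            hk <- fish[fish$species == sp, , drop = FALSE]
            any(vapply(seq_len(nrow(hk)), function(r) {
                ch <- chunk_statuses[
                    chunk_statuses$record_id == hk$subject_id[r], ,
                    drop = FALSE]
                !overlaps_heterospecific(hk$subject_start[r],
                                         hk$subject_end[r], ch,
                                         min_frac = hetero_overlap_frac)
            }, logical(1)))
        }, logical(1))
        if (any(!supported) && any(supported)) {
            notes <- c(notes, "heterospecific_filtered")
            kept <- kept[supported]
        } else if (all(!supported) && length(kept) > 0L) {
            notes <- c(notes, "all_hits_heterospecific")
        }
    }
    if (length(kept) == 0L) {
        notes <- c(notes, "all_filtered_fallback")
        kept <- species
    }
    if (length(kept) == 1L)
        return(res("species", kept, rank = "species",
                   best_identity = best_id, evidence = fish))
    res("species_complex", sort(kept), rank = "species",
        best_identity = best_id, evidence = fish)
}

#' Label of an annotation (complex members joined by "/")
#' @param taxa character vector of taxa.
#' @return single label string.
#' @export
complex_label <- function(taxa) paste(sort(taxa), collapse = "/")

#' Annotate every ASV of a set against reference + background
#'
#' Runs [search_with_fallback()] and [annotate_asv()] for each ASV.
#'
#' @param asvs an `mb_asvs` object.
#' @param db an `mb_searchdb` from [combined_search_db()].
#' @param chunk_statuses,taxonomy,threshold,hetero_overlap_frac see
#'   [annotate_asv()].
#' @return list of `mb_annotation` objects, one per ASV.
#' @export
annotate_asvs <- function(asvs, db, chunk_statuses = NULL, taxonomy,
                          threshold = 99, hetero_overlap_frac = 0.5) {
    lapply(seq_len(nrow(asvs$asvs)), function(i) {
        q <- setNames(asvs$asvs$sequence[i], asvs$asvs$asv_id[i])
        sr <- search_with_fallback(q, db, species_threshold = threshold)
        bad <- setdiff(sr$hits$subject_id, db$meta$id)
        if (length(bad) > 0L)
            stop("hit references unknown subject id: ",
                 paste(bad, collapse = ", "))
        annotate_asv(asvs$asvs$asv_id[i], sr$hits, chunk_statuses, taxonomy,
                     threshold, hetero_overlap_frac)
    })
}

#' Summarize annotations into the three result tables
#'
#' Species-level calls (single species and species complexes) are
#' aggregated by taxon label, summing read counts of all member ASVs per
#' sample. Higher-taxon and non-fish calls keep one row per ASV with its
#' MD5 checksum. Total reads are conserved across the three tables plus
#' the unassigned remainder.
#'
#' @param annotations list of `mb_annotation` (from [annotate_asvs()]).
#' @param asvs the `mb_asvs` object the annotations refer to.
#' @return list with data.frames `species` (label, members, best_identity,
#'   notes, per-sample counts), `higher` and `nonfish` (asv_id, taxon,
#'   rank/identity, md5, per-sample counts), `unassigned` (asv_id, md5,
#'   per-sample counts).
#' @export
summarize_tables <- function(annotations, asvs) {
    samples <- colnames(asvs$counts)
    cnt <- function(i) asvs$counts[i, , drop = FALSE]
    idx <- setNames(seq_len(nrow(asvs$asvs)), asvs$asvs$asv_id)
    sp_rows <- list(); hi_rows <- list(); nf_rows <- list(); un_rows <- list()
    for (a in annotations) {
        i <- idx[[a$asv_id]]
        if (a$category %in% c("species", "species_complex")) {
            lab <- complex_label(a$taxa)
            if (is.null(sp_rows[[lab]])) {
                sp_rows[[lab]] <- list(label = lab, members = list(a$taxa),
                                       best_identity = a$best_identity,
                                       notes = paste(a$notes, collapse = ";"),
                                       counts = cnt(i))
            } else {
                sp_rows[[lab]]$counts <- sp_rows[[lab]]$counts + cnt(i)
                sp_rows[[lab]]$best_identity <-
                    max(sp_rows[[lab]]$best_identity, a$best_identity)
            }
        } else if (a$category == "higher_taxon") {
            hi_rows[[a$asv_id]] <- data.frame(
                asv_id = a$asv_id, taxon = a$taxa, rank = a$rank,
                best_identity = a$best_identity,
                md5 = asvs$asvs$md5[i], cnt(i), check.names = FALSE,
                stringsAsFactors = FALSE)
        } else if (a$category == "nonfish") {
            nf_rows[[a$asv_id]] <- data.frame(
                asv_id = a$asv_id, taxon = a$taxa,
                best_identity = a$best_identity,
                md5 = asvs$asvs$md5[i], cnt(i), check.names = FALSE,
                stringsAsFactors = FALSE)
        } else {
            un_rows[[a$asv_id]] <- data.frame(
                asv_id = a$asv_id, md5 = asvs$asvs$md5[i], cnt(i),
                check.names = FALSE, stringsAsFactors = FALSE)
        }
    }
    bind <- function(rows, cols) {
        if (length(rows) == 0L) {
            df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                         cols), stringsAsFactors = FALSE)
            for (s in samples) df[[s]] <- integer(0)
            return(df)
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    }
    sp <- if (length(sp_rows) == 0L) {
        df <- data.frame(label = character(0), best_identity = numeric(0),
                         notes = character(0), stringsAsFactors = FALSE)
        df$members <- list()
        for (s in samples) df[[s]] <- integer(0)
        df
    } else {
        df <- data.frame(
            label = vapply(sp_rows, `[[`, "", "label"),
            best_identity = vapply(sp_rows, `[[`, 0, "best_identity"),
            notes = vapply(sp_rows, `[[`, "", "notes"),
            stringsAsFactors = FALSE)
        df$members <- lapply(sp_rows, function(r) r$members[[1]])
        cm <- do.call(rbind, lapply(sp_rows, `[[`, "counts"))
        for (s in samples) df[[s]] <- as.integer(cm[, s])
        rownames(df) <- NULL
        df
    }
    list(species = sp,
         higher = bind(hi_rows, c("asv_id", "taxon", "rank",
                                  "best_identity", "md5")),
         nonfish = bind(nf_rows, c("asv_id", "taxon", "best_identity",
                                   "md5")),
         unassigned = bind(un_rows, c("asv_id", "md5")))
}
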