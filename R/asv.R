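#' MD5 digest of a DNA sequence
#'
#' ASVs reported in the higher-taxon and non-fish tables carry the MD5
#' checksum of their sequence so they can be tracked across reanalyses.
#' The digest is computed over the uppercase sequence bytes.
#'
#' @param sequence character vector of DNA sequences.
#' @return lowercase 32-character hex digests.
#' @examples
#' md5_of_sequence("ACGT")
#' @export
md5_of_sequence <- function(sequence) {
    vapply(sequence, function(s) {
        s <- toupper(s)
        if (!nzchar(s)) stop("sequence must be non-empty")
        tf <- tempfile()
        on.exit(unlink(tf))
        writeBin(charToRaw(s), tf)
        unname(tools::md5sum(tf))
    }, character(1), USE.NAMES = FALSE)
}

#' Dereplicate reads into unique sequences
#'
#' @param reads character vector or `DNAStringSet` of (primer-trimmed)
#'   reads.
#' @return data.frame with `sequence` and `abundance`, sorted by abundance
#'   descending then sequence ascending.
#' @export
dereplicate <- function(reads) {
    reads <- toupper(as.character(reads))
    if (length(reads) == 0L)
        return(data.frame(sequence = character(0), abundance = integer(0)))
    tab <- table(reads)
    out <- data.frame(sequence = names(tab),
                      abundance = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$abundance, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Simple abundance-skew denoising of dereplicated reads
#'
#' A deliberately transparent stand-in for UNOISE-style denoisers: unique
#' sequences are visited in decreasing abundance; a sequence is absorbed
#' into an earlier (more abundant) sequence when it lies within `max_dist`
#' substitutions of it and that sequence is at least `skew` times more
#' abundant -- the signature of a sequencing-error satellite. Surviving
#' sequences with abundance at or above `min_abundance` become ASVs;
#' unabsorbed sequences below `min_abundance` are discarded (their total
#' abundance is reported in the `"discarded_abundance"` attribute, so read
#' counts can be reconciled). With `min_abundance = 1` total abundance is
#' conserved exactly.
#'
#' @param uniques data.frame from [dereplicate()].
#' @param min_abundance minimum abundance for an unabsorbed sequence to be
#'   kept (default 2).
#' @param max_dist maximum substitution distance for absorption (default 1;
#'   only equal-length sequences are compared).
#' @param skew minimum abundance ratio parent/satellite (default 8).
#' @return data.frame with `sequence`, `abundance` (absorbed counts
#'   included) and an `"absorption"` attribute mapping every input sequence
#'   to the sequence that now holds its reads (`NA` for discarded).
#' @export
denoise_simple <- function(uniques, min_abundance = 2, max_dist = 1,
                           skew = 8) {
    uniques <- uniques[order(-uniques$abundance, uniques$sequence), ,
                       drop = FALSE]
    n <- nrow(uniques)
    parent <- rep(NA_integer_, n)    # index of absorbing founder
    founders <- integer(0)
    total <- numeric(n)
    for (k in seq_len(n)) {
        absorbed <- FALSE
        for (f in founders) {
            if (uniques$abundance[f] < skew * uniques$abundance[k]) next
            d <- .hamming_cpp(uniques$sequence[k], uniques$sequence[f])
            if (d >= 0L && d <= max_dist) {
                parent[k] <- f
                total[f] <- total[f] + uniques$abundance[k]
                absorbed <- TRUE
                break
            }
        }
        if (!absorbed) {
            founders <- c(founders, k)
            parent[k] <- k
            total[k] <- total[k] + uniques$abundance[k]
        }
    }
    keep <- founders[uniques$abundance[founders] >= min_abundance]
    discarded <- sum(total[setdiff(founders, keep)])
    parent[parent %in% setdiff(founders, keep)] <- NA_integer_
    out <- data.frame(sequence = uniques$sequence[keep],
                      abundance = as.integer(total[keep]),
                      stringsAsFactors = FALSE)
    ord <- order(-out$abundance, out$sequence)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    absorption <- setNames(uniques$sequence[parent], uniques$sequence)
    attr(out, "absorption") <- absorption
    attr(out, "discarded_abundance") <- as.integer(discarded)
    out
}

#' Greedy clustering of noisy long reads
#'
#' Reads are sorted by decreasing length (ties by id) and clustered in one
#' greedy pass: a read joins the first existing centroid whose
#' global-alignment identity is at or above `identity`, otherwise it founds
#' a new cluster. The alignment uses long-read-appropriate penalties:
#' internal gap open 4, terminal gap open 2 (extensions 2 and 1), i.e.
#' terminal gaps -- ubiquitous with ragged amplicon ends -- are charged
#' mildly. Deterministic given the sort.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param identity inclusive identity threshold in percent (default 97).
#' @return list of clusters (class `mb_clusters`); each cluster has
#'   `centroid_id`, `centroid`, `member_ids`, `members`, `size`.
#' @export
nanopore_cluster <- function(reads, identity = 97) {
    reads <- setNames(toupper(as.character(reads)), names(reads))
    if (is.null(names(reads)))
        names(reads) <- sprintf("read_%d", seq_along(reads))
    ord <- order(-nchar(reads), names(reads))
    reads <- reads[ord]
    clusters <- list()
    for (k in seq_along(reads)) {
        joined <- FALSE
        for (c in seq_along(clusters)) {
            cen <- clusters[[c]]$centroid
            lr <- nchar(reads[[k]]) / nchar(cen)
            if (min(lr, 1 / lr) * 100 < identity) next  # length bound
            aln <- .nanopore_align(reads[[k]], cen)
            if (aln$identity >= identity) {
                clusters[[c]]$member_ids <- c(clusters[[c]]$member_ids,
                                              names(reads)[k])
                clusters[[c]]$members <- c(clusters[[c]]$members, reads[[k]])
                clusters[[c]]$size <- clusters[[c]]$size + 1L
                joined <- TRUE
                break
            }
        }
        if (!joined)
            clusters[[length(clusters) + 1L]] <- list(
                centroid_id = names(reads)[k], centroid = reads[[k]],
                member_ids = names(reads)[k], members = reads[[k]],
                size = 1L)
    }
    structure(clusters, class = "mb_clusters")
}

.nanopore_align <- function(query, subject) {
    pairwise_alignment(query, subject, mode = "global",
                       match = 2, mismatch = -4,
                       gap_open = 4, gap_ext = 2,
                       term_open = 2, term_ext = 1)
}

#' Consensus sequence of a read cluster
#'
#' Members are aligned pairwise to the centroid. For every centroid column
#' the plurality base among members wins (deletion counts as a vote for
#' absence; ties go to the centroid base). Insertions relative to the
#' centroid are kept only when present in more than half of the members (the
#' plurality inserted string is used). A singleton cluster returns its read
#' verbatim.
#'
#' @param cluster one element of an `mb_clusters` list.
#' @return the consensus DNA string.
#' @export
cluster_consensus <- function(cluster) {
    if (cluster$size == 1L) return(cluster$members[[1]])
    cen <- cluster$centroid
    L <- nchar(cen)
    n <- cluster$size
    votes <- matrix("", nrow = n, ncol = L)
    insertions <- vector("list", n)   # per member: named list pos -> string
    for (i in seq_len(n)) {
        aln <- .nanopore_align(cluster$members[[i]], cen)
        qa <- strsplit(aln$aligned_query, "")[[1]]
        sa <- strsplit(aln$aligned_subject, "")[[1]]
        cpos <- 0L
        ins <- list()
        for (k in seq_along(sa)) {
            if (sa[k] != "-") {
                cpos <- cpos + 1L
                votes[i, cpos] <- qa[k]
            } else if (qa[k] != "-") {
                key <- as.character(cpos)   # insertion after centroid cpos
                ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]],
                                     qa[k])
            }
        }
        insertions[[i]] <- ins
    }
    cen_bases <- strsplit(cen, "")[[1]]
    pieces <- character(0)
    emit_insertion <- function(pos) {
        strs <- vapply(insertions, function(ins) {
            v <- ins[[as.character(pos)]]
            if (is.null(v)) "" else v
        }, character(1))
        present <- strs[nzchar(strs)]
        if (length(present) * 2L > n) {
            tab <- sort(table(present), decreasing = TRUE)
            top <- names(tab)[tab == max(tab)]
            sort(top)[1]
        } else ""
    }
    pieces <- c(pieces, emit_insertion(0L))
    for (p in seq_len(L)) {
        v <- votes[, p]
        tab <- table(v)
        winners <- names(tab)[tab == max(tab)]
        base <- if (cen_bases[p] %in% winners) cen_bases[p] else winners[1]
        if (base != "-") pieces <- c(pieces, base)
        pieces <- c(pieces, emit_insertion(p))
    }
    paste(pieces, collapse = "")
}

.new_asv_set <- function(sequences, counts) {
    ids <- sprintf("asv_%d", seq_along(sequences))
    structure(list(
        asvs = data.frame(asv_id = ids, sequence = sequences,
                          md5 = md5_of_sequence(sequences),
                          stringsAsFactors = FALSE),
        counts = matrix(counts, nrow = length(sequences),
                        dimnames = list(ids, colnames(counts)))),
        class = "mb_asvs")
}

#' Build ASVs from short accurate reads (multi-sample)
#'
#' Pools reads across samples, dereplicates and denoises them
#' ([denoise_simple()]), then distributes per-sample counts through the
#' absorption map.
#'
#' @param reads_by_sample named list of character vectors / `DNAStringSet`s.
#' @param min_abundance,max_dist,skew see [denoise_simple()].
#' @return an `mb_asvs` object: `$asvs` (asv_id, sequence, md5) and
#'   `$counts` (ASV x sample matrix).
#' @export
illumina_asvs <- function(reads_by_sample, min_abundance = 2, max_dist = 1,
                          skew = 8) {
    stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
    pooled <- dereplicate(unlist(lapply(reads_by_sample, as.character),
                                 use.names = FALSE))
    den <- denoise_simple(pooled, min_abundance, max_dist, skew)
    absorption <- attr(den, "absorption")
    samples <- names(reads_by_sample)
    counts <- matrix(0L, nrow = nrow(den), ncol = length(samples),
                     dimnames = list(NULL, samples))
    for (s in samples) {
        der <- dereplicate(reads_by_sample[[s]])
        i <- match(absorption[der$sequence], den$sequence)
        for (k in seq_len(nrow(der)))
            if (!is.na(i[k]))
                counts[i[k], s] <- counts[i[k], s] + der$abundance[k]
    }
    out <- .new_asv_set(den$sequence, counts)
    attr(out, "discarded_abundance") <- attr(den, "discarded_abundance")
    out
}

#' Build ASVs from noisy long reads (multi-sample)
#'
#' Pools reads, clusters them greedily at `identity` percent
#' ([nanopore_cluster()]) and uses each cluster's consensus
#' ([cluster_consensus()]) as an ASV; per-sample counts come from member
#' provenance. All clusters are emitted; downstream abundance filters act
#' on the counts.
#'
#' @param reads_by_sample named list of character vectors / `DNAStringSet`s.
#' @param identity clustering identity threshold in percent (default 97,
#'   suited to accurate long reads; for noisier reads the threshold should
#'   sit between the within-template and cross-template read-pair
#'   identities, e.g. 90 at a 3 percent per-base error rate).
#' @param min_cluster_size smallest cluster emitted as an ASV (default 1:
#'   emit all; stray error-rich reads that join no cluster form singletons,
#'   which a floor of 2-3 removes).
#' @param merge_identity after consensus calling, consensus sequences at or
#'   above this global identity are merged into one ASV (counts summed).
#'   Greedy clustering can split one template across clusters when an
#'   error-rich read founds a centroid; the denoised consensuses of such
#'   clusters are near-identical and collapse here. Default 97 (the
#'   ASV-level identity); `NULL` disables merging.
#' @return an `mb_asvs` object.
#' @export
nanopore_asvs <- function(reads_by_sample, identity = 97,
                          min_cluster_size = 1, merge_identity = 97) {
    stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
    samples <- names(reads_by_sample)
    pooled <- character(0)
    for (s in samples) {
        r <- as.character(reads_by_sample[[s]])
        nm <- names(reads_by_sample[[s]])
        if (is.null(nm)) nm <- sprintf("r%d", seq_along(r))
        pooled <- c(pooled, setNames(r, paste0(s, "\r", nm)))
    }
    cl <- nanopore_cluster(pooled, identity = identity)
    seqs <- vapply(cl, cluster_consensus, character(1))
    counts <- matrix(0L, nrow = length(cl), ncol = length(samples),
                     dimnames = list(NULL, samples))
    for (c in seq_along(cl)) {
        src <- sub("\r.*$", "", cl[[c]]$member_ids)
        tab <- table(factor(src, levels = samples))
        counts[c, ] <- as.integer(tab)
    }
    if (!is.null(merge_identity) && length(cl) > 1L) {
        ord <- order(-rowSums(counts), seqs)
        keep <- integer(0)
        dest <- integer(length(cl))
        for (k in ord) {
            hit <- 0L
            for (j in keep) {
                aln <- .nanopore_align(seqs[k], seqs[j])
                if (aln$identity >= merge_identity) { hit <- j; break }
            }
            if (hit > 0L) dest[k] <- hit
            else { keep <- c(keep, k); dest[k] <- k }
        }
        merged_counts <- rowsum(counts, group = dest, reorder = FALSE)
        keep_in_order <- as.integer(rownames(merged_counts))
        seqs <- seqs[keep_in_order]
        counts <- merged_counts
        dimnames(counts) <- list(NULL, samples)
    }
    sizes <- rowSums(counts)
    ok <- sizes >= min_cluster_size
    if (!any(ok)) stop("no cluster reached min_cluster_size")
    .new_asv_set(seqs[ok], counts[ok, , drop = FALSE])
}

#' Load precomputed ASVs/OTUs from a FASTA file
#'
#' Supports reanalysis against an updated reference without repeating the
#' read-processing stage. Headers of the form `>id;size=<n>` carry a total
#' abundance (assigned to a single pseudo-sample `"sample"` unless
#' `sample_id` is given); otherwise each ASV gets count 1.
#'
#' @param path FASTA file of ASV/OTU sequences.
#' @param sample_id column name for the counts (default `"sample"`).
#' @return an `mb_asvs` object.
#' @export
read_asv_fasta <- function(path, sample_id = "sample") {
    ss <- Biostrings::readDNAStringSet(path)
    sz <- suppressWarnings(as.integer(sub("^.*;size=(\\d+).*$", "\\1",
                                          names(ss))))
    sz[is.na(sz)] <- 1L
    counts <- matrix(sz, ncol = 1, dimnames = list(NULL, sample_id))
    .new_asv_set(toupper(as.character(ss)), counts)
}

#' Write ASVs as FASTA plus a per-sample count table
#' @param asvs an `mb_asvs` object.
#' @param fasta,counts_tsv output paths (`NULL` to skip one of them).
#' @export
write_asvs <- function(asvs, fasta = NULL, counts_tsv = NULL) {
    if (!is.null(fasta)) {
        total <- rowSums(asvs$counts)
        ss <- Biostrings::DNAStringSet(setNames(
            asvs$asvs$sequence,
            sprintf("%s;size=%d", asvs$asvs$asv_id, as.integer(total))))
        Biostrings::writeXStringSet(ss, fasta)
    }
    if (!is.null(counts_tsv)) {
        df <- data.frame(asv_id = asvs$asvs$asv_id, asvs$counts,
                         check.names = FALSE)
        write.table(df, counts_tsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(asvs)
}
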