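# Independent oracles and small fixture builders used across tests.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

point_mutate <- function(seq, positions) {
    b <- strsplit(seq, "")[[1]]
    for (p in positions)
        b[p] <- c(A = "C", C = "G", G = "T", T = "A")[b[p]]
    paste(b, collapse = "")
}

# Exhaustive all-pairs best subject: aligns the query (both strands,
# semi-global) against every subject with no seed filtering, applies the
# 80% coverage gate and returns the best score and the subjects attaining
# it. Independent of the search path (no word filter, no ranking code).
oracle_best_subject <- function(query, seqs, min_coverage = 80) {
    qrc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(query)))
    score <- rep(-Inf, length(seqs))
    for (j in seq_along(seqs)) {
        for (q in c(query, qrc)) {
            a <- pairwise_alignment(q, seqs[[j]], mode = "semi-global")
            if (a$query_coverage >= min_coverage && a$score > score[j])
                score[j] <- a$score
        }
    }
    if (all(!is.finite(score)))
        return(list(best_score = NA_real_, best_ids = character(0)))
    mx <- max(score)
    list(best_score = mx,
         best_ids = sort(names(seqs)[round(score, 1) == round(mx, 1)]))
}

# Global alignment score via Biostrings (independent DP implementation,
# same scoring convention: gap of length L costs open + L * ext).
biostrings_global_score <- function(q, s, match = 2, mismatch = -3,
                                    gap_open = 5, gap_ext = 2) {
    m <- matrix(mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
    diag(m) <- match
    Biostrings::pairwiseAlignment(q, s, substitutionMatrix = m,
                                  gapOpening = gap_open,
                                  gapExtension = gap_ext,
                                  type = "global", scoreOnly = TRUE)
}

# hit-row builder matching the search engine's hit schema
make_hit <- function(subject_id, species = NA_character_, is_fish = TRUE,
                     identity = 100, score = 300, sstart = 0L, send = 150L,
                     taxon = species, query_id = "asv_1") {
    data.frame(query_id = query_id, subject_id = subject_id,
               subject_is_fish = is_fish, identity = identity,
               query_coverage = 100, score = score,
               columns = send - sstart, mismatches = 0L, gap_opens = 0L,
               query_start = 0L, query_end = send - sstart,
               subject_start = as.integer(sstart),
               subject_end = as.integer(send), strand = "+",
               species = species, taxon = taxon, stringsAsFactors = FALSE)
}

# small taxonomy fixture: 4 species, 2 genera, 2 families, 2 orders
toy_taxonomy <- function() {
    data.frame(
        species = c("Gena spa", "Gena spb", "Genb spa", "Genc spa"),
        genus = c("Gena", "Gena", "Genb", "Genc"),
        family = c("Fama", "Fama", "Fama", "Famb"),
        order = c("Orda", "Orda", "Orda", "Ordb"),
        stringsAsFactors = FALSE)
}
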