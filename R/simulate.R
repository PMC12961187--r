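#' Random DNA sequence
#' @param n length.
#' @return a DNA string.
#' @keywords internal
random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence by point substitutions
#'
#' Substitutes `round(divergence * width)` distinct positions (within
#' `region` when given, 0-based half-open) to a different base each.
#' @param seq DNA string.
#' @param divergence substitution fraction in (0, 0.5).
#' @param region optional `c(start, end)` restricting mutated positions.
#' @return the mutated string.
#' @keywords internal
mutate_sequence <- function(seq, divergence, region = NULL) {
    bases <- strsplit(seq, "")[[1]]
    idx <- if (is.null(region)) seq_along(bases)
           else (region[1] + 1L):region[2]
    k <- round(divergence * length(idx))
    if (k < 1L) return(seq)
    pos <- sample(idx, k)
    for (p in pos)
        bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
    paste(bases, collapse = "")
}

#' Generate a synthetic reference database with known ground truth
#'
#' Species marker sequences are produced by mutating a common root at the
#' stated divergence (star phylogeny: pairwise divergence is roughly twice
#' `divergence`). Each species gets `n_records_per_species` records: the
#' first is the species sequence, later ones append 10 extra 3' bases per
#' copy so that records are distinct (and survive identical-sequence
#' merging) yet corroborate each other's chunks exactly. Every record
#' carries an author drawn from a rotating pool, so same-species records
#' come from disjoint author sets. Deterministic per seed.
#'
#' @param n_species number of species (assigned 2 per genus, 2 genera per
#'   family).
#' @param gene_length marker gene length in bp.
#' @param divergence per-species substitution fraction from the root.
#' @param n_records_per_species records per species (default 2).
#' @param n_author_pools number of distinct author names to rotate through
#'   (default: one per record, i.e. all disjoint).
#' @param seed integer RNG seed.
#' @return list with `db` (an `mb_refdb`) and `truth` (`templates`: named
#'   species sequences; `seed`).
#' @export
make_reference_db <- function(n_species, gene_length = 650,
                              divergence = 0.08,
                              n_records_per_species = 2,
                              n_author_pools =
                                  n_species * n_records_per_species,
                              seed = 1) {
    stopifnot(divergence > 0, divergence < 0.5)
    set.seed(seed)
    root <- random_dna(gene_length)
    sp_names <- character(n_species)
    genera <- character(n_species); families <- character(n_species)
    orders <- character(n_species)
    for (i in seq_len(n_species)) {
        g <- (i - 1L) %/% 2L + 1L          # 2 species per genus
        f <- (g - 1L) %/% 2L + 1L          # 2 genera per family
        o <- (f - 1L) %/% 2L + 1L
        genera[i] <- paste0("Fishgen", letters[g])
        families[i] <- paste0("Famil", letters[f], "idae")
        orders[i] <- paste0("Order", letters[o], "formes")
        sp_names[i] <- paste0(genera[i], " sp", letters[(i - 1L) %% 2L + 1L])
    }
    templates <- setNames(
        vapply(seq_len(n_species), function(i)
            mutate_sequence(root, divergence), character(1)),
        sp_names)
    rec <- list(); k <- 0L
    for (i in seq_len(n_species)) {
        for (j in seq_len(n_records_per_species)) {
            k <- k + 1L
            seq <- templates[[i]]
            if (j > 1L) seq <- paste0(seq, random_dna(10L * (j - 1L)))
            pool <- (k - 1L) %% n_author_pools + 1L
            rec[[k]] <- list(
                record_id = sprintf("REF%03d", k),
                sequence = seq, species = sp_names[i], genus = genera[i],
                family = families[i], order = orders[i],
                authors = sprintf("Author pool%02d", pool))
        }
    }
    db <- reference_db(
        record_id = vapply(rec, `[[`, "", "record_id"),
        sequence = vapply(rec, `[[`, "", "sequence"),
        gene = rep("12S rRNA", k),
        species = vapply(rec, `[[`, "", "species"),
        genus = vapply(rec, `[[`, "", "genus"),
        family = vapply(rec, `[[`, "", "family"),
        order = vapply(rec, `[[`, "", "order"),
        authors = lapply(rec, `[[`, "authors"))
    list(db = db, truth = list(templates = templates, seed = seed))
}

#' Plant a heterospecific (chimeric) segment into a reference record
#'
#' Replaces `interval` (0-based half-open) of the record's sequence with
#' the matching subsequence of `donor_sequence`, emulating chimeric
#' contamination of deposited records.
#'
#' @param db an `mb_refdb`.
#' @param record_id record to modify.
#' @param donor_sequence sequence of the (divergent) donor species; must be
#'   at least `interval[2]` long.
#' @param interval integer `c(start, end)`.
#' @return the modified `mb_refdb`.
#' @export
plant_chimera <- function(db, record_id, donor_sequence, interval) {
    i <- match(record_id, db$record_id)
    if (is.na(i)) stop("unknown record id: ", record_id)
    len <- nchar(db$sequence[i])
    if (interval[1] < 0 || interval[2] > len || interval[1] >= interval[2])
        stop("interval out of bounds")
    if (nchar(donor_sequence) < interval[2])
        stop("donor sequence shorter than interval end")
    seg <- substr(donor_sequence, interval[1] + 1L, interval[2])
    db$sequence[i] <- paste0(substr(db$sequence[i], 1L, interval[1]), seg,
                             substr(db$sequence[i], interval[2] + 1L, len))
    db
}

.add_read_errors <- function(seq, platform, error_rate) {
    if (error_rate <= 0) return(seq)
    bases <- strsplit(seq, "")[[1]]
    out <- character(0)
    for (b in bases) {
        if (stats::runif(1) < error_rate) {
            if (platform == "illumina") {
                out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b), 1))
            } else {
                # long-read error mix: 40% substitution, 30% ins, 30% del
                u <- stats::runif(1)
                if (u < 0.4)
                    out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b), 1))
                else if (u < 0.7)
                    out <- c(out, b, sample(c("A", "C", "G", "T"), 1))
                # else deletion: emit nothing
            }
        } else out <- c(out, b)
    }
    paste(out, collapse = "")
}

#' Simulate multi-sample amplicon reads with known provenance
#'
#' For each sample, reads are drawn multinomially from the template species
#' according to the composition weights and corrupted with
#' platform-appropriate errors: per-base substitutions for `"illumina"`, a
#' 40/30/30 substitution/insertion/deletion mix at the stated per-base rate
#' for `"nanopore"`. Deterministic per seed; read names record the source
#' species.
#'
#' @param compositions named list: sample id -> named numeric vector of
#'   species weights.
#' @param templates named character vector of template (amplicon)
#'   sequences per species.
#' @param platform `"illumina"` or `"nanopore"`.
#' @param error_rate per-base error rate (>= 0).
#' @param n_reads reads per sample (single value or named per sample;
#'   ignored when `exact_counts = TRUE`).
#' @param seed integer RNG seed.
#' @param exact_counts when `TRUE` the composition weights are taken as
#'   exact per-species read counts instead of multinomial weights.
#' @return named list of named character vectors (reads per sample); the
#'   `"provenance"` attribute of each vector gives the source species.
#' @export
simulate_reads <- function(compositions, templates,
                           platform = c("illumina", "nanopore"),
                           error_rate = 0.001, n_reads = 100, seed = 1,
                           exact_counts = FALSE) {
    platform <- match.arg(platform)
    stopifnot(error_rate >= 0)
    set.seed(seed)
    if (length(n_reads) == 1L)
        n_reads <- setNames(rep(n_reads, length(compositions)),
                            names(compositions))
    out <- list()
    for (s in names(compositions)) {
        w <- compositions[[s]]
        stopifnot(all(names(w) %in% names(templates)))
        src <- if (exact_counts) sample(rep(names(w), times = w))
               else sample(names(w), n_reads[[s]], replace = TRUE,
                           prob = w / sum(w))
        reads <- vapply(src, function(sp)
            .add_read_errors(templates[[sp]], platform, error_rate),
            character(1))
        names(reads) <- sprintf("%s_read%04d", s, seq_along(reads))
        attr(reads, "provenance") <- unname(src)
        out[[s]] <- reads
    }
    out
}

#' Generate non-fish background contaminant sequences
#'
#' Independent random sequences (hence far from any fish template) labeled
#' with non-fish taxa, standing in for off-target amplification sources.
#'
#' @param kinds character vector of taxon labels (e.g.
#'   `c("human", "frog", "bird")`).
#' @param length sequence length.
#' @param seed integer RNG seed.
#' @return data.frame with `id`, `sequence`, `taxon`.
#' @export
make_background_contaminants <- function(kinds = c("human", "frog", "bird"),
                                         length = 650, seed = 1) {
    if (base::length(kinds) == 0L)
        return(data.frame(id = character(0), sequence = character(0),
                          taxon = character(0)))
    set.seed(seed)
    data.frame(id = paste0("BG_", kinds),
               sequence = vapply(kinds, function(k) random_dna(length),
                                 character(1), USE.NAMES = FALSE),
               taxon = kinds, stringsAsFactors = FALSE)
}

#' Fixture preset: reference database with a planted chimeric record
#'
#' Six host species (two records each) plus two donor congeners that are
#' identical to each other across the terminal 150 bp window and divergent
#' elsewhere. The terminal 150 bp of one host record is replaced by the
#' donor segment -- emulating the documented pattern of chimeric terminal
#' rRNA regions in deposited mitogenomes. Truth records the modified
#' record, the interval, and the host and donor species.
#'
#' @param seed integer RNG seed.
#' @return list with `db`, `chunk-ready` truth fields (`chimera_record`,
#'   `interval`, `host_species`, `donor_species`, `templates`).
#' @export
preset_chimera <- function(seed = 1) {
    gene_length <- 650L
    interval <- c(500L, 650L)
    base <- make_reference_db(n_species = 6, gene_length = gene_length,
                              divergence = 0.08, n_records_per_species = 2,
                              seed = seed)
    db <- base$db
    set.seed(seed + 1000L)
    donor_root <- mutate_sequence(random_dna(gene_length), 0.0)
    d1 <- donor_root
    d2 <- mutate_sequence(d1, 0.06, region = c(0L, interval[1]))
    donor_sp <- c("Donorgen spa", "Donorgen spb")
    k0 <- nrow(db)
    donor_db <- reference_db(
        record_id = sprintf("REF%03d", k0 + 1:4),
        sequence = c(d1, paste0(d1, random_dna(10)),
                     d2, paste0(d2, random_dna(10))),
        gene = rep("12S rRNA", 4),
        species = rep(donor_sp, each = 2),
        genus = rep("Donorgen", 4),
        family = rep("Donoridae", 4),
        order = rep("Orderzformes", 4),
        authors = list("Author donor1", "Author donor2",
                       "Author donor3", "Author donor4"))
    db <- rbind(db, donor_db)
    class(db) <- c("mb_refdb", "data.frame")
    chim_rec <- "REF001"
    db <- plant_chimera(db, chim_rec, d1, interval)
    list(db = db,
         truth = list(chimera_record = chim_rec, interval = interval,
                      host_species = db$species[db$record_id == chim_rec],
                      donor_species = donor_sp,
                      donor_segment = substr(d1, interval[1] + 1L,
                                             interval[2]),
                      templates = base$truth$templates, seed = seed))
}

#' Fixture preset: long-read run over five well-separated species
#'
#' Five species at >= 5\% pairwise divergence (200 bp marker), 50
#' noisy long reads each at 3\% per-base error, one pooled sample; truth
#' lists the templates and the published-style species list. `params`
#' carries the analysis settings matched to this error rate: clustering
#' identity 90 (between the cross-template ~84\% and within-template ~94\%
#' read-pair identities implied by 3\% per-base error) and a cluster-size
#' floor of 3 to drop stray error-rich reads that join no cluster.
#'
#' @param seed integer RNG seed.
#' @return list with `db`, `reads_by_sample`, `published`, `params` and
#'   `truth`.
#' @export
preset_nanopore <- function(seed = 1) {
    base <- make_reference_db(n_species = 5, gene_length = 200,
                              divergence = 0.06, n_records_per_species = 2,
                              seed = seed)
    sp <- names(base$truth$templates)
    comp <- list(aquarium = setNames(rep(50, 5), sp))
    reads <- simulate_reads(comp, base$truth$templates,
                            platform = "nanopore", error_rate = 0.03,
                            seed = seed + 1L, exact_counts = TRUE)
    published <- data.frame(taxon = sp, level = "species",
                            stringsAsFactors = FALSE)
    list(db = base$db, reads_by_sample = reads, published = published,
         params = list(cluster_identity = 90, min_cluster_size = 3),
         truth = base$truth)
}

#' Fixture preset: multi-sample short-read design with controls
#'
#' Eight fish species (120 bp marker region), two replicates of one site, a
#' separate sample, a positive control carrying a mock species, a negative
#' control with a trace contaminant, and a human background contaminant in
#' one sample. Truth records per-sample species read counts.
#'
#' @param seed integer RNG seed.
#' @return list with `db`, `background`, `templates` (marker amplicons),
#'   `reads_by_sample`, `manifest`, `truth`.
#' @export
preset_multisample <- function(seed = 1) {
    base <- make_reference_db(n_species = 8, gene_length = 650,
                              divergence = 0.08, n_records_per_species = 2,
                              seed = seed)
    sp <- names(base$truth$templates)
    amplicon <- vapply(base$truth$templates, substr, "", 1L, 120L)
    bg <- make_background_contaminants("human", length = 650,
                                       seed = seed + 2L)
    templates <- c(amplicon,
                   setNames(substr(bg$sequence[1], 1, 120), "human"))
    comp <- list(
        rep1 = setNames(c(10, 8, 6, 4), sp[1:4]),
        rep2 = setNames(c(10, 8, 6, 4), sp[1:4]),
        siteB = setNames(c(6, 5, 2), c(sp[5], sp[6], "human")),
        pos_ctrl = setNames(1, sp[8]),
        neg_ctrl = setNames(1, sp[1]))
    n_reads <- c(rep1 = 280, rep2 = 280, siteB = 260, pos_ctrl = 60,
                 neg_ctrl = 4)
    reads <- simulate_reads(comp, templates, platform = "illumina",
                            error_rate = 0.001, n_reads = n_reads,
                            seed = seed + 3L)
    manifest <- sample_manifest(
        c("rep1", "rep2", "siteB", "pos_ctrl", "neg_ctrl"),
        role = c("sample", "sample", "sample", "positive_control",
                 "negative_control"),
        replicate_group = c("siteA", "siteA", NA, NA, NA))
    truth <- list(templates = templates, seed = seed,
                  sample_compositions = lapply(reads, function(r)
                      table(attr(r, "provenance"))))
    list(db = base$db, background = bg, templates = templates,
         reads_by_sample = reads, manifest = manifest, truth = truth)
}
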