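tax <- toy_taxonomy()

test_that("lowest common ancestor walks genus, family, order", {
    expect_equal(lowest_common_ancestor(c("Gena spa", "Gena spb"), tax),
                 list(name = "Gena", rank = "genus"))
    expect_equal(lowest_common_ancestor(c("Gena spa", "Genb spa"), tax),
                 list(name = "Fama", rank = "family"))
    expect_equal(lowest_common_ancestor(c("Gena spa", "Genc spa"), tax),
                 list(name = "Fish", rank = "root"))
    expect_equal(lowest_common_ancestor("Gena spa", tax),
                 list(name = "Gena", rank = "genus"))
    expect_error(lowest_common_ancestor("Nope spx", tax), "not in taxonomy")
})

test_that("heterospecific overlap uses the 50% interval-coverage rule", {
    ch <- data.frame(record_id = "R", start = c(0L, 100L),
                     end = c(100L, 200L),
                     status = c("heterospecific", "heterospecific"))
    expect_true(overlaps_heterospecific(0L, 170L, ch))
    expect_false(overlaps_heterospecific(
        0L, 170L, data.frame(start = 900L, end = 1000L,
                             status = "heterospecific")))
    # hit (50,250) vs het (100,200): 100/200 = 50% -> boundary inclusive
    ch2 <- data.frame(start = 100L, end = 200L, status = "heterospecific")
    expect_true(overlaps_heterospecific(50L, 250L, ch2))
    expect_false(overlaps_heterospecific(50L, 251L, ch2))
    # homospecific chunks never trigger
    ch3 <- data.frame(start = 0L, end = 200L, status = "homospecific")
    expect_false(overlaps_heterospecific(0L, 170L, ch3))
})

test_that("the annotation decision table covers every branch", {
    run <- function(hits, chunks = NULL, threshold = 99)
        annotate_asv("asv_1", hits, chunks, tax, threshold = threshold)
    # 1. no hits -> unassigned
    a <- run(NULL)
    expect_equal(a$category, "unassigned")
    expect_equal(nrow(a$evidence), 0L)
    # 2. background-only stratum -> nonfish
    a <- run(make_hit("BG_human", species = NA, is_fish = FALSE,
                      taxon = "human"))
    expect_equal(a$category, "nonfish")
    expect_equal(a$taxa, "human")
    # 3. sub-threshold -> higher taxon (LCA of the stratum)
    a <- run(rbind(make_hit("r1", "Gena spa", identity = 96),
                   make_hit("r2", "Gena spb", identity = 96)))
    expect_equal(a$category, "higher_taxon")
    expect_equal(a$taxa, "Gena")
    expect_equal(a$rank, "genus")
    # 4. sub-threshold single species -> its genus
    a <- run(make_hit("r1", "Gena spa", identity = 96))
    expect_equal(a$category, "higher_taxon")
    expect_equal(a$taxa, "Gena")
    # 5. single species at threshold -> species
    a <- run(make_hit("r1", "Gena spa", identity = 100))
    expect_equal(a$category, "species")
    expect_equal(a$taxa, "Gena spa")
    # 6. two species tied, neither filtered -> complex, sorted
    a <- run(rbind(make_hit("r2", "Gena spb", identity = 99.5),
                   make_hit("r1", "Gena spa", identity = 99.5)))
    expect_equal(a$category, "species_complex")
    expect_equal(a$taxa, c("Gena spa", "Gena spb"))
    # 7. nonbinomial dropped when a binomial coexists
    tax2 <- rbind(tax, data.frame(species = "Gena sp.", genus = "Gena",
                                  family = "Fama", order = "Orda"))
    a <- annotate_asv("asv_1",
                      rbind(make_hit("r1", "Gena sp."),
                            make_hit("r2", "Gena spa")), NULL, tax2)
    expect_equal(a$category, "species")
    expect_equal(a$taxa, "Gena spa")
    expect_true("nonbinomial_filtered" %in% a$notes)
    # 8. all-nonbinomial stratum keeps the nonbinomial species
    a <- annotate_asv("asv_1", make_hit("r1", "Gena sp."), NULL, tax2)
    expect_equal(a$category, "species")
    expect_equal(a$taxa, "Gena sp.")
    # 9. heterospecific filter resolves a complex to one species
    ch <- data.frame(record_id = "r1", start = 0L, end = 200L,
                     status = "heterospecific")
    a <- run(rbind(make_hit("r1", "Gena spa", sstart = 0, send = 150),
                   make_hit("r2", "Gena spb", sstart = 0, send = 150)),
             chunks = ch)
    expect_equal(a$category, "species")
    expect_equal(a$taxa, "Gena spb")
    expect_true("heterospecific_filtered" %in% a$notes)
    # 10. every species heterospecific -> set kept, flagged
    ch2 <- rbind(ch, data.frame(record_id = "r2", start = 0L, end = 200L,
                                status = "heterospecific"))
    a <- run(rbind(make_hit("r1", "Gena spa", sstart = 0, send = 150),
                   make_hit("r2", "Gena spb", sstart = 0, send = 150)),
             chunks = ch2)
    expect_equal(a$category, "species_complex")
    expect_true("all_hits_heterospecific" %in% a$notes)
    # 11. fish/background score tie -> fish, flagged
    a <- run(rbind(make_hit("r1", "Gena spa"),
                   make_hit("BG_h", species = NA, is_fish = FALSE,
                            taxon = "human")))
    expect_equal(a$category, "species")
    expect_true("score_tie_with_nonfish" %in% a$notes)
    # 12. a species survives when one of several hits is clean
    ch3 <- data.frame(record_id = "r1", start = 0L, end = 100L,
                      status = "heterospecific")
    a <- run(rbind(make_hit("r1", "Gena spa", sstart = 0, send = 150),
                   make_hit("r3", "Gena spa", sstart = 300, send = 450),
                   make_hit("r2", "Gena spb", sstart = 0, send = 150)),
             chunks = ch3)
    expect_equal(a$category, "species_complex")
    expect_equal(a$taxa, c("Gena spa", "Gena spb"))
    # unknown subject id in the wired pipeline raises an integrity error
    set.seed(71)
    sdb <- search_db(setNames(rand_dna(60), "known"))
    expect_error(annotate_asvs(
        structure(list(asvs = data.frame(asv_id = "x", sequence = "ACGT",
                                         md5 = md5_of_sequence("ACGT")),
                       counts = matrix(1, 1, 1,
                                       dimnames = list("x", "s1"))),
                  class = "mb_asvs"),
        sdb, NULL, tax), NA)   # no hits at all is fine, not an error
})

test_that("each ASV receives exactly one category", {
    cats <- c("unassigned", "nonfish", "higher_taxon", "species",
              "species_complex")
    scenarios <- list(
        NULL,
        make_hit("b", is_fish = FALSE, taxon = "frog"),
        make_hit("r1", "Gena spa", identity = 95),
        make_hit("r1", "Gena spa"),
        rbind(make_hit("r1", "Gena spa"), make_hit("r2", "Gena spb")))
    got <- vapply(scenarios, function(h)
        annotate_asv("a", h, NULL, tax)$category, character(1))
    expect_equal(got, cats)
})

test_that("raising the species threshold never promotes an ASV to species", {
    set.seed(72)
    for (k in 1:20) {
        id <- runif(1, 95, 100)
        h <- make_hit("r1", "Gena spa", identity = id)
        lo <- annotate_asv("a", h, NULL, tax, threshold = 97)$category
        hi <- annotate_asv("a", h, NULL, tax, threshold = 99)$category
        if (lo == "higher_taxon") expect_equal(hi, "higher_taxon")
        if (hi == "species") expect_equal(lo, "species")
    }
})

test_that("heterospecific filtering can only shrink a complex", {
    set.seed(73)
    sp <- c("Gena spa", "Gena spb", "Genb spa")
    hits <- do.call(rbind, lapply(seq_along(sp), function(i)
        make_hit(paste0("r", i), sp[i], sstart = 0, send = 150)))
    for (k in 1:10) {
        het_on <- sample(c(TRUE, FALSE), 3, replace = TRUE)
        ch <- do.call(rbind, lapply(which(het_on), function(i)
            data.frame(record_id = paste0("r", i), start = 0L, end = 200L,
                       status = "heterospecific")))
        base <- annotate_asv("a", hits, NULL, tax)
        filt <- annotate_asv("a", hits, ch, tax)
        expect_true(all(filt$taxa %in% base$taxa))
    }
})

test_that("tables aggregate species counts and conserve total reads", {
    set.seed(74)
    seqs <- vapply(1:5, function(i) rand_dna(60), character(1))
    counts <- matrix(rbinom(10, 40, 0.5), nrow = 5,
                     dimnames = list(NULL, c("s1", "s2")))
    asvs <- structure(list(
        asvs = data.frame(asv_id = sprintf("asv_%d", 1:5), sequence = seqs,
                          md5 = md5_of_sequence(seqs),
                          stringsAsFactors = FALSE),
        counts = counts), class = "mb_asvs")
    anns <- list(
        annotate_asv("asv_1", make_hit("r1", "Gena spa",
                                       query_id = "asv_1"), NULL, tax),
        annotate_asv("asv_2", make_hit("r1", "Gena spa",
                                       query_id = "asv_2"), NULL, tax),
        annotate_asv("asv_3", make_hit("r1", "Gena spa", identity = 96,
                                       query_id = "asv_3"), NULL, tax),
        annotate_asv("asv_4", make_hit("bg", is_fish = FALSE,
                                       taxon = "human",
                                       query_id = "asv_4"), NULL, tax),
        annotate_asv("asv_5", NULL, NULL, tax))
    tb <- summarize_tables(anns, asvs)
    # two ASVs of the same species collapse into one row, counts summed
    expect_equal(nrow(tb$species), 1L)
    expect_equal(tb$species$s1, sum(counts[1:2, "s1"]))
    expect_equal(tb$species$s2, sum(counts[1:2, "s2"]))
    # higher and nonfish rows keep asv ids and 32-char digests
    expect_equal(tb$higher$asv_id, "asv_3")
    expect_match(tb$higher$md5, "^[0-9a-f]{32}$")
    expect_equal(tb$nonfish$taxon, "human")
    # conservation across the four tables
    tot <- sum(counts)
    got <- sum(tb$species$s1, tb$species$s2) +
        sum(tb$higher$s1, tb$higher$s2) +
        sum(tb$nonfish$s1, tb$nonfish$s2) +
        sum(tb$unassigned$s1, tb$unassigned$s2)
    expect_equal(got, tot)
})
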